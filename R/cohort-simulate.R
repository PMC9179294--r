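#' Specify the generative model for a transformed density trait
#'
#' The simulator treats each (suitably transformed) density measure as an
#' additive polygenic trait.  On the transformed scale a woman's latent value
#' is
#' \deqn{t = \beta_{age} \cdot age + \beta_{1/BMI} \cdot (1/BMI) +
#'   \gamma \cdot PRS^{std} + A + C + E,}
#' where the additive genetic component \eqn{A} is fully shared within
#' monozygotic (MZ) pairs and correlated 0.5 within dizygotic (DZ) twin and
#' sister pairs, \eqn{C} is an environment shared by all members of a family,
#' and \eqn{E} is individual-specific.  The variance fractions `a2`, `c2`,
#' `e2` must sum to one, so with no covariate or polygenic-score effects the
#' expected within-pair correlations of the transformed trait are `a2 + c2`
#' for MZ pairs and `a2/2 + c2` for DZ and sister pairs.
#'
#' Defaults follow twin-model estimates for the bright-area (Altocumulus
#' style) risk score: additive genetic variance about 60% with no separate
#' shared-environment component, so MZ pairs correlate about 0.6 and DZ and
#' sister pairs about 0.3.
#'
#' @param a2,c2,e2 Additive genetic, shared-environment and unique variance
#'   fractions of the transformed trait; must be non-negative and sum to 1.
#' @param beta_age Effect of one year of age on the transformed trait
#'   (trait-SD units per year).
#' @param beta_invbmi Effect of one unit of 1/BMI (m^2/kg) on the transformed
#'   trait.
#' @param prs_effect Effect of one standard deviation of the polygenic risk
#'   score on the transformed trait.  A single number gives every density
#'   measure the same total (marginal) effect; a named vector with entries
#'   among `cumulus`, `cumulus_percent`, `altocumulus`, `cirrocumulus`
#'   (unnamed measures get 0) specifies direct, measure-level effects,
#'   which also propagate down the nesting chain into the measures that
#'   contain them — injecting a signal into `altocumulus` only gives the
#'   dense area a fully mediated association of `measure_cor` times it.
#' @param measure_cor Weight in `[0, 1]` of the nesting chain linking
#'   successive density measures (brightest -> bright -> dense ->
#'   percent): each measure's latent inherits this fraction of its
#'   parent's latent — familial structure and any polygenic signal
#'   included — and draws the remainder independently with the same
#'   a2/c2/e2 decomposition.  Adjacent measures therefore correlate
#'   `measure_cor`, a bright-area polygenic effect propagates into the
#'   dense area scaled by `measure_cor`, and it is fully mediated: the
#'   dense-area association vanishes once the bright-area score is
#'   adjusted for.
#'
#' @return An object of class `trait_model`.
#' @examples
#' trait_model()                        # MZ ~ 0.6, DZ/sister ~ 0.3
#' trait_model(a2 = 0.4, e2 = 0.6)      # brightest-area style trait
#' @export
trait_model <- function(a2 = 0.6, c2 = 0, e2 = 1 - a2 - c2,
                        beta_age = 0, beta_invbmi = 0,
                        prs_effect = 0, measure_cor = 0.7) {
  if (any(c(a2, c2, e2) < 0)) {
    abort("variance fractions `a2`, `c2`, `e2` must be non-negative")
  }
  if (abs(a2 + c2 + e2 - 1) > 1e-8) {
    abort("variance fractions must satisfy a2 + c2 + e2 = 1")
  }
  if (measure_cor < 0 || measure_cor > 1) {
    abort("`measure_cor` must be in [0, 1]")
  }
  structure(
    list(a2 = a2, c2 = c2, e2 = e2,
         beta_age = beta_age, beta_invbmi = beta_invbmi,
         prs_effect = prs_effect, measure_cor = measure_cor),
    class = "trait_model"
  )
}

#' @export
print.trait_model <- function(x, ...) {
  cat("<trait_model>\n")
  cat(sprintf("  variance fractions: a2 = %.3g, c2 = %.3g, e2 = %.3g\n",
              x$a2, x$c2, x$e2))
  cat(sprintf("  implied pair correlations: MZ = %.3g, DZ/sister = %.3g\n",
              x$a2 + x$c2, x$a2 / 2 + x$c2))
  cat(sprintf("  beta_age = %.3g, beta_invbmi = %.3g\n",
              x$beta_age, x$beta_invbmi))
  cat("  prs_effect:", paste(format(x$prs_effect), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a twin and sister pedigree cohort
#'
#' Builds a cohort of MZ twin pairs, DZ twin pairs and non-twin sisters with
#' ages and body mass indices.  Twin pairs form their own two-person
#' families and share their age; non-twin sisters are grouped into families
#' whose sizes are drawn from `sib_family_sizes`, with member ages scattered
#' around a family mean.  Defaults reproduce a cohort of 584 MZ pairs, 318
#' DZ pairs and 755 sisters (2559 women) aged 30 to 80 with mean age 54
#' (SD 8.4) and mean BMI 26.1 (SD 5.2).
#'
#' @param n_mz_pairs,n_dz_pairs Numbers of MZ and DZ twin pairs.
#' @param n_sibs Number of non-twin sisters.
#' @param age_mean_sd,bmi_mean_sd Length-2 numeric vectors `c(mean, sd)` for
#'   age (years) and BMI (kg/m^2).
#' @param age_range Ages are truncated to this interval.
#' @param sib_family_sizes Candidate sizes for sister families; sizes are
#'   drawn uniformly and the last family truncated so sister count is exact.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#'
#' @return A tibble with columns `id`, `family_id`, `pair_id` (`NA` for
#'   non-twins), `zygosity` (`"MZ"`, `"DZ"` or `"SIB"`), `age`, `bmi`.
#' @examples
#' coh <- simulate_pedigrees(2, 1, 3, seed = 1)
#' dplyr::count(coh, zygosity)
#' @export
simulate_pedigrees <- function(n_mz_pairs = 584, n_dz_pairs = 318,
                               n_sibs = 755,
                               age_mean_sd = c(54, 8.4),
                               bmi_mean_sd = c(26.1, 5.2),
                               age_range = c(30, 80),
                               sib_family_sizes = 1:3,
                               seed = NULL) {
  stopifnot(n_mz_pairs >= 0, n_dz_pairs >= 0, n_sibs >= 0,
            age_mean_sd[2] > 0, bmi_mean_sd[2] > 0)
  if (n_mz_pairs + n_dz_pairs + n_sibs == 0) abort("empty cohort")
  if (!is.null(seed)) set.seed(seed)

  clip_age <- function(a) pmin(pmax(a, age_range[1]), age_range[2])

  rows <- list()
  fam <- 0L

  make_pair <- function(zyg, k, fam) {
    age <- clip_age(rnorm(1, age_mean_sd[1], age_mean_sd[2]))
    tibble::tibble(
      id = sprintf("%s%04d_%d", zyg, k, 1:2),
      family_id = sprintf("F%04d", fam),
      pair_id = sprintf("P_%s%04d", zyg, k),
      zygosity = zyg,
      age = age,  # co-twins share age
      bmi = pmax(rnorm(2, bmi_mean_sd[1], bmi_mean_sd[2]), 15)
    )
  }

  mz <- purrr::map(seq_len(n_mz_pairs), function(k) {
    make_pair("MZ", k, k)
  })
  dz <- purrr::map(seq_len(n_dz_pairs), function(k) {
    make_pair("DZ", k, n_mz_pairs + k)
  })
  fam <- n_mz_pairs + n_dz_pairs

  sibs <- list()
  if (n_sibs > 0) {
    sizes <- integer(0)
    while (sum(sizes) < n_sibs) {
      sizes <- c(sizes, sample(sib_family_sizes, 1))
    }
    sizes[length(sizes)] <- sizes[length(sizes)] -
      (sum(sizes) - n_sibs)
    sizes <- sizes[sizes > 0]
    sibs <- purrr::imap(sizes, function(sz, k) {
      fam_mean <- rnorm(1, age_mean_sd[1], age_mean_sd[2])
      tibble::tibble(
        id = sprintf("SIB%04d_%d", k, seq_len(sz)),
        family_id = sprintf("F%04d", fam + k),
        pair_id = NA_character_,
        zygosity = "SIB",
        age = clip_age(rnorm(sz, fam_mean, 5)),
        bmi = pmax(rnorm(sz, bmi_mean_sd[1], bmi_mean_sd[2]), 15)
      )
    })
  }

  dplyr::bind_rows(mz, dz, sibs)
}

#' Simulate genotypes with Mendelian within-family sharing
#'
#' Draws biallelic SNP genotypes for a pedigree cohort by explicit gamete
#' transmission: for every family two unobserved parents are given allele
#' pairs at each SNP (allele frequency drawn uniformly from `maf_range`),
#' and each child receives one allele from each parent.  MZ co-twins are
#' copies of a single meiosis, so their genotype vectors are identical; DZ
#' twins and sisters are independent meioses from the same parents and share
#' alleles identically by descent with expectation one half.
#'
#' @param cohort A cohort tibble from [simulate_pedigrees()].
#' @param n_snps Number of independent SNPs.
#' @param maf_range Interval in (0, 0.5] from which per-SNP effect-allele
#'   frequencies are drawn uniformly.
#' @param missing_rate Fraction of genotype calls set to missing at random
#'   (default 0), to exercise quality-control filters.
#' @param seed Integer seed.
#'
#' @return A [genotype_panel] whose dosages count effect alleles (0, 1, 2).
#' @examples
#' coh <- simulate_pedigrees(2, 2, 0, seed = 1)
#' gp <- simulate_genotypes(coh, n_snps = 5, seed = 1)
#' dim(gp$dosage)
#' @export
simulate_genotypes <- function(cohort, n_snps, maf_range = c(0.05, 0.5),
                               missing_rate = 0, seed = NULL) {
  stopifnot(n_snps >= 1, maf_range[1] > 0, maf_range[2] <= 0.5,
            missing_rate >= 0, missing_rate < 1)
  if (nrow(cohort) == 0) abort("empty cohort")
  if (!is.null(seed)) set.seed(seed)

  n <- nrow(cohort)
  maf <- runif(n_snps, maf_range[1], maf_range[2])

  fam_ids <- unique(cohort$family_id)
  n_fam <- length(fam_ids)
  fam_of <- match(cohort$family_id, fam_ids)

  # Parental alleles per family x SNP: mother (m1, m2), father (f1, f2).
  draw <- function() matrix(rbinom(n_fam * n_snps, 1, rep(maf, each = n_fam)),
                            n_fam, n_snps)
  m1 <- draw(); m2 <- draw(); f1 <- draw(); f2 <- draw()

  # One meiosis = choose one maternal and one paternal allele per SNP.
  meiosis <- function(fam_row) {
    pick_m <- matrix(runif(length(fam_row) * n_snps) < 0.5,
                     length(fam_row), n_snps)
    pick_f <- matrix(runif(length(fam_row) * n_snps) < 0.5,
                     length(fam_row), n_snps)
    mat <- ifelse(pick_m, m1[fam_row, , drop = FALSE],
                  m2[fam_row, , drop = FALSE])
    pat <- ifelse(pick_f, f1[fam_row, , drop = FALSE],
                  f2[fam_row, , drop = FALSE])
    mat + pat
  }

  # MZ co-twins duplicate one meiosis; everyone else gets their own.
  is_mz <- cohort$zygosity == "MZ"
  mz_pair <- ifelse(is_mz, cohort$pair_id, NA_character_)
  first_of_pair <- !is_mz | !duplicated(mz_pair)

  dosage <- matrix(NA_real_, n, n_snps)
  idx_first <- which(first_of_pair)
  dosage[idx_first, ] <- meiosis(fam_of[idx_first])
  idx_dup <- which(!first_of_pair)
  if (length(idx_dup)) {
    src <- idx_first[match(mz_pair[idx_dup], mz_pair[idx_first])]
    dosage[idx_dup, ] <- dosage[src, , drop = FALSE]
  }

  if (missing_rate > 0) {
    dosage[matrix(runif(n * n_snps) < missing_rate, n, n_snps)] <- NA_real_
  }
  rownames(dosage) <- cohort$id

  snp_meta <- tibble::tibble(
    snp_id = sprintf("snp%05d", seq_len(n_snps)),
    chrom = as.character(1 + (seq_len(n_snps) - 1) %% 22),
    pos = 1e5 + 1e3 * seq_len(n_snps),
    effect_allele = "A",
    other_allele = "G",
    maf = maf
  )
  colnames(dosage) <- snp_meta$snp_id
  genotype_panel(dosage, snp_meta)
}

# Correlated standard-normal draws shared within groups: for each level of
# `group`, one draw; members inherit it.
.group_normal <- function(group) {
  u <- unique(group)
  rnorm(length(u))[match(group, u)]
}

# Familial component (variance a2 + c2).  A is split A_family +
# A_segregation (variance a2/2 each): the family part is shared by all
# members, the segregation part is individual but duplicated within MZ
# pairs, giving corr(MZ) = a2 + c2 and corr(DZ/sib) = a2/2 + c2 once the
# unique part is added.
.familial_score <- function(cohort, a2, c2) {
  seg_group <- ifelse(cohort$zygosity == "MZ", cohort$pair_id, cohort$id)
  sqrt(a2 / 2) * .group_normal(cohort$family_id) +
    sqrt(a2 / 2) * .group_normal(seg_group) +
    sqrt(c2) * .group_normal(cohort$family_id)
}

#' Simulate nested mammographic density measures
#'
#' Generates, for every woman in the cohort, the four raw density measures
#' (Cumulus dense area, Altocumulus "bright" area, Cirrocumulus "brightest"
#' area, total breast area) by inverting the normalizing transformations the
#' downstream analysis uses: dense areas are cubes of a Gaussian latent
#' (cube-root transformed traits), the brightest area is the exponential of
#' a Gaussian latent (log transformed), and the total area is implied by a
#' squared-Gaussian percent-density latent.  Location and scale constants
#' are chosen so medians land near values typical of screening mammograms
#' (Cumulus ~ 29 cm^2, Altocumulus ~ 11 cm^2, Cirrocumulus ~ 1.6 cm^2,
#' percent density ~ 30%).
#'
#' Each measure's latent follows the additive polygenic model of
#' [trait_model()]; the measures form a nesting chain (brightest ->
#' bright -> dense -> percent) with weight `measure_cor`, so they are
#' strongly but not perfectly correlated within a woman and a polygenic
#' signal placed on one measure propagates — fully mediated — to the
#' measures that physically contain it.
#' Nesting (Cirrocumulus <= Altocumulus <= Cumulus <= total area) is
#' enforced by clipping, and non-positive back-transformed areas are clipped
#' at `area_floor` (a message reports how many values were touched).
#'
#' @param cohort A cohort tibble from [simulate_pedigrees()].
#' @param model A [trait_model()].
#' @param panel,weights Optional [genotype_panel] and weight table (see
#'   [read_prs_weights()]); when both are given the standardized overall
#'   polygenic score enters each latent with coefficient `model$prs_effect`.
#' @param area_floor Smallest admissible area in cm^2.
#' @param seed Integer seed.
#'
#' @return The cohort tibble with columns `cumulus`, `altocumulus`,
#'   `cirrocumulus`, `total_area` (cm^2) appended.  The Gaussian latents are
#'   attached as `attr(, "latents")` (a tibble, one column per measure) for
#'   calibration checks.
#' @examples
#' coh <- simulate_pedigrees(50, 50, 0, seed = 1)
#' dens <- simulate_density(coh, trait_model(), seed = 2)
#' all(dens$cirrocumulus <= dens$altocumulus)
#' @export
simulate_density <- function(cohort, model = trait_model(),
                             panel = NULL, weights = NULL,
                             area_floor = 0.05, seed = NULL) {
  stopifnot(inherits(model, "trait_model"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort)

  measures <- c("cumulus", "cumulus_percent", "altocumulus", "cirrocumulus")
  gamma <- model$prs_effect
  wm <- model$measure_cor
  if (length(gamma) == 1 && is.null(names(gamma))) {
    # scalar = the same total (marginal) effect on every measure: the
    # chain already propagates a fraction `measure_cor` from the parent,
    # so child nodes only add the remainder directly; the chain root
    # (cirrocumulus) carries the full effect
    gamma <- setNames(rep(gamma * (1 - wm), 4), measures)
    gamma[["cirrocumulus"]] <- model$prs_effect
  } else {
    # named vector = direct, measure-level effects that propagate down
    # the nesting chain
    gamma <- setNames(ifelse(measures %in% names(gamma),
                             gamma[measures], 0), measures)
  }

  prs_std <- rep(0, n)
  if (!is.null(panel) && !is.null(weights)) {
    prs <- compute_prs(panel, weights, endpoint = "overall")$prs
    prs_std <- as.numeric(scale(prs))
  }

  e2 <- model$e2
  w <- model$measure_cor
  fixed <- model$beta_age * cohort$age + model$beta_invbmi / cohort$bmi

  # Nesting chain mirroring the physical containment brightest < bright <
  # dense area: each measure inherits a fraction w of its parent's whole
  # latent (carrying any polygenic signal with it) and fills the rest with
  # an independent familial-plus-unique draw, so every measure has the
  # exact a2/c2/e2 correlation structure, adjacent measures correlate w,
  # and a parent's polygenic effect is fully mediated by the parent.
  fresh <- function() {
    .familial_score(cohort, model$a2, model$c2) + sqrt(e2) * rnorm(n)
  }
  child <- function(parent, g) {
    w * parent + sqrt(1 - w^2) * fresh() + g * prs_std
  }
  latent <- list()
  latent$cirrocumulus <- fresh() + gamma[["cirrocumulus"]] * prs_std
  latent$altocumulus <- child(latent$cirrocumulus, gamma[["altocumulus"]])
  latent$cumulus <- child(latent$altocumulus, gamma[["cumulus"]])
  latent$cumulus_percent <- child(latent$cumulus, gamma[["cumulus_percent"]])
  latent <- purrr::map(latent[measures], ~ .x + fixed)
  latent <- tibble::as_tibble(latent)

  # Back-transform: cube roots ~ N(mu, s) for the dense areas, log for the
  # brightest area, sqrt for percent density.  Constants target the medians
  # and spreads noted above.
  cumulus <- (3.09 + 0.60 * latent$cumulus)^3
  altocumulus <- (2.25 + 0.50 * latent$altocumulus)^3
  cirrocumulus <- exp(0.47 + 1.05 * latent$cirrocumulus)
  percent <- pmin(pmax(5.45 + 1.50 * latent$cumulus_percent, 1), 9.8)^2

  n_clip <- sum(cumulus < area_floor) + sum(altocumulus < area_floor) +
    sum(cirrocumulus < area_floor)
  cumulus <- pmax(cumulus, area_floor)
  altocumulus <- pmin(pmax(altocumulus, area_floor), cumulus)
  cirrocumulus <- pmin(pmax(cirrocumulus, area_floor), altocumulus)
  total_area <- pmax(cumulus * 100 / percent, cumulus)
  if (n_clip > 0) {
    inform(sprintf("simulate_density: %d area value(s) clipped at floor %g",
                   n_clip, area_floor))
  }

  out <- dplyr::mutate(cohort,
                       cumulus = cumulus,
                       altocumulus = altocumulus,
                       cirrocumulus = cirrocumulus,
                       total_area = total_area)
  attr(out, "latents") <- latent
  out
}

#' Read or write a cohort table as TSV
#'
#' The on-disk layout is one row per woman with the pedigree columns (`id`,
#' `family_id`, `pair_id`, `zygosity`), covariates (`age`, `bmi`) and
#' whatever density / risk-score columns have been added.
#'
#' @param cohort A cohort tibble.
#' @param path File path.
#' @return `read_cohort_tsv()` returns a tibble; `write_cohort_tsv()`
#'   returns `path` invisibly.
#' @export
write_cohort_tsv <- function(cohort, path) {
  readr::write_tsv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    id = "c", family_id = "c", pair_id = "c", zygosity = "c",
                    .default = readr::col_double()
                  ))
}
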