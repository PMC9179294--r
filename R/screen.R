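.mrs_cols <- c(cumulus = "cumulus_mrs", cumulus_percent = "percent_mrs",
               altocumulus = "alto_mrs", cirrocumulus = "cirro_mrs",
               cumulus_white = "white_mrs")

# Normalize a PRS input (one compute_prs() tibble or several bound
# together) into a wide tibble keyed by id, checking alignment with data.
.prs_wide <- function(prs, data) {
  stopifnot(all(c("id", "endpoint", "prs") %in% names(prs)))
  wide <- tidyr::pivot_wider(prs, id_cols = "id", names_from = "endpoint",
                             values_from = "prs")
  m <- match(data$id, wide$id)
  if (anyNA(m)) abort("PRS ids do not cover the cohort: misaligned ids")
  wide[m, , drop = FALSE]
}

#' Bonferroni adjustment
#'
#' @param p Raw p-values.
#' @param n_tests Number of tests (default `length(p)`).
#' @return `pmin(1, p * n_tests)`.
#' @export
bonferroni_adjust <- function(p, n_tests = length(p)) pmin(1, p * n_tests)

#' Excess of nominally significant tests
#'
#' Given the p-values of a family of tests (assumed independent), compares
#' the observed count of nominal hits at level `alpha` with the count
#' expected by chance via the one-sided binomial tail
#' \eqn{P(K \ge k_{obs})} with \eqn{K \sim Bin(n_{tests}, \alpha)}.
#'
#' @param p Raw p-values.
#' @param alpha Nominal significance level.
#' @param n_tests Number of tests.
#' @return A one-row tibble: `n_tests`, `n_nominal`, `n_expected`,
#'   `p_excess`.
#' @examples
#' excess_significance(c(rep(0.01, 18), runif(184, 0.06, 1)))
#' @export
excess_significance <- function(p, alpha = 0.05, n_tests = length(p)) {
  k <- sum(p < alpha)
  tibble::tibble(
    n_tests = n_tests,
    n_nominal = k,
    n_expected = n_tests * alpha,
    p_excess = pbinom(k - 1, n_tests, alpha, lower.tail = FALSE)
  )
}

#' Evidence label for a BIC difference
#'
#' Bins a (positive) BIC difference between two models into the customary
#' evidence grades: `< 2` negligible, `[2, 6)` positive, `[6, 10)` strong,
#' `>= 10` very strong.
#'
#' @param delta_bic Numeric BIC difference(s).
#' @return Character vector of labels.
#' @examples
#' label_bic_evidence(c(0, 3, 6.78, 15.54))
#' @export
label_bic_evidence <- function(delta_bic) {
  stopifnot(all(is.finite(delta_bic)))
  as.character(cut(delta_bic, c(-Inf, 2, 6, 10, Inf), right = FALSE,
                   labels = c("negligible", "positive", "strong",
                              "very strong")))
}

#' Correlations and associations between risk scores
#'
#' For every mammogram risk score (5) and every polygenic-score endpoint
#' present in `prs` (up to 3: overall, ER-negative, ER-positive disease),
#' estimates
#'
#' * the Pearson correlation with family-clustered bootstrap CI
#'   ([family_corr()]), plus the BIC of the corresponding one-predictor
#'   family mixed model, and
#' * the mixed-model association coefficient adjusted for `k` genotype
#'   principal components as fixed effects, scaled per adjusted SD of the
#'   PRS ([opera_scale()]), with its BIC.
#'
#' With five risk scores and three endpoints this yields the canonical 15
#' correlation rows and 15 association rows; within each endpoint the
#' outcome with the smallest BIC is flagged.
#'
#' @param data Cohort tibble with the five `*_mrs` columns and pedigree
#'   columns.
#' @param prs Stacked PRS tibble (`id`, `endpoint`, `prs`), e.g.
#'   `dplyr::bind_rows()` of [compute_prs()] calls.
#' @param pcs Principal-component score matrix from [compute_pcs()],
#'   rows aligned with `data` ids.
#' @param n_boot Bootstrap resamples for the correlation CIs.
#' @param seed Optional seed for the bootstrap.
#' @return An object of class `prs_analysis`: list with tibbles
#'   `correlations` and `associations` (columns `outcome`, `predictor`,
#'   `estimate`, `conf.low`, `conf.high`, `p.value`, `bic`, `min_bic`)
#'   and metadata `n`, `n_families`.
#' @export
run_prs_analysis <- function(data, prs, pcs, n_boot = 1000, seed = NULL) {
  miss <- setdiff(unname(.mrs_cols), names(data))
  if (length(miss)) abort(paste("missing MRS columns:",
                                paste(miss, collapse = ", ")))
  pw <- .prs_wide(prs, data)
  endpoints <- setdiff(names(pw), "id")
  pcs <- as.matrix(pcs)
  if (!is.null(rownames(pcs))) {
    m <- match(data$id, rownames(pcs))
    if (anyNA(m)) abort("PC matrix rows do not cover the cohort: misaligned ids")
    pcs <- pcs[m, , drop = FALSE]
  } else if (nrow(pcs) != nrow(data)) {
    abort("PC matrix rows do not match the cohort: misaligned ids")
  }
  if (!is.null(seed)) set.seed(seed)

  grid <- tidyr::expand_grid(outcome = unname(.mrs_cols),
                             predictor = endpoints)

  one <- function(outcome, predictor) {
    y <- data[[outcome]]
    x <- pw[[predictor]]
    ok <- complete.cases(y, x)
    coh <- data[ok, , drop = FALSE]

    ct <- family_corr(y[ok], x[ok], coh, n_boot = n_boot)
    X1 <- cbind(`(Intercept)` = 1, prs = x[ok])
    f1 <- fit_reml(y[ok], X1, coh)
    corr_row <- tibble::tibble(
      outcome = outcome, predictor = predictor,
      estimate = ct$estimate, conf.low = ct$conf.low,
      conf.high = ct$conf.high, p.value = ct$p.value, bic = f1$bic
    )

    Xp <- pcs[ok, , drop = FALSE]
    X2 <- cbind(`(Intercept)` = 1, prs = x[ok], Xp)
    f2 <- fit_reml(y[ok], X2, coh)
    op <- opera_scale(f2, x[ok], covariates = Xp, term = "prs")
    assoc_row <- tibble::tibble(
      outcome = outcome, predictor = predictor,
      estimate = op$estimate, conf.low = op$conf.low,
      conf.high = op$conf.high, p.value = op$p.value, bic = f2$bic
    )
    list(corr = corr_row, assoc = assoc_row)
  }

  res <- purrr::pmap(grid, one)
  flag_min <- function(tab) {
    dplyr::mutate(dplyr::group_by(tab, .data$predictor),
                  min_bic = .data$bic == min(.data$bic)) |>
      dplyr::ungroup()
  }
  out <- list(
    correlations = flag_min(dplyr::bind_rows(purrr::map(res, "corr"))),
    associations = flag_min(dplyr::bind_rows(purrr::map(res, "assoc"))),
    n = nrow(data),
    n_families = length(unique(data$family_id))
  )
  class(out) <- "prs_analysis"
  out
}

#' @export
print.prs_analysis <- function(x, ...) {
  cat(sprintf("<prs_analysis> %d individuals, %d families\n",
              x$n, x$n_families))
  cat("correlations:\n"); print(x$correlations, n = Inf)
  cat("associations (per adjusted SD of PRS):\n")
  print(x$associations, n = Inf)
  invisible(x)
}

# Default mutual-adjustment sets: for each outcome risk score, the other
# scores it is customarily adjusted for (composites are not adjusted for
# their own components' complement, matching the published table layout).
.default_adjustment_sets <- function() {
  list(
    cumulus_mrs = list("alto_mrs", "cirro_mrs", c("alto_mrs", "cirro_mrs")),
    percent_mrs = list("alto_mrs", "cirro_mrs", c("alto_mrs", "cirro_mrs")),
    alto_mrs = list("cumulus_mrs", "cirro_mrs",
                    c("cumulus_mrs", "cirro_mrs")),
    cirro_mrs = list("cumulus_mrs", "alto_mrs",
                     c("cumulus_mrs", "alto_mrs")),
    white_mrs = list("alto_mrs", "cirro_mrs", c("alto_mrs", "cirro_mrs"))
  )
}

#' Associations after mutual adjustment between risk scores
#'
#' Refits each risk-score-on-PRS mixed model with one or more of the other
#' mammogram risk scores added as fixed effects, quantifying how much of
#' an association is carried by the correlated scores.  For every outcome,
#' adjustment set and endpoint, reports the adjusted per-adjusted-SD
#' coefficient and the attenuation relative to the unadjusted model,
#' `100 * (b_unadjusted - b_adjusted) / b_unadjusted` (percent).
#'
#' @inheritParams run_prs_analysis
#' @param adjustment_sets Named list (by outcome MRS column) of character
#'   vectors of MRS columns to adjust for; defaults to every other-score
#'   combination of the published layout.  An adjustment set containing
#'   its own outcome is an error.
#' @return A tibble of class `mutual_adjustment`: `outcome`, `adjusted_for`,
#'   `predictor`, `estimate`, `conf.low`, `conf.high`, `p.value`,
#'   `estimate_unadjusted`, `attenuation_pct`.
#' @export
run_mutual_adjustment <- function(data, prs, pcs,
                                  adjustment_sets = NULL) {
  pw <- .prs_wide(prs, data)
  endpoints <- setdiff(names(pw), "id")
  pcs <- as.matrix(pcs)
  if (is.null(adjustment_sets)) adjustment_sets <- .default_adjustment_sets()

  rows <- list()
  for (outcome in names(adjustment_sets)) {
    for (set in adjustment_sets[[outcome]]) {
      if (outcome %in% set) {
        abort(sprintf("adjustment set for `%s` contains the outcome itself",
                      outcome))
      }
      for (ep in endpoints) {
        y <- data[[outcome]]
        x <- pw[[ep]]
        adj <- as.matrix(data[, set, drop = FALSE])
        ok <- complete.cases(y, x, adj)
        coh <- data[ok, , drop = FALSE]
        Xp <- pcs[ok, , drop = FALSE]

        X0 <- cbind(`(Intercept)` = 1, prs = x[ok], Xp)
        b0 <- opera_scale(fit_reml(y[ok], X0, coh), x[ok],
                          covariates = Xp, term = "prs")

        cov_adj <- cbind(Xp, adj[ok, , drop = FALSE])
        X1 <- cbind(`(Intercept)` = 1, prs = x[ok], cov_adj)
        b1 <- opera_scale(fit_reml(y[ok], X1, coh), x[ok],
                          covariates = cov_adj, term = "prs")

        rows[[length(rows) + 1]] <- tibble::tibble(
          outcome = outcome,
          adjusted_for = paste(set, collapse = "+"),
          predictor = ep,
          estimate = b1$estimate, conf.low = b1$conf.low,
          conf.high = b1$conf.high, p.value = b1$p.value,
          estimate_unadjusted = b0$estimate,
          attenuation_pct = 100 * (b0$estimate - b1$estimate) / b0$estimate
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mutual_adjustment", class(out))
  out
}

#' Per-SNP association screen against the mammogram risk scores
#'
#' Fits, for every SNP and every mammogram risk score, the family mixed
#' model with the SNP's effect-allele dosage as predictor and `k` genotype
#' principal components as fixed-effect covariates, then summarizes the
#' screen per risk score: nominal hits at `alpha`, the chance expectation,
#' a one-sided binomial excess-significance p-value, direction-consistent
#' nominal hits, and Bonferroni-adjusted discoveries.  Monomorphic SNPs
#' are skipped with a warning and excluded from the number of tests.
#'
#' Note the excess-of-significance test treats SNPs as independent; for
#' panels containing fine-mapped variants in linkage disequilibrium it is
#' anti-conservative.
#'
#' @inheritParams run_prs_analysis
#' @param panel A [genotype_panel] whose samples cover `data$id`.
#' @param snp_ids SNPs to test (default: every SNP in the panel).
#' @param alpha Nominal significance level.
#' @param expected_direction Named numeric (+1/-1) per MRS column giving
#'   the direction in which an association is counted as consistent with
#'   the score's relation to disease risk; defaults to +1 for all five.
#' @return An object of class `snp_screen`: list with `per_snp` (one row
#'   per SNP x MRS: `snp_id`, `outcome`, `estimate`, `std.error`,
#'   `p.value`, `p.bonferroni`, `direction_consistent`), `summary` (one
#'   row per MRS), `n_tests`, `alpha`.
#' @export
run_snp_screen <- function(data, panel, pcs, snp_ids = NULL,
                           alpha = 0.05, expected_direction = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.null(snp_ids)) snp_ids <- panel$snp_meta$snp_id
  if (length(snp_ids) < 1) abort("need at least one SNP")
  if (is.null(expected_direction)) {
    expected_direction <- setNames(rep(1, 5), unname(.mrs_cols))
  }
  pcs <- as.matrix(pcs)
  m <- match(data$id, panel$sample_ids)
  if (anyNA(m)) abort("panel samples do not cover the cohort: misaligned ids")

  rows <- list()
  skipped <- character(0)
  for (s in snp_ids) {
    g <- panel$dosage[m, s]
    if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
    if (sd(g) == 0) {
      skipped <- c(skipped, s)
      next
    }
    for (mc in unname(.mrs_cols)) {
      y <- data[[mc]]
      ok <- complete.cases(y, g)
      X <- cbind(`(Intercept)` = 1, dosage = g[ok], pcs[ok, , drop = FALSE])
      fit <- fit_reml(y[ok], X, data[ok, , drop = FALSE])
      cf <- fit$coefficients[fit$coefficients$term == "dosage", ]
      rows[[length(rows) + 1]] <- tibble::tibble(
        snp_id = s, outcome = mc,
        estimate = cf$estimate, std.error = cf$std.error,
        p.value = cf$p.value,
        direction_consistent =
          sign(cf$estimate) == sign(expected_direction[[mc]])
      )
    }
  }
  if (length(skipped)) {
    warn(sprintf("run_snp_screen: skipped %d monomorphic SNP(s): %s",
                 length(skipped), paste(head(skipped, 5), collapse = ", ")))
  }
  per_snp <- dplyr::bind_rows(rows)
  if (nrow(per_snp) == 0) abort("no polymorphic SNPs to test")
  n_tests <- length(unique(per_snp$snp_id))
  per_snp <- dplyr::mutate(per_snp,
                           p.bonferroni = bonferroni_adjust(.data$p.value,
                                                            n_tests))

  summary <- per_snp |>
    dplyr::group_by(outcome = .data$outcome) |>
    dplyr::summarise(
      n_tests = n_tests,
      n_nominal = sum(.data$p.value < alpha),
      n_expected = n_tests * alpha,
      p_excess = pbinom(sum(.data$p.value < alpha) - 1, n_tests, alpha,
                        lower.tail = FALSE),
      n_direction_consistent = sum(.data$p.value < alpha &
                                     .data$direction_consistent),
      n_bonferroni_hits = sum(.data$p.bonferroni < alpha),
      .groups = "drop"
    )

  structure(list(per_snp = per_snp, summary = summary,
                 n_tests = n_tests, alpha = alpha,
                 n_skipped = length(skipped)),
            class = "snp_screen")
}

#' @export
print.snp_screen <- function(x, ...) {
  cat(sprintf("<snp_screen> %d SNPs tested at alpha = %g (%d skipped)\n",
              x$n_tests, x$alpha, x$n_skipped))
  print(x$summary)
  invisible(x)
}
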