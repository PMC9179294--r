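#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test on biallelic genotype counts.  Conditional on the
#' observed allele counts, the number of heterozygotes under
#' Hardy-Weinberg equilibrium follows a known discrete distribution over
#' the heterozygote counts of the same parity; the p-value sums the
#' probabilities of all configurations no more probable than the observed
#' one.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (reference homozygote,
#'   heterozygote, alternate homozygote).
#' @return The exact two-sided p-value.  A monomorphic site returns 1.
#' @examples
#' hwe_exact_test(64, 32, 4)
#' hwe_exact_test(0, 100, 0) < 1e-7   # extreme heterozygote excess
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n < 1) abort("at least one genotype is required")
  n_rare <- 2 * min(n_hom_ref, n_hom_alt) + n_het
  if (n_rare == 0 || n_rare == 2 * n) return(1)

  # Heterozygote counts share the parity of the rare-allele count.
  het_grid <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  # log P(het = h | allele counts) up to a shared constant
  log_p <- function(h) {
    rare_hom <- (n_rare - h) / 2
    common_hom <- n - h - rare_hom
    h * log(2) - lgamma(h + 1) - lgamma(rare_hom + 1) -
      lgamma(common_hom + 1)
  }
  lp <- log_p(het_grid)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- p[match(n_het, het_grid)]
  if (is.na(obs)) abort("heterozygote count inconsistent with allele counts")
  # tolerance guards ties against floating-point noise
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

# Hard-call fractional dosages at 0.5 / 1.5 for QC statistics only.
.hard_call <- function(dosage) {
  hc <- matrix(NA_real_, nrow(dosage), ncol(dosage))
  hc[dosage < 0.5] <- 0
  hc[dosage >= 0.5 & dosage < 1.5] <- 1
  hc[dosage >= 1.5] <- 2
  dimnames(hc) <- dimnames(dosage)
  hc
}

#' Genotype quality control for a panel
#'
#' Applies the standard pre-analysis filters in two stages, samples first
#' and then SNPs on the surviving samples:
#'
#' 1. samples with call rate below `sample_call_rate_min`;
#' 2. samples whose observed heterozygosity (over hard-called genotypes)
#'    lies more than `het_sd` standard deviations from the sample mean;
#' 3. SNPs with call rate below `snp_call_rate_min`;
#' 4. SNPs out of Hardy-Weinberg equilibrium at `hwe_p_min`;
#' 5. SNPs with minor allele frequency below `maf_min`.
#'
#' Fractional (imputed) dosages are accepted; Hardy-Weinberg and
#' heterozygosity statistics use genotypes hard-called at 0.5/1.5.  SNPs
#' named in `exempt_snps` (typically the SNPs of a published polygenic
#' score, whose allele frequencies may fall below a cohort-level floor)
#' bypass the MAF filter; the exemption is reported.
#'
#' @param panel A [genotype_panel].
#' @param snp_call_rate_min,sample_call_rate_min Minimum call rates.
#' @param hwe_p_min Hardy-Weinberg exact-test p-value threshold.
#' @param maf_min Minor-allele-frequency floor.
#' @param het_sd Heterozygosity outlier cutoff in standard deviations.
#' @param exempt_snps Character vector of SNP ids exempt from the MAF
#'   filter.
#' @return A list with elements `panel` (the filtered [genotype_panel]) and
#'   `report` (class `qc_report`: per-filter removal counts in application
#'   order, thresholds, and ids removed).
#' @export
qc_filter <- function(panel,
                      snp_call_rate_min = 0.95,
                      sample_call_rate_min = 0.95,
                      hwe_p_min = 1e-7,
                      maf_min = 0.01,
                      het_sd = 4.89,
                      exempt_snps = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  d <- panel$dosage
  if (nrow(d) == 0 || ncol(d) == 0) abort("empty panel")
  steps <- list()

  # -- sample filters ------------------------------------------------------
  cr_sample <- rowMeans(!is.na(d))
  drop_cr <- cr_sample < sample_call_rate_min
  steps$sample_call_rate <- rownames(d)[drop_cr]
  d <- d[!drop_cr, , drop = FALSE]

  hc <- .hard_call(d)
  het <- rowMeans(hc == 1, na.rm = TRUE)
  mu <- mean(het); s <- sd(het)
  drop_het <- if (is.na(s) || s == 0) rep(FALSE, nrow(d)) else
    abs(het - mu) > het_sd * s
  steps$sample_heterozygosity <- rownames(d)[drop_het]
  d <- d[!drop_het, , drop = FALSE]
  if (nrow(d) == 0) abort("all samples removed by QC")

  # -- SNP filters (on surviving samples) ---------------------------------
  cr_snp <- colMeans(!is.na(d))
  drop_snp_cr <- cr_snp < snp_call_rate_min
  steps$snp_call_rate <- colnames(d)[drop_snp_cr]
  keep <- !drop_snp_cr

  hc <- .hard_call(d)
  hwe_p <- vapply(seq_len(ncol(d)), function(j) {
    g <- hc[, j]
    hwe_exact_test(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
                   sum(g == 2, na.rm = TRUE))
  }, numeric(1))
  drop_hwe <- keep & hwe_p < hwe_p_min
  steps$snp_hwe <- colnames(d)[drop_hwe]
  keep <- keep & !drop_hwe

  af <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  exempt <- colnames(d) %in% exempt_snps
  drop_maf <- keep & maf < maf_min & !exempt
  n_exempted <- sum(keep & maf < maf_min & exempt)
  steps$snp_maf <- colnames(d)[drop_maf]
  keep <- keep & !drop_maf

  out <- panel_subset(panel, samples = rownames(d), snps = colnames(d)[keep])
  out$snp_meta$call_rate <- cr_snp[keep]
  out$snp_meta$maf <- maf[keep]

  report <- structure(list(
    n_samples_in = nrow(panel$dosage), n_snps_in = ncol(panel$dosage),
    n_samples_out = nrow(out$dosage), n_snps_out = ncol(out$dosage),
    removed = purrr::map(steps, identity),
    counts = purrr::map_int(steps, length),
    thresholds = list(snp_call_rate_min = snp_call_rate_min,
                      sample_call_rate_min = sample_call_rate_min,
                      hwe_p_min = hwe_p_min, maf_min = maf_min,
                      het_sd = het_sd),
    n_maf_exempted = n_exempted
  ), class = "qc_report")
  if (n_exempted > 0) {
    inform(sprintf("qc_filter: %d weight-file SNP(s) below MAF %g kept by exemption",
                   n_exempted, maf_min))
  }
  list(panel = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat(sprintf("  samples: %d -> %d; SNPs: %d -> %d\n",
              x$n_samples_in, x$n_samples_out, x$n_snps_in, x$n_snps_out))
  for (nm in names(x$counts)) {
    cat(sprintf("  %-24s removed %d\n", nm, x$counts[[nm]]))
  }
  if (x$n_maf_exempted > 0) {
    cat(sprintf("  (%d SNP(s) below the MAF floor kept by exemption)\n",
                x$n_maf_exempted))
  }
  invisible(x)
}

#' Serialize a QC report to JSON
#'
#' @param report A `qc_report` from [qc_filter()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Principal components of a genotype panel
#'
#' Computes principal-component scores of the column-standardized dosage
#' matrix (missing dosages imputed to the column mean; zero-variance
#' columns dropped).  Columns are ordered by decreasing eigenvalue, scores
#' are mutually orthogonal with mean zero, and each component's sign is
#' fixed so its largest-magnitude SNP loading is positive.
#'
#' @param panel A [genotype_panel].
#' @param k Number of components.
#' @return A numeric matrix (individuals x `k`) with columns `PC1..PCk`,
#'   with the eigenvalues (score variances) attached as
#'   `attr(, "eigenvalues")`.
#' @export
compute_pcs <- function(panel, k = 10) {
  stopifnot(inherits(panel, "genotype_panel"))
  d <- panel$dosage
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  keep <- apply(d, 2, sd) > 0
  d <- d[, keep, drop = FALSE]
  if (k >= min(dim(d))) {
    abort(sprintf("k = %d must be smaller than min(n_samples, n_snps) = %d",
                  k, min(dim(d))))
  }
  pc <- prcomp(d, center = TRUE, scale. = TRUE, rank. = k)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(k)) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- panel$sample_ids
  attr(scores, "eigenvalues") <- pc$sdev[seq_len(k)]^2
  scores
}
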