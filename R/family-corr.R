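#' Pearson correlation with family-aware inference
#'
#' Estimates the Pearson correlation between two per-individual variables
#' in a family-structured sample.  The point estimate is the ordinary
#' Pearson correlation; the confidence interval comes from a percentile
#' bootstrap that resamples whole families (so within-family dependence is
#' preserved); the p-value uses the Fisher z transform with an effective
#' sample size equal to the number of families (the independent units),
#' alongside the naive Fisher z p-value that treats individuals as
#' independent.
#'
#' @param x,y Numeric vectors, one value per individual.
#' @param cohort Cohort tibble aligned with `x`/`y` (`family_id` used).
#' @param n_boot Number of bootstrap resamples (>= 200).
#' @param conf_level Confidence level.
#' @param seed Optional integer seed for the bootstrap.
#' @return A one-row tibble: `estimate`, `conf.low`, `conf.high`,
#'   `p.value` (family-clustered Fisher z), `p.naive`, `n`, `n_families`,
#'   `n_boot`.
#' @examples
#' coh <- simulate_pedigrees(30, 30, 30, seed = 1)
#' family_corr(rnorm(nrow(coh)), rnorm(nrow(coh)), coh, n_boot = 200, seed = 2)
#' @export
family_corr <- function(x, y, cohort, n_boot = 1000, conf_level = 0.95,
                        seed = NULL) {
  stopifnot(length(x) == length(y), length(x) == nrow(cohort))
  if (n_boot < 200) abort("n_boot must be at least 200")
  if (sd(x) == 0 || sd(y) == 0) abort("constant input")
  if (!is.null(seed)) set.seed(seed)

  r <- cor(x, y)
  fam_idx <- split(seq_along(x), cohort$family_id)
  n_fam <- length(fam_idx)

  boot_r <- vapply(seq_len(n_boot), function(b) {
    take <- unlist(fam_idx[sample.int(n_fam, n_fam, replace = TRUE)],
                   use.names = FALSE)
    xs <- x[take]; ys <- y[take]
    if (sd(xs) == 0 || sd(ys) == 0) return(NA_real_)
    cor(xs, ys)
  }, numeric(1))
  boot_r <- boot_r[!is.na(boot_r)]
  a <- (1 - conf_level) / 2
  ci <- quantile(boot_r, c(a, 1 - a), names = FALSE)

  fisher_p <- function(r, n_eff) {
    if (n_eff <= 3) return(NA_real_)
    z <- atanh(min(max(r, -1), 1)) * sqrt(n_eff - 3)
    2 * pnorm(-abs(z))
  }
  tibble::tibble(
    estimate = r,
    conf.low = ci[1],
    conf.high = ci[2],
    p.value = fisher_p(r, n_fam),
    p.naive = fisher_p(r, length(x)),
    n = length(x),
    n_families = n_fam,
    n_boot = n_boot
  )
}
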