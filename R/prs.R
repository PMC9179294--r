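#' Compute a polygenic risk score from effect-allele dosages
#'
#' For each individual the score is the weighted sum of effect-allele
#' dosages over the SNPs of a weight table, \eqn{PRS_j = \sum_i \beta_i
#' X_{ij}}.  Where the panel's counted allele differs from the weight
#' file's effect allele the dosage is flipped (`X -> 2 - X`); missing
#' dosages are imputed to twice the allele frequency of the effect allele
#' (reported via a message).  Strand-ambiguous SNPs (A/T or C/G) whose
#' alleles cannot be oriented are dropped with a warning when
#' `drop_ambiguous = TRUE`.
#'
#' @param panel A [genotype_panel].
#' @param weights A weight tibble as returned by [read_prs_weights()] or
#'   [simulate_weights()].
#' @param endpoint Which weight column to use: `"overall"`, `"ERneg"` or
#'   `"ERpos"`.
#' @param drop_ambiguous Drop strand-ambiguous SNPs with mismatched allele
#'   pairs instead of erroring.
#' @return A tibble with columns `id`, `endpoint`, `prs` (unitless log-odds
#'   sum), one row per individual in panel order.
#' @examples
#' coh <- simulate_pedigrees(5, 5, 5, seed = 1)
#' gp <- simulate_genotypes(coh, 20, seed = 2)
#' w <- simulate_weights(gp, seed = 3)
#' head(compute_prs(gp, w, "overall"))
#' @export
compute_prs <- function(panel, weights,
                        endpoint = c("overall", "ERneg", "ERpos"),
                        drop_ambiguous = TRUE) {
  stopifnot(inherits(panel, "genotype_panel"))
  endpoint <- match.arg(endpoint)
  bcol <- switch(endpoint, overall = "beta_overall",
                 ERneg = "beta_erneg", ERpos = "beta_erpos")
  if (!bcol %in% names(weights)) {
    abort(sprintf("weight table lacks column `%s`", bcol))
  }

  idx <- match(weights$snp_id, panel$snp_meta$snp_id)
  if (anyNA(idx)) {
    abort(paste("weight SNPs absent from panel:",
                paste(head(weights$snp_id[is.na(idx)], 10), collapse = ", ")))
  }
  pm <- panel$snp_meta[idx, ]

  same <- pm$effect_allele == weights$effect_allele &
    pm$other_allele == weights$other_allele
  flipped <- pm$effect_allele == weights$other_allele &
    pm$other_allele == weights$effect_allele
  unresolved <- !same & !flipped
  if (any(unresolved)) {
    if (drop_ambiguous) {
      warn(sprintf("compute_prs: dropping %d SNP(s) with unresolvable allele orientation",
                   sum(unresolved)))
      keepers <- !unresolved
      weights <- weights[keepers, , drop = FALSE]
      idx <- idx[keepers]
      flipped <- flipped[keepers]
    } else {
      abort(paste("allele orientation unresolvable for SNPs:",
                  paste(head(weights$snp_id[unresolved], 10), collapse = ", ")))
    }
  }

  d <- panel$dosage[, idx, drop = FALSE]
  d[, flipped] <- 2 - d[, flipped, drop = FALSE]

  if (anyNA(d)) {
    # effect-allele frequency on the oriented dosages
    eaf <- colMeans(d, na.rm = TRUE) / 2
    miss <- which(is.na(d), arr.ind = TRUE)
    d[miss] <- 2 * eaf[miss[, 2]]
    inform(sprintf("compute_prs: %d missing dosage(s) imputed to 2 x allele frequency",
                   nrow(miss)))
  }

  beta <- weights[[bcol]]
  tibble::tibble(
    id = panel$sample_ids,
    endpoint = endpoint,
    prs = as.numeric(d %*% beta)
  )
}
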