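# Shared fixture builders and independent oracles used across test files.

# Small mixed-structure cohort: MZ pairs, DZ pairs, sister families.
make_cohort <- function(n_mz = 30, n_dz = 20, n_sibs = 40, seed = 42) {
  simulate_pedigrees(n_mz, n_dz, n_sibs, seed = seed)
}

# Cohort + genotypes + weights + density + MRS, ready for the pipeline.
make_run <- function(n_mz = 30, n_dz = 20, n_sibs = 40, n_snps = 30,
                     prs_effect = 0, seed = 42) {
  coh <- simulate_pedigrees(n_mz, n_dz, n_sibs, seed = seed)
  gp <- simulate_genotypes(coh, n_snps, seed = seed + 1)
  w <- simulate_weights(gp, seed = seed + 2)
  dens <- suppressMessages(simulate_density(
    coh, trait_model(prs_effect = prs_effect),
    panel = gp, weights = w, seed = seed + 3))
  mrs <- suppressMessages(add_mrs(dens))
  prs <- dplyr::bind_rows(
    compute_prs(gp, w, "overall"),
    compute_prs(gp, w, "ERneg"),
    compute_prs(gp, w, "ERpos"))
  pcs <- compute_pcs(gp, k = min(5, n_snps - 1))
  list(cohort = coh, panel = gp, weights = w, mrs = mrs, prs = prs, pcs = pcs)
}

# Within-pair Pearson correlation for a two-per-family trait vector laid
# out pair-by-pair.
pair_cor <- function(x) {
  m <- matrix(x, ncol = 2, byrow = TRUE)
  cor(m[, 1], m[, 2])
}

# --- independent oracles ---------------------------------------------------

# Exact HWE p-value by full closed-form enumeration (log-multinomial over
# heterozygote counts conditional on allele counts).
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_a <- 2 * n_hom_ref + n_het   # reference allele count
  hets <- seq(n_a %% 2, min(n_a, 2 * n - n_a), by = 2)
  logp <- vapply(hets, function(h) {
    hra <- (n_a - h) / 2          # ref homozygotes
    hrb <- n - h - hra            # alt homozygotes
    lgamma(n + 1) - lgamma(hra + 1) - lgamma(h + 1) - lgamma(hrb + 1) +
      h * log(2) +
      lgamma(n_a + 1) + lgamma(2 * n - n_a + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp)
  obs <- p[hets == n_het]
  sum(p[p <= obs * (1 + 1e-12)])
}

# PRS by explicit per-individual, per-SNP loop with allele flipping.
prs_loop_oracle <- function(panel, weights, beta_col) {
  idx <- match(weights$snp_id, panel$snp_meta$snp_id)
  out <- numeric(nrow(panel$dosage))
  for (j in seq_len(nrow(panel$dosage))) {
    s <- 0
    for (i in seq_along(idx)) {
      x <- panel$dosage[j, idx[i]]
      flip <- panel$snp_meta$effect_allele[idx[i]] != weights$effect_allele[i]
      if (flip) x <- 2 - x
      s <- s + weights[[beta_col]][i] * x
    }
    out[j] <- s
  }
  out
}

# OLS coefficients by the normal equations.
ols_oracle <- function(X, y) solve(crossprod(X), crossprod(X, y))
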