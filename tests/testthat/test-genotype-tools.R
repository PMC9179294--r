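test_that("compute_prs matches trivial cases and the loop oracle", {
  meta <- tibble::tibble(snp_id = c("a", "b"), chrom = "1", pos = c(1, 2),
                         effect_allele = c("A", "C"),
                         other_allele = c("G", "T"))
  d <- matrix(0, 3, 2, dimnames = list(c("s1", "s2", "s3"), c("a", "b")))
  w <- tibble::tibble(snp_id = c("a", "b"), effect_allele = c("A", "C"),
                      other_allele = c("G", "T"),
                      beta_overall = c(0.5, -0.2),
                      beta_erneg = 0, beta_erpos = 0)
  expect_equal(compute_prs(genotype_panel(d, meta), w, "overall")$prs,
               c(0, 0, 0))

  d[1, 1] <- 2
  expect_equal(compute_prs(genotype_panel(d, meta), w, "overall")$prs[1], 1.0)

  # random 313-SNP panel with flipped orientations: loop oracle to 1e-12
  coh <- make_cohort(20, 15, 30, seed = 51)
  gp <- simulate_genotypes(coh, 313, seed = 52)
  flip <- seq(1, 313, by = 3)
  wts <- simulate_weights(gp, seed = 53)
  wts$effect_allele[flip] <- gp$snp_meta$other_allele[flip]
  wts$other_allele[flip] <- gp$snp_meta$effect_allele[flip]
  got <- compute_prs(gp, wts, "overall")$prs
  expect_equal(got, prs_loop_oracle(gp, wts, "beta_overall"),
               tolerance = 1e-12)
})

test_that("compute_prs is linear in weights and flip-invariant up to 2*sum(beta)", {
  coh <- make_cohort(10, 10, 10, seed = 54)
  gp <- simulate_genotypes(coh, 40, seed = 55)
  w1 <- simulate_weights(gp, seed = 56)
  w2 <- simulate_weights(gp, seed = 57)
  w12 <- w1
  w12$beta_overall <- w1$beta_overall + w2$beta_overall
  expect_equal(compute_prs(gp, w12, "overall")$prs,
               compute_prs(gp, w1, "overall")$prs +
                 compute_prs(gp, w2, "overall")$prs,
               tolerance = 1e-12)

  # report the other allele as the effect allele and negate the weights:
  # PRS shifts by the constant -2*sum(beta) but is otherwise unchanged
  wf <- w1
  wf$effect_allele <- w1$other_allele
  wf$other_allele <- w1$effect_allele
  wf$beta_overall <- -w1$beta_overall
  expect_equal(compute_prs(gp, wf, "overall")$prs,
               compute_prs(gp, w1, "overall")$prs - 2 * sum(w1$beta_overall),
               tolerance = 1e-12)
})

test_that("compute_prs imputes missing dosages to 2*AF and errors on unknown SNPs", {
  coh <- make_cohort(10, 10, 10, seed = 58)
  gp <- simulate_genotypes(coh, 5, seed = 59)
  w <- simulate_weights(gp, seed = 60)
  gp$dosage[1, 2] <- NA
  eaf <- mean(gp$dosage[-1, 2]) / 2
  expect_message(out <- compute_prs(gp, w, "overall"), "imputed")
  manual <- sum(gp$dosage[1, -2] * w$beta_overall[-2]) +
    2 * eaf * w$beta_overall[2]
  expect_equal(out$prs[1], manual, tolerance = 1e-10)

  w_bad <- w
  w_bad$snp_id[1] <- "nope"
  expect_error(compute_prs(gp, w_bad, "overall"), "absent.*nope")
})

test_that("hwe_exact_test matches the enumeration oracle", {
  expect_equal(hwe_exact_test(100, 0, 0), 1.0)
  expect_equal(hwe_exact_test(25, 50, 25), hwe_oracle(25, 50, 25),
               tolerance = 1e-12)
  expect_lt(hwe_exact_test(0, 100, 0), 1e-7)
  # a grid of configurations against the oracle
  cases <- list(c(5, 5, 5), c(60, 30, 10), c(1, 10, 1), c(0, 3, 97),
                c(40, 20, 40), c(2, 0, 2))
  for (cs in cases) {
    expect_equal(hwe_exact_test(cs[1], cs[2], cs[3]),
                 hwe_oracle(cs[1], cs[2], cs[3]),
                 tolerance = 1e-12)
  }
})

test_that("hwe_exact_test p-values are asymptotically uniform under HWE", {
  set.seed(71)
  p_af <- 0.3
  probs <- c((1 - p_af)^2, 2 * p_af * (1 - p_af), p_af^2)
  ps <- replicate(300, {
    g <- as.vector(stats::rmultinom(1, 10000, probs))
    hwe_exact_test(g[1], g[2], g[3])
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("qc_filter removes what it should, in order, and is idempotent", {
  coh <- simulate_pedigrees(0, 0, 300, sib_family_sizes = 1, seed = 81)
  gp <- simulate_genotypes(coh, 60, maf_range = c(0.2, 0.5), seed = 82)

  clean <- qc_filter(gp)
  expect_equal(clean$report$counts, setNames(rep(0L, 5),
    c("sample_call_rate", "sample_heterozygosity", "snp_call_rate",
      "snp_hwe", "snp_maf")))
  expect_equal(dim(clean$panel$dosage), dim(gp$dosage))

  # null 10% of one SNP -> call-rate removal of that SNP only
  gp2 <- gp
  gp2$dosage[1:30, 5] <- NA
  res <- qc_filter(gp2)
  expect_equal(res$report$removed$snp_call_rate, "snp00005")
  expect_equal(ncol(res$panel$dosage), 59)

  # an all-heterozygous sample is a heterozygosity outlier and its SNPs
  # are filtered on the survivors only
  gp3 <- gp
  gp3$dosage[7, ] <- 1
  res3 <- qc_filter(gp3)
  expect_true(coh$id[7] %in% res3$report$removed$sample_heterozygosity)

  # idempotence
  again <- qc_filter(res$panel)
  expect_equal(sum(again$report$counts), 0L)

  # an all-heterozygote SNP is an extreme HWE violation
  gp4 <- gp
  gp4$dosage[, 3] <- 1
  res4 <- qc_filter(gp4)
  expect_true("snp00003" %in% res4$report$removed$snp_hwe)
})

test_that("qc_filter honors the weight-SNP MAF exemption", {
  coh <- simulate_pedigrees(0, 0, 400, sib_family_sizes = 1, seed = 83)
  gp <- simulate_genotypes(coh, 20, maf_range = c(0.2, 0.4), seed = 84)
  # force one SNP to be very rare
  gp$dosage[, 4] <- c(rep(1, 2), rep(0, 398))
  gp$snp_meta$maf[4] <- 0.0025
  dropped <- qc_filter(gp)
  expect_true("snp00004" %in% dropped$report$removed$snp_maf)
  kept <- suppressMessages(qc_filter(gp, exempt_snps = "snp00004"))
  expect_false("snp00004" %in% kept$report$removed$snp_maf)
  expect_equal(kept$report$n_maf_exempted, 1L)
})

test_that("compute_pcs matches a dense eigendecomposition oracle", {
  coh <- simulate_pedigrees(0, 0, 80, sib_family_sizes = 1, seed = 91)
  gp <- simulate_genotypes(coh, 50, seed = 92)
  k <- 6
  scores <- compute_pcs(gp, k = k)

  # oracle: eigendecomposition of the covariance of the standardized matrix
  Z <- scale(gp$dosage)
  ev <- eigen(crossprod(Z) / (nrow(Z) - 1), symmetric = TRUE)
  oracle <- Z %*% ev$vectors[, 1:k]
  for (j in 1:k) {
    expect_lt(min(max(abs(scores[, j] - oracle[, j])),
                  max(abs(scores[, j] + oracle[, j]))), 1e-8)
    expect_equal(attr(scores, "eigenvalues")[j], ev$values[j],
                 tolerance = 1e-8)
  }

  # zero mean, diagonal Gram matrix
  expect_true(all(abs(colMeans(scores)) < 1e-10))
  G <- crossprod(scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
})

test_that("compute_pcs degenerate and structured cases behave", {
  # all SNPs identical -> PC1 carries all the variance
  d <- matrix(rep(rbinom(40, 2, 0.4), 5), 40, 5)
  rownames(d) <- paste0("s", 1:40)
  meta <- tibble::tibble(snp_id = paste0("v", 1:5), chrom = "1", pos = 1:5,
                         effect_allele = "A", other_allele = "G")
  p1 <- compute_pcs(genotype_panel(d, meta), k = 2)
  ev <- attr(p1, "eigenvalues")
  expect_gt(ev[1] / 5, 0.999)  # proportion of total standardized variance

  # two subpopulations with shifted allele frequencies separate on PC1
  set.seed(93)
  n1 <- 60; n2 <- 60; m <- 80
  d2 <- rbind(
    matrix(rbinom(n1 * m, 2, 0.15), n1, m),
    matrix(rbinom(n2 * m, 2, 0.45), n2, m))
  rownames(d2) <- paste0("s", seq_len(n1 + n2))
  meta2 <- tibble::tibble(snp_id = paste0("v", 1:m), chrom = "1", pos = 1:m,
                          effect_allele = "A", other_allele = "G")
  pcs <- compute_pcs(genotype_panel(d2, meta2), k = 2)
  grp <- rep(c(0, 1), c(n1, n2))
  expect_gt(abs(cor(pcs[, 1], grp)), 0.9)

  expect_error(compute_pcs(genotype_panel(d2, meta2), k = 500), "smaller")
})
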