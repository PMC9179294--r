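test_that("build_covariance assembles the family/zygosity blocks", {
  coh <- simulate_pedigrees(1, 1, 3, sib_family_sizes = 3, seed = 141)

  # residual only -> diagonal blocks
  V0 <- build_covariance(coh, c(0, 0, 2))
  expect_true(all(vapply(V0, function(b) all(b == 2 * diag(nrow(b))),
                         logical(1))))

  # one MZ pair with components (1, 1, 1) -> [[3, 2], [2, 3]]
  V1 <- build_covariance(coh, c(1, 1, 1))
  mz_fam <- unique(coh$family_id[coh$zygosity == "MZ"])
  expect_equal(unname(V1[[mz_fam]]), matrix(c(3, 2, 2, 3), 2))
  # DZ co-twins share only the family intercept; the zygosity-group
  # variance still sits on their diagonal, keeping variances equal
  dz_fam <- unique(coh$family_id[coh$zygosity == "DZ"])
  expect_equal(unname(V1[[dz_fam]]), matrix(c(3, 1, 1, 3), 2))

  # random non-negative components -> every block PSD (eigen oracle)
  set.seed(142)
  for (i in 1:5) {
    comp <- runif(3, 0, 3)
    V <- build_covariance(coh, comp)
    mins <- vapply(V, function(b) min(eigen(b, symmetric = TRUE,
                                            only.values = TRUE)$values),
                   numeric(1))
    expect_true(all(mins >= -1e-12))
  }
  expect_error(build_covariance(coh, c(-1, 0, 1)), "non-negative")
})

test_that("fit_reml reduces to OLS on an all-singleton cohort", {
  set.seed(143)
  coh <- simulate_pedigrees(0, 0, 200, sib_family_sizes = 1, seed = 143)
  X <- cbind(`(Intercept)` = 1, x1 = rnorm(200), x2 = runif(200))
  y <- X %*% c(1, 0.5, -2) + rnorm(200)
  fit <- fit_reml(as.numeric(y), X, coh)

  lmfit <- lm(y ~ X - 1)
  expect_equal(fit$coefficients$estimate, unname(coef(lmfit)),
               tolerance = 1e-8)
  expect_equal(fit$coefficients$std.error,
               unname(sqrt(diag(vcov(lmfit)))), tolerance = 1e-8)
  expect_equal(unname(fit$varcomp[c("family", "mz_pair")]), c(0, 0))
  sig2 <- sum(resid(lmfit)^2) / (200 - 3)
  expect_equal(unname(fit$varcomp["residual"]), sig2, tolerance = 1e-6)
  # ML log-likelihood at the REML variance (OLS Gaussian log-likelihood
  # evaluated at the same sigma^2)
  ll <- -0.5 * (200 * log(2 * pi * sig2) + sum(resid(lmfit)^2) / sig2)
  expect_equal(fit$loglik_ml, ll, tolerance = 1e-6)
})

test_that("duplicated outcomes within MZ pairs drive the residual to zero", {
  coh <- simulate_pedigrees(200, 0, 0, seed = 144)
  set.seed(1440)
  y_pair <- rnorm(200)
  y <- rep(y_pair, each = 2)
  fit <- fit_reml(y, matrix(1, 400, 1, dimnames = list(NULL, "(Intercept)")),
                  coh)
  g <- glance(fit)
  expect_lt(g$var_residual / (g$var_family + g$var_mz_pair + g$var_residual),
            1e-6)
  expect_gt(g$icc_mz, 0.999)
})

test_that("fit_reml agrees with lme4 on a small mixed cohort", {
  coh <- simulate_pedigrees(40, 30, 60, seed = 145)
  dens <- suppressMessages(add_mrs(simulate_density(coh, trait_model(),
                                                    seed = 146)))
  X <- cbind(`(Intercept)` = 1, age = coh$age)
  fit <- fit_reml(dens$alto_mrs, X, coh)

  # reference model: family intercept plus a zygosity-group intercept
  # (MZ pair for co-twins, the individual otherwise)
  df <- data.frame(y = dens$alto_mrs, age = coh$age, fam = coh$family_id,
                   mz = ifelse(coh$zygosity == "MZ", coh$pair_id, coh$id))
  ref <- lme4::lmer(y ~ age + (1 | fam) + (1 | mz), data = df, REML = TRUE)
  sref <- summary(ref)$coefficients
  expect_equal(fit$coefficients$estimate, unname(sref[, "Estimate"]),
               tolerance = 1e-4)
  expect_equal(fit$coefficients$std.error, unname(sref[, "Std. Error"]),
               tolerance = 1e-4)
  expect_equal(fit$loglik_reml, as.numeric(logLik(ref)), tolerance = 1e-5)
  vc <- as.data.frame(lme4::VarCorr(ref))
  expect_equal(unname(fit$varcomp["family"]), vc$vcov[vc$grp == "fam"],
               tolerance = 1e-3)
  expect_equal(unname(fit$varcomp["mz_pair"]), vc$vcov[vc$grp == "mz"],
               tolerance = 1e-3)

  # REML criterion at the optimum beats a coarse grid over the components
  prep <- mammotwin:::.lmm_prepare(X, dens$alto_mrs,
                                   mammotwin:::.lmm_structure(coh))
  crit_opt <- mammotwin:::.lmm_neg2reml(prep, fit$varcomp, nrow(coh), 2)
  grid <- expand.grid(f = seq(0.05, 1, length.out = 8),
                      z = seq(0.05, 1, length.out = 8),
                      e = seq(0.05, 1, length.out = 8))
  crit_grid <- min(apply(grid, 1, function(g)
    mammotwin:::.lmm_neg2reml(prep, as.numeric(g), nrow(coh), 2)))
  expect_lte(crit_opt, crit_grid + 1e-6)
})

test_that("fit_reml is invariant to family ordering and shift-stable in BIC", {
  coh <- simulate_pedigrees(25, 20, 30, seed = 147)
  set.seed(1470)
  dens <- suppressMessages(add_mrs(simulate_density(coh, trait_model(),
                                                    seed = 148)))
  y <- dens$cumulus_mrs
  X <- cbind(`(Intercept)` = 1, x = rnorm(nrow(coh)))

  fit1 <- fit_reml(y, X, coh)
  perm <- sample(nrow(coh))
  fit2 <- fit_reml(y[perm], X[perm, ], coh[perm, ])
  expect_equal(fit1$coefficients$estimate, fit2$coefficients$estimate,
               tolerance = 1e-6)
  expect_equal(unname(fit1$varcomp), unname(fit2$varcomp), tolerance = 1e-5)

  # BIC differences between two fixed-effect specifications are invariant
  # to adding a constant to the outcome
  X2 <- cbind(X, x2 = rnorm(nrow(coh)))
  d1 <- fit_reml(y, X, coh)$bic - fit_reml(y, X2, coh)$bic
  d2 <- fit_reml(y + 100, X, coh)$bic - fit_reml(y + 100, X2, coh)$bic
  expect_equal(d1, d2, tolerance = 1e-4)

  expect_error(fit_reml(y, cbind(X, dup = X[, 2]), coh), "collinear")
})

test_that("opera_scale rescales per adjusted SD of the predictor", {
  coh <- simulate_pedigrees(0, 0, 500, sib_family_sizes = 1, seed = 151)
  set.seed(152)
  n <- 500
  z <- rnorm(n)                     # covariate
  x <- z + rnorm(n, 0, 0.5)         # predictor = covariate + noise(SD 0.5)
  y <- 0.3 * x + rnorm(n)
  X <- cbind(`(Intercept)` = 1, x = x, z = z)
  fit <- fit_reml(y, X, coh)

  op <- opera_scale(fit, x, covariates = z, term = "x")
  expect_equal(op$sd_adjusted, 0.5, tolerance = 0.05)
  expect_equal(op$estimate, op$estimate_raw * op$sd_adjusted)
  expect_equal(sign(op$estimate), sign(op$estimate_raw))

  # orthogonal unit-variance predictor: scaled == raw
  x2 <- as.numeric(scale(rnorm(n)))
  X2 <- cbind(`(Intercept)` = 1, x = x2)
  fit2 <- fit_reml(y, X2, coh)
  op2 <- opera_scale(fit2, x2, covariates = NULL, term = "x")
  expect_equal(op2$estimate, op2$estimate_raw * sd(x2))

  # doubling the predictor's units leaves the scaled coefficient unchanged
  X3 <- cbind(`(Intercept)` = 1, x = 2 * x, z = z)
  fit3 <- fit_reml(y, X3, coh)
  op3 <- opera_scale(fit3, 2 * x, covariates = z, term = "x")
  expect_equal(op3$estimate, op$estimate, tolerance = 1e-6)
  expect_equal(op3$p.value, op$p.value, tolerance = 1e-6)

  expect_error(opera_scale(fit, rep(1, n), covariates = NULL, term = "x"),
               "zero variance")
})

test_that("family_corr handles degenerate and null inputs", {
  coh <- make_cohort(30, 30, 30, seed = 161)
  x <- rnorm(nrow(coh))
  same <- family_corr(x, x, coh, n_boot = 200, seed = 1)
  expect_equal(same$estimate, 1)
  expect_equal(same$conf.low, 1)
  expect_equal(same$conf.high, 1)
  expect_equal(same$p.value, 0)

  expect_error(family_corr(rep(1, nrow(coh)), x, coh, n_boot = 200),
               "constant")
  expect_error(family_corr(x, x, coh, n_boot = 50), "at least 200")

  # independent inputs at the study's family structure: |r| < 0.04 in a
  # strong majority of replicates (naive SE ~ 0.02 at n = 2559)
  coh_big <- simulate_pedigrees(584, 318, 755, seed = 162)
  set.seed(163)
  rs <- replicate(60, cor(rnorm(2559), rnorm(2559)))
  expect_gte(mean(abs(rs) < 0.04), 0.85)
})

test_that("fit_family_lmm is a formula front end over fit_reml", {
  run <- make_run(seed = 171)
  dat <- dplyr::mutate(run$mrs,
                       prs_overall = run$prs$prs[run$prs$endpoint == "overall"])
  fit <- fit_family_lmm(dat, alto_mrs ~ prs_overall)
  X <- cbind(`(Intercept)` = 1, prs_overall = dat$prs_overall)
  ref <- fit_reml(dat$alto_mrs, X, dat)
  expect_equal(tidy(fit)$estimate, tidy(ref)$estimate, tolerance = 1e-8)
  expect_s3_class(glance(fit), "tbl_df")
})
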