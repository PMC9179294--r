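#' @name family_lmm
#' @title Variance-components mixed model for twin and sister families
#'
#' @description
#' The analysis model for a family-structured outcome \eqn{y} is
#' \deqn{y = X\beta + u_{family} + u_{MZ pair} + e,}
#' with independent random intercepts for family (variance
#' \eqn{\sigma^2_f}, shared by all family members) and for zygosity group
#' (variance \eqn{\sigma^2_z}; the group is the MZ pair for monozygotic
#' co-twins and the individual otherwise), plus residual
#' \eqn{\sigma^2_e}.  The marginal covariance is block-diagonal over
#' families; within a family,
#' \eqn{V_F = \sigma^2_f J + \sigma^2_z Z + \sigma^2_e I}, where `J` is the
#' all-ones matrix and `Z` is the zygosity-group indicator (identity plus
#' the MZ co-twin off-diagonals).  MZ covariance
#' (\eqn{\sigma^2_f + \sigma^2_z}) therefore exceeds DZ/sister covariance
#' (\eqn{\sigma^2_f}) while every individual keeps the same marginal
#' variance \eqn{\sigma^2_f + \sigma^2_z + \sigma^2_e} — the standard
#' twin-study coding (`(1|family) + (1|pair-or-individual)` in lme4
#' terms), under which the implied intraclass correlations are
#' \eqn{(\sigma^2_f + \sigma^2_z)/\sigma^2_{tot}} for MZ pairs and
#' \eqn{\sigma^2_f/\sigma^2_{tot}} for DZ and sister pairs.
#'
#' Variance components are estimated by restricted maximum likelihood
#' (REML) with log-parameterized components and a bounded quasi-Newton
#' optimizer; fixed effects follow by generalized least squares at the
#' optimum.  Because the covariance blocks take only a handful of distinct
#' patterns (MZ pair, DZ pair, sister families of each size), the
#' likelihood is evaluated pattern-wise, which keeps each evaluation cheap
#' even for thousands of families.
NULL

# Family/zygosity block structure of a cohort, grouped by pattern so each
# distinct within-family covariance matrix is built once per likelihood
# evaluation.
.lmm_structure <- function(cohort) {
  n <- nrow(cohort)
  fam <- cohort$family_id
  is_mz <- cohort$zygosity == "MZ" & !is.na(cohort$pair_id)
  mz_key <- ifelse(is_mz, paste0("z", cohort$pair_id), paste0("i", seq_len(n)))

  fam_split <- split(seq_len(n), fam)
  sig <- character(length(fam_split))
  ord <- vector("list", length(fam_split))
  for (f in seq_along(fam_split)) {
    idx <- fam_split[[f]]
    key <- mz_key[idx]
    # canonical order: MZ pairs first, pairs contiguous
    o <- order(match(key, unique(key)))
    idx <- idx[o]
    codes <- match(key[o], unique(key[o]))
    sig[f] <- paste(codes, collapse = ",")
    ord[[f]] <- idx
  }

  patterns <- lapply(split(seq_along(fam_split), sig), function(fs) {
    k <- length(ord[[fs[1]]])
    idx <- do.call(rbind, ord[fs])
    codes <- as.integer(strsplit(sig[fs[1]], ",")[[1]])
    # zygosity-group intercept: the group is the MZ pair for MZ co-twins
    # and the individual otherwise, so sigma^2_z sits on every diagonal
    # (marginal variances stay equal across zygosity) but is shared only
    # within MZ pairs
    Z <- outer(codes, codes, "==") * 1
    list(idx = idx, k = k, m = length(fs), Z = Z,
         J = matrix(1, k, k), I = diag(k))
  })
  list(patterns = patterns,
       n = n,
       n_families = length(fam_split),
       has_mz = any(is_mz),
       max_family = max(lengths(fam_split)))
}

#' Within-family covariance blocks
#'
#' Builds the marginal covariance matrix of every family implied by the
#' variance components: \eqn{V_F = \sigma^2_f J + \sigma^2_z Z +
#' \sigma^2_e I} with `Z` the zygosity-group indicator (see
#' [family_lmm]): identity on the diagonal, 1 between MZ co-twins.
#'
#' @param cohort Cohort tibble with `family_id`, `pair_id`, `zygosity`.
#' @param components Numeric vector `c(family, mz_pair, residual)` of
#'   non-negative variance components.
#' @return Named list of dense symmetric matrices, one per family, with
#'   member ids as dimnames.
#' @examples
#' coh <- simulate_pedigrees(1, 1, 0, seed = 1)
#' build_covariance(coh, c(1, 1, 1))
#' @export
build_covariance <- function(cohort, components) {
  if (length(components) != 3 || any(components < 0)) {
    abort("components must be 3 non-negative variances (family, mz_pair, residual)")
  }
  st <- .lmm_structure(cohort)
  out <- list()
  for (p in st$patterns) {
    V <- components[1] * p$J + components[2] * p$Z + components[3] * p$I
    for (r in seq_len(p$m)) {
      ids <- cohort$id[p$idx[r, ]]
      B <- V
      dimnames(B) <- list(ids, ids)
      out[[cohort$family_id[p$idx[r, 1]]]] <- B
    }
  }
  out[order(names(out))]
}

# Pattern-wise sufficient pieces for GLS: slices of X and y per member slot.
.lmm_prepare <- function(X, y, st) {
  lapply(st$patterns, function(p) {
    Xs <- lapply(seq_len(p$k), function(i) X[p$idx[, i], , drop = FALSE])
    ys <- matrix(y[p$idx], p$m, p$k)
    c(p, list(Xs = Xs, ys = ys))
  })
}

# Accumulate log|V|, X'V^-1 X, X'V^-1 y, y'V^-1 y over all families.
.lmm_quadratics <- function(prep, comp) {
  p_dim <- ncol(prep[[1]]$Xs[[1]])
  XtViX <- matrix(0, p_dim, p_dim)
  XtViy <- numeric(p_dim)
  ytViy <- 0
  logdetV <- 0
  for (p in prep) {
    V <- comp[1] * p$J + comp[2] * p$Z + comp[3] * p$I
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    Vinv <- chol2inv(R)
    logdetV <- logdetV + 2 * p$m * sum(log(diag(R)))
    for (i in seq_len(p$k)) {
      for (j in seq_len(p$k)) {
        w <- Vinv[i, j]
        if (w == 0) next
        XtViX <- XtViX + w * crossprod(p$Xs[[i]], p$Xs[[j]])
        XtViy <- XtViy + w * crossprod(p$Xs[[i]], p$ys[, j])
        ytViy <- ytViy + w * sum(p$ys[, i] * p$ys[, j])
      }
    }
  }
  list(XtViX = XtViX, XtViy = XtViy, ytViy = ytViy, logdetV = logdetV)
}

# -2 x restricted log-likelihood (up to no constant: the full constant is
# included so values are comparable across software conventions).
.lmm_neg2reml <- function(prep, comp, n, p_dim) {
  q <- .lmm_quadratics(prep, comp)
  if (is.null(q)) return(1e10)
  cx <- tryCatch(chol(q$XtViX), error = function(e) NULL)
  if (is.null(cx)) return(1e10)
  beta <- backsolve(cx, forwardsolve(t(cx), q$XtViy))
  rVr <- q$ytViy - sum(beta * q$XtViy)
  (n - p_dim) * log(2 * pi) + q$logdetV + 2 * sum(log(diag(cx))) + rVr
}

#' Fit the family/zygosity mixed model by REML
#'
#' Estimates the three variance components (family, MZ-pair, residual) by
#' restricted maximum likelihood and the fixed effects by generalized
#' least squares at the optimum.  Components are optimized on the log
#' scale (L-BFGS-B); a component with no information in the design (no MZ
#' pairs, or no multi-member families) is fixed at zero.  The maximum
#' log-likelihood (ML) is evaluated at the REML components and used for
#' the Bayesian Information Criterion, `BIC = -2 logLik_ML +
#' (p + 3) log(n)` with `n` the number of individuals.  Inference on fixed
#' effects is Wald with a normal reference.
#'
#' @param y Numeric outcome vector, complete.
#' @param X Fixed-effect design matrix (include the intercept), full
#'   column rank.
#' @param cohort Cohort tibble aligned row-wise with `y` (`family_id`,
#'   `pair_id`, `zygosity`).
#' @param conf_level Confidence level for Wald intervals.
#' @return An object of class `lmm_fit`; see [tidy.lmm_fit()] and
#'   [glance.lmm_fit()].
#' @examples
#' coh <- simulate_pedigrees(50, 50, 50, seed = 1)
#' dens <- add_mrs(simulate_density(coh, trait_model(), seed = 2))
#' X <- cbind(`(Intercept)` = 1, age = coh$age)
#' fit <- fit_reml(dens$alto_mrs, X, coh)
#' tidy(fit)
#' @export
fit_reml <- function(y, X, cohort, conf_level = 0.95) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (anyNA(y) || anyNA(X)) abort("y and X must be complete")
  if (length(y) != nrow(X) || length(y) != nrow(cohort)) {
    abort("y, X and cohort must have matching rows")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    abort(paste("X is rank deficient; collinear column(s):",
                paste(drop, collapse = ", ")))
  }
  n <- length(y)
  p_dim <- ncol(X)
  st <- .lmm_structure(cohort)
  prep <- .lmm_prepare(X, y, st)

  active <- c(family = st$max_family > 1, mz_pair = st$has_mz, residual = TRUE)
  vy <- var(y)
  if (vy == 0) vy <- 1
  init <- log(c(family = vy / 4, mz_pair = vy / 4, residual = vy / 2))
  lower <- log(vy) - 30
  upper <- log(vy) + 5

  to_comp <- function(par) {
    comp <- c(family = 0, mz_pair = 0, residual = 0)
    comp[active] <- exp(par)
    comp
  }
  obj <- function(par) .lmm_neg2reml(prep, to_comp(par), n, p_dim)

  n_par <- sum(active)
  ctl <- list(maxit = 500, factr = 1e2, ndeps = rep(1e-6, n_par))
  safe_lbfgs <- function(start) {
    tryCatch(optim(start, obj, method = "L-BFGS-B",
                   lower = lower, upper = upper, control = ctl),
             error = function(e) list(par = start, value = obj(start),
                                      convergence = 99L,
                                      counts = c(NA_integer_, NA_integer_)))
  }
  opt <- safe_lbfgs(init[active])
  if (opt$convergence != 0) {
    # multi-start from dispersed initial values
    for (s in list(init[active] + 1, init[active] - 2,
                   rep(log(vy / 3), n_par))) {
      o2 <- safe_lbfgs(s)
      if (o2$value < opt$value) opt <- o2
      if (o2$convergence == 0) break
    }
  }
  # derivative-free polish from the best point: guards against
  # quasi-Newton stalls and line-search failures on nearly-flat
  # directions of the profile surface.  The fit is accepted if either
  # stage reports convergence (on boundary-degenerate surfaces the
  # polish can exit with a degenerate simplex after improving the
  # criterion, which is not a failure of the quasi-Newton stage).
  converged <- opt$convergence == 0
  if (n_par > 1) {
    nm <- optim(opt$par, obj, method = "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-12))
    if (nm$value <= opt$value) {
      nm$par <- pmin(pmax(nm$par, lower), upper)
      nm$counts <- opt$counts
      converged <- converged || nm$convergence == 0
      opt <- nm
    }
  } else if (!converged) {
    o3 <- optim(opt$par, obj, method = "Brent",
                lower = lower, upper = upper)
    if (o3$value <= opt$value) opt <- o3
    converged <- o3$convergence == 0
  }
  if (!converged) {
    abort(sprintf("REML optimizer failed to converge (code %d, criterion %.6g)",
                  opt$convergence, opt$value))
  }

  comp <- to_comp(opt$par)
  # snap numerically-zero random-effect variances to exact zero; the
  # residual stays positive so every block remains positive definite
  comp[1:2][comp[1:2] < exp(lower) * 2] <- 0

  # exact polish along the overall-scale direction: for V = s V0 the REML
  # criterion is minimized at s = r'V0^-1 r / (n - p), in closed form
  q0 <- .lmm_quadratics(prep, comp)
  b0 <- solve(q0$XtViX, q0$XtViy)
  s_hat <- (q0$ytViy - sum(b0 * q0$XtViy)) / (n - p_dim)
  if (is.finite(s_hat) && s_hat > 0) comp <- comp * s_hat

  q <- .lmm_quadratics(prep, comp)
  XtViX_inv <- chol2inv(chol(q$XtViX))
  beta <- as.numeric(XtViX_inv %*% q$XtViy)
  rVr <- q$ytViy - sum(beta * q$XtViy)
  se <- sqrt(diag(XtViX_inv))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  stat <- beta / se
  coefs <- tibble::tibble(
    term = colnames(X),
    estimate = beta,
    std.error = se,
    statistic = stat,
    p.value = 2 * pnorm(-abs(stat)),
    conf.low = beta - zq * se,
    conf.high = beta + zq * se
  )

  loglik_reml <- -0.5 * ((n - p_dim) * log(2 * pi) + q$logdetV +
                           determinant(q$XtViX)$modulus[1] + rVr)
  loglik_ml <- -0.5 * (n * log(2 * pi) + q$logdetV + rVr)
  n_params <- p_dim + 3
  bic <- -2 * loglik_ml + n_params * log(n)

  structure(list(
    coefficients = coefs,
    varcomp = comp,
    loglik_reml = as.numeric(loglik_reml),
    loglik_ml = as.numeric(loglik_ml),
    bic = bic,
    n = n,
    n_families = st$n_families,
    n_params = n_params,
    conf_level = conf_level,
    convergence = list(code = opt$convergence, criterion = opt$value,
                       counts = opt$counts),
    y = y, X = X
  ), class = "lmm_fit")
}

#' Fit the family mixed model from a cohort tibble
#'
#' Formula front end to [fit_reml()]: builds the fixed-effect design with
#' [stats::model.matrix()] from columns of `data` (optionally binding in a
#' principal-component score matrix as `PC1..PCk`) and fits the
#' family/zygosity variance-components model.  Rows with missing values in
#' the model variables are dropped.
#'
#' @param data Cohort tibble carrying the outcome, predictors, and the
#'   pedigree columns `family_id`, `pair_id`, `zygosity`.
#' @param formula Model formula for the fixed effects, e.g.
#'   `alto_mrs ~ prs_overall + PC1 + PC2`.
#' @param pcs Optional matrix of principal-component scores (rows aligned
#'   with `data`); its columns become available to the formula.
#' @inheritParams fit_reml
#' @return An `lmm_fit`.
#' @export
fit_family_lmm <- function(data, formula, pcs = NULL, conf_level = 0.95) {
  if (!is.null(pcs)) {
    pcs <- as.matrix(pcs)
    data <- dplyr::bind_cols(data, tibble::as_tibble(pcs))
  }
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.pass)
  keep <- complete.cases(mf)
  if (any(!keep)) {
    inform(sprintf("fit_family_lmm: dropping %d incomplete row(s)", sum(!keep)))
  }
  mf <- mf[keep, , drop = FALSE]
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  fit_reml(y, X, data[keep, , drop = FALSE], conf_level = conf_level)
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> n = %d individuals in %d families\n",
              x$n, x$n_families))
  cat(sprintf("  variance components: family = %.4g, MZ pair = %.4g, residual = %.4g\n",
              x$varcomp[1], x$varcomp[2], x$varcomp[3]))
  cat(sprintf("  logLik (REML) = %.3f, logLik (ML) = %.3f, BIC = %.2f\n",
              x$loglik_reml, x$loglik_ml, x$bic))
  print(x$coefficients)
  invisible(x)
}

#' Tidy a family mixed-model fit
#'
#' @param x An `lmm_fit` from [fit_reml()].
#' @param ... Unused.
#' @return A tibble with one row per fixed effect: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`, `conf.low`, `conf.high`.
#' @method tidy lmm_fit
#' @export
tidy.lmm_fit <- function(x, ...) x$coefficients

#' One-row summary of a family mixed-model fit
#'
#' @param x An `lmm_fit`.
#' @param ... Unused.
#' @return A one-row tibble: variance components, implied MZ and DZ/sister
#'   intraclass correlations, log-likelihoods, `BIC`, `n`, `n_families`.
#' @method glance lmm_fit
#' @export
glance.lmm_fit <- function(x, ...) {
  tot <- sum(x$varcomp)
  tibble::tibble(
    var_family = x$varcomp[["family"]],
    var_mz_pair = x$varcomp[["mz_pair"]],
    var_residual = x$varcomp[["residual"]],
    icc_mz = (x$varcomp[["family"]] + x$varcomp[["mz_pair"]]) / tot,
    icc_dz_sib = x$varcomp[["family"]] / tot,
    logLik_reml = x$loglik_reml,
    logLik_ml = x$loglik_ml,
    BIC = x$bic,
    n = x$n,
    n_families = x$n_families
  )
}

#' Scale an association per adjusted standard deviation of the predictor
#'
#' Reporting convention for comparing predictors on a common footing: the
#' raw mixed-model coefficient is multiplied by the standard deviation of
#' the predictor's residuals after ordinary-least-squares adjustment for
#' the model covariates, giving the change in outcome per adjusted-SD
#' change of the predictor.  Confidence limits are scaled identically; the
#' p-value is unchanged (the Wald statistic is scale invariant).
#'
#' @param fit An `lmm_fit` containing `term` among its fixed effects.
#' @param predictor The predictor's values (the column of the design used
#'   for `term`).
#' @param covariates Matrix/data frame of the other covariates (an
#'   intercept is added); `NULL` adjusts for the mean only.
#' @param term Name of the predictor's fixed effect in `fit`; defaults to
#'   the first non-intercept term.
#' @return A one-row tibble: `term`, `estimate` (scaled), `conf.low`,
#'   `conf.high`, `p.value`, `sd_adjusted`, `estimate_raw`.
#' @export
opera_scale <- function(fit, predictor, covariates = NULL, term = NULL) {
  stopifnot(inherits(fit, "lmm_fit"))
  cf <- fit$coefficients
  if (is.null(term)) {
    term <- setdiff(cf$term, "(Intercept)")[1]
  }
  if (!term %in% cf$term) abort(sprintf("term `%s` not in fit", term))
  row <- cf[cf$term == term, ]
  cv <- if (is.null(covariates)) {
    matrix(1, length(predictor), 1)
  } else cbind(1, as.matrix(covariates))
  r <- resid(stats::lm.fit(cv, predictor))
  s <- sd(r)
  if (s < 1e-12 * max(1, abs(mean(predictor)))) {
    abort("residualized predictor has zero variance")
  }
  tibble::tibble(
    term = term,
    estimate = row$estimate * s,
    conf.low = row$conf.low * s,
    conf.high = row$conf.high * s,
    p.value = row$p.value,
    sd_adjusted = s,
    estimate_raw = row$estimate
  )
}
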