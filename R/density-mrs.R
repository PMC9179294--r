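#' Derive the composite density measures
#'
#' From the three nested dense areas and the total breast area, adds
#' percent density (`cumulus_percent = 100 * cumulus / total_area`) and the
#' "white but not bright" area (`cumulus_white = cumulus - altocumulus`).
#'
#' @param data A tibble with columns `cumulus`, `altocumulus`,
#'   `cirrocumulus`, `total_area` (cm^2).
#' @return `data` with `cumulus_percent` (%) and `cumulus_white` (cm^2)
#'   appended.
#' @examples
#' derive_measures(tibble::tibble(cumulus = 30, altocumulus = 12,
#'                                cirrocumulus = 2, total_area = 100))
#' @export
derive_measures <- function(data) {
  need <- c("cumulus", "altocumulus", "cirrocumulus", "total_area")
  miss <- setdiff(need, names(data))
  if (length(miss)) abort(paste("missing columns:", paste(miss, collapse = ", ")))
  bad <- which(data$altocumulus > data$cumulus |
                 data$cirrocumulus > data$altocumulus |
                 data$cumulus > data$total_area)
  if (length(bad)) {
    abort(sprintf("nesting violated (cirrocumulus <= altocumulus <= cumulus <= total_area) at row(s): %s",
                  paste(head(bad, 10), collapse = ", ")))
  }
  dplyr::mutate(data,
                cumulus_percent = 100 * .data$cumulus / .data$total_area,
                cumulus_white = .data$cumulus - .data$altocumulus)
}

#' Box-Cox power transformation
#'
#' `boxcox_transform()` applies the power transformation
#' \eqn{y^{(\lambda)} = (y^\lambda - 1)/\lambda} (natural log when
#' \eqn{\lambda = 0}).  `boxcox_select()` picks, by profile log-likelihood,
#' the power under which the transformed values are closest to Gaussian.
#' By default the search is restricted to the interpretable grid
#' \{-1, -1/2, 0, 1/3, 1/2, 1\} (reciprocal, inverse square root, log, cube
#' root, square root, identity) so that selected powers are reportable;
#' `continuous = TRUE` instead polishes the grid optimum to the continuous
#' maximum-likelihood value.
#'
#' Zeros are admitted by adding half the smallest positive value of the
#' column before transformation (`offset = NULL`, reported); negative
#' values are an error.
#'
#' @param values Positive numeric vector.
#' @param lambda Power.
#' @param lambda_grid Candidate powers.
#' @param offset Added to `values` before transformation; `NULL` means 0
#'   when all values are positive, else half the smallest positive value.
#' @param continuous Polish to the continuous maximum-likelihood power.
#' @return `boxcox_select()`: the selected power, with the applied offset
#'   and per-grid-point profile log-likelihoods as attributes.
#'   `boxcox_transform()`: the transformed vector.
#' @examples
#' z <- rnorm(500, 5)
#' boxcox_select(z^3)      # recovers the cube root
#' @export
boxcox_select <- function(values,
                          lambda_grid = c(-1, -1/2, 0, 1/3, 1/2, 1),
                          offset = NULL, continuous = FALSE) {
  if (length(lambda_grid) == 0) abort("empty lambda grid")
  if (any(values < 0, na.rm = TRUE)) abort("values must be non-negative")
  values <- values[!is.na(values)]
  if (length(unique(values)) < 3) abort("degenerate distribution")
  if (is.null(offset)) {
    offset <- if (any(values == 0)) min(values[values > 0]) / 2 else 0
  }
  y <- values + offset
  n <- length(y)
  slog <- sum(log(y))
  prof <- vapply(lambda_grid, function(l) {
    t <- boxcox_transform(y, l)
    -n / 2 * log(mean((t - mean(t))^2)) + (l - 1) * slog
  }, numeric(1))
  lambda <- lambda_grid[which.max(prof)]
  if (continuous) {
    opt <- optim(lambda, function(l) {
      t <- boxcox_transform(y, l)
      n / 2 * log(mean((t - mean(t))^2)) - (l - 1) * slog
    }, method = "Brent", lower = min(lambda_grid) - 1,
    upper = max(lambda_grid) + 1)
    lambda <- opt$par
  }
  structure(lambda, offset = offset,
            profile = setNames(prof, format(lambda_grid)))
}

#' @rdname boxcox_select
#' @export
boxcox_transform <- function(values, lambda, offset = 0) {
  y <- values + offset
  if (any(y <= 0, na.rm = TRUE)) abort("values + offset must be positive")
  if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
}

#' Convert a density measure into a mammogram risk score
#'
#' A mammogram risk score (MRS) is the standardized residual of a
#' Box-Cox-transformed density measure after linear adjustment for age and
#' the inverse of BMI: the transformed values are regressed by ordinary
#' least squares on an intercept, age (years) and 1/BMI, and the residuals
#' are divided by their sample standard deviation (denominator `n - 1`).
#'
#' @param values Raw density measure (cm^2 or %), positive.
#' @param age,bmi Covariates, same length as `values`; `bmi > 0`.
#' @param lambda Box-Cox power; `NULL` selects it with [boxcox_select()].
#' @param offset Offset for zeros, as in [boxcox_select()].
#' @return Numeric vector of standardized residuals (mean 0, SD 1), with
#'   the power, offset and adjustment coefficients attached as attributes
#'   `lambda`, `offset`, `coefficients`.
#' @export
compute_mrs <- function(values, age, bmi, lambda = NULL, offset = NULL) {
  stopifnot(length(values) == length(age), length(age) == length(bmi))
  if (length(values) < 4) abort("need at least 4 observations")
  if (any(bmi <= 0, na.rm = TRUE)) abort("bmi must be positive")
  if (is.null(lambda)) {
    lambda <- boxcox_select(values, offset = offset)
    offset <- attr(lambda, "offset")
  } else if (is.null(offset)) {
    offset <- if (any(values == 0, na.rm = TRUE)) {
      min(values[values > 0], na.rm = TRUE) / 2
    } else 0
  }
  t <- boxcox_transform(values, as.numeric(lambda), offset)
  fit <- lm(t ~ age + I(1 / bmi))
  r <- resid(fit)
  out <- as.numeric(r / sd(r))
  attributes(out) <- list(lambda = as.numeric(lambda), offset = offset,
                          coefficients = coef(fit))
  out
}

#' Add the five mammogram risk scores to a cohort table
#'
#' Computes, for each of the five density measures (Cumulus dense area,
#' percent density, Altocumulus, Cirrocumulus, Cumulus-white), its
#' mammogram risk score via [compute_mrs()] and appends the columns
#' `cumulus_mrs`, `percent_mrs`, `alto_mrs`, `cirro_mrs`, `white_mrs`.
#' Composite measures are derived first when absent.  Rows with missing
#' BMI (or age) are excluded from estimation and receive `NA` scores; a
#' message reports how many.
#'
#' @param data Cohort tibble with the raw density columns plus `age`, `bmi`.
#' @param lambda Named list/vector of fixed Box-Cox powers per measure
#'   (names among `cumulus`, `cumulus_percent`, `altocumulus`,
#'   `cirrocumulus`, `cumulus_white`); measures not named are selected by
#'   profile likelihood.
#' @return `data` with the five `*_mrs` columns appended and the fit
#'   metadata (selected powers, offsets, adjustment coefficients) attached
#'   as `attr(, "mrs_fit")`.
#' @examples
#' coh <- simulate_pedigrees(30, 30, 30, seed = 1)
#' dens <- simulate_density(coh, trait_model(), seed = 2)
#' mrs <- add_mrs(dens)
#' attr(mrs, "mrs_fit")$lambda
#' @export
add_mrs <- function(data, lambda = NULL) {
  if (!all(c("cumulus_percent", "cumulus_white") %in% names(data))) {
    data <- derive_measures(data)
  }
  measures <- c(cumulus = "cumulus_mrs", cumulus_percent = "percent_mrs",
                altocumulus = "alto_mrs", cirrocumulus = "cirro_mrs",
                cumulus_white = "white_mrs")
  ok <- complete.cases(data$age, data$bmi)
  if (any(!ok)) {
    inform(sprintf("add_mrs: %d row(s) with missing age/BMI excluded from MRS estimation",
                   sum(!ok)))
  }
  meta <- list(lambda = list(), offset = list(), coefficients = list())
  for (m in names(measures)) {
    lam <- if (!is.null(lambda) && m %in% names(lambda)) lambda[[m]] else NULL
    score <- rep(NA_real_, nrow(data))
    s <- compute_mrs(data[[m]][ok], data$age[ok], data$bmi[ok], lambda = lam)
    score[ok] <- s
    data[[measures[[m]]]] <- score
    meta$lambda[[m]] <- attr(s, "lambda")
    meta$offset[[m]] <- attr(s, "offset")
    meta$coefficients[[m]] <- attr(s, "coefficients")
  }
  attr(data, "mrs_fit") <- meta
  data
}

#' Serialize MRS fit metadata to JSON
#'
#' @param data Output of [add_mrs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mrs_fit <- function(data, path) {
  meta <- attr(data, "mrs_fit")
  if (is.null(meta)) abort("no mrs_fit attribute; run add_mrs() first")
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
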