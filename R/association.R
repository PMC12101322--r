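#' Nudge probabilities off the unit-interval boundaries
#'
#' Exact zeros become `epsilon` and exact ones become `1 - epsilon` so
#' that a power transform of the values is defined; interior values are
#' unchanged.
#'
#' @param values Numeric vector in `[0, 1]`.
#' @param epsilon Boundary correction (default `1e-6`).
#' @return Corrected vector.
#' @export
adjust_boundaries <- function(values, epsilon = 1e-6) {
  if (any(values < 0 | values > 1))
    stop("values outside [0, 1]")
  values[values == 0] <- epsilon
  values[values == 1] <- 1 - epsilon
  values
}

#' Box-Cox power transform
#'
#' `(v^lambda - 1) / lambda` for `lambda != 0`; `log(v)` at
#' `lambda = 0`.
#'
#' @param values Positive numeric vector.
#' @param lambda Transform exponent.
#' @return Transformed vector.
#' @export
boxcox_transform <- function(values, lambda) {
  if (any(values <= 0)) stop("Box-Cox requires strictly positive values")
  if (lambda == 0) log(values) else (values^lambda - 1) / lambda
}

# profile log-likelihood of the Box-Cox model at one or more lambdas:
# normal likelihood of the transformed data, profiled over mean and
# variance, plus the Jacobian term (lambda - 1) * sum(log v)
boxcox_loglik <- function(values, lambdas) {
  n <- length(values)
  slog <- sum(log(values))
  vapply(lambdas, function(l) {
    z <- boxcox_transform(values, l)
    s2 <- mean((z - mean(z))^2)
    -n / 2 * log(s2) + (l - 1) * slog
  }, numeric(1L))
}

#' Estimate the Box-Cox exponent by profile likelihood
#'
#' Maximizes the Box-Cox profile log-likelihood (normality of the
#' transformed values) over the search interval: a grid scan at step
#' `1e-3` locates the neighbourhood of the optimum, then golden-section
#' refinement narrows it to `1e-5`.
#'
#' @param values Positive numeric vector, `n >= 3`, not all equal.
#' @param interval Search interval for lambda (default `c(-2, 2)`).
#' @return Estimated lambda.
#' @export
estimate_lambda <- function(values, interval = c(-2, 2)) {
  if (length(values) < 3L) stop("need at least 3 values")
  if (any(values <= 0)) stop("Box-Cox requires strictly positive values")
  if (sd(values) == 0) stop("degenerate input: all values equal")
  grid <- seq(interval[1L], interval[2L], by = 1e-3)
  ll <- boxcox_loglik(values, grid)
  best <- grid[which.max(ll)]
  lo <- max(interval[1L], best - 1e-3)
  hi <- min(interval[2L], best + 1e-3)
  opt <- optimize(function(l) boxcox_loglik(values, l),
                  interval = c(lo, hi), maximum = TRUE, tol = 1e-5)
  opt$maximum
}

#' Second-degree polynomial regression with diagnostics
#'
#' Ordinary least squares of `y` on `(1, x, x^2)` with the overall
#' F-test against the intercept-only model and a per-observation
#' diagnostics table sufficient to draw the four standard regression
#' diagnostic plots (residuals vs fitted, normal quantile comparison,
#' scale-location, residuals vs leverage).
#'
#' A constant response is flagged (`degenerate = TRUE`, `r_squared = 0`,
#' `f_pvalue = NA`) rather than raised as an error.
#'
#' @param x,y Numeric vectors of equal length, `n > 3`; `x` must not be
#'   constant.
#' @return List of class `quad_fit`: `coefficients` (intercept, linear,
#'   quadratic), `r_squared`, `f_pvalue`, `n`, `degenerate`, and
#'   `diagnostics` (columns `fitted`, `residual`,
#'   `standardized_residual`, `leverage`, `cooks_distance`).
#' @export
fit_quadratic <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) <= 3L) stop("need more than 3 observations")
  if (sd(x) == 0) stop("rank deficiency: x is constant")
  fit <- lm(y ~ x + I(x^2))
  if (any(is.na(coef(fit)))) stop("rank-deficient quadratic fit")
  degenerate <- sd(y) == 0
  # summary.lm warns on exact interpolation; the fit itself is fine
  fsum <- suppressWarnings(summary(fit))
  rss <- sum(residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (degenerate) 0 else 1 - rss / tss
  fp <- if (degenerate) NA_real_ else {
    fstat <- fsum$fstatistic
    unname(pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE))
  }
  diag <- data.frame(
    fitted = fitted(fit),
    residual = residuals(fit),
    standardized_residual = if (degenerate) rep(0, length(y))
                            else rstandard(fit),
    leverage = hatvalues(fit),
    cooks_distance = if (degenerate) rep(0, length(y))
                     else cooks.distance(fit))
  rownames(diag) <- NULL
  structure(list(coefficients = setNames(unname(coef(fit)),
                                         c("intercept", "linear",
                                           "quadratic")),
                 r_squared = r2, f_pvalue = fp, n = length(y),
                 degenerate = degenerate, diagnostics = diag,
                 std_errors = setNames(
                   unname(fsum$coefficients[, "Std. Error"]),
                   c("intercept", "linear", "quadratic"))),
            class = "quad_fit")
}

#' @export
print.quad_fit <- function(x, ...) {
  cat(sprintf(
    "quadratic fit (n = %d): R^2 = %.3f, F-test p = %.3g\n",
    x$n, x$r_squared, x$f_pvalue))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Disorder-LLPS association analysis
#'
#' The full statistical pipeline linking intrinsic disorder to LLPS
#' propensity: the per-protein phase-separation probabilities are
#' boundary-corrected, Box-Cox transformed with an empirically
#' estimated (or fixed) exponent, and regressed on the mean PPIDR with
#' a second-degree polynomial.
#'
#' @param disorder A `disorder_summary` (its `summary$mean_ppidr` is the
#'   predictor).
#' @param llps Data frame with columns `protein_id`, `p_llps`.
#' @param epsilon Boundary correction passed to [adjust_boundaries()].
#' @param fixed_lambda Optional fixed Box-Cox exponent; when `NULL`
#'   (default) the exponent is estimated by profile likelihood.
#' @return List of class `association_fit`: `lambda`, plus all
#'   `quad_fit` fields, plus `protein_id` ordering of the diagnostics
#'   rows.
#' @export
run_association <- function(disorder, llps, epsilon = 1e-6,
                            fixed_lambda = NULL) {
  stopifnot(inherits(disorder, "disorder_summary"),
            all(c("protein_id", "p_llps") %in% names(llps)))
  dsum <- disorder$summary
  only_d <- setdiff(dsum$protein_id, llps$protein_id)
  only_l <- setdiff(llps$protein_id, dsum$protein_id)
  if (length(only_d) > 0L || length(only_l) > 0L)
    stop("protein sets differ; only in disorder summary: {",
         paste(only_d, collapse = ", "), "}; only in LLPS table: {",
         paste(only_l, collapse = ", "), "}")
  if (nrow(dsum) < 4L) stop("need at least 4 proteins")
  llps <- llps[match(dsum$protein_id, llps$protein_id), , drop = FALSE]
  x <- dsum$mean_ppidr
  v <- adjust_boundaries(llps$p_llps, epsilon)
  lambda <- fixed_lambda %||% estimate_lambda(v)
  y <- boxcox_transform(v, lambda)
  fit <- fit_quadratic(x, y)
  fit$lambda <- lambda
  fit$protein_id <- dsum$protein_id
  class(fit) <- c("association_fit", class(fit))
  fit
}

#' @export
print.association_fit <- function(x, ...) {
  cat(sprintf("disorder-LLPS association (n = %d): lambda = %.4f, R^2 = %.3f, F-test p = %.3g\n",
              x$n, x$lambda, x$r_squared, x$f_pvalue))
  invisible(x)
}
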