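test_that("boundary adjustment only moves exact 0 and 1", {
  expect_equal(adjust_boundaries(c(0, 0.5, 1)),
               c(1e-6, 0.5, 1 - 1e-6))
  expect_equal(adjust_boundaries(0.5), 0.5)
  expect_error(adjust_boundaries(c(0.2, 1.4)), "outside")
})

test_that("the Box-Cox transform matches its closed forms", {
  v <- c(0.5, 1, 2, 4)
  expect_equal(boxcox_transform(v, 1), v - 1)
  expect_equal(boxcox_transform(v, 0), log(v))
  expect_equal(boxcox_transform(4, 0.5), 2)
  expect_error(boxcox_transform(c(1, 0), 0.5), "positive")
  # strictly increasing in v for several lambdas
  for (l in c(-1, -0.5, 0, 0.5, 2)) {
    z <- boxcox_transform(sort(runif(50, 0.01, 5)), l)
    expect_true(all(diff(z) > 0))
  }
  # continuity at lambda -> 0
  v2 <- c(0.3, 1.7, 2.9)
  expect_equal(boxcox_transform(v2, 1e-8), log(v2), tolerance = 1e-6)
})

test_that("lambda estimation matches a dense-grid oracle and external reference", {
  set.seed(61)
  v <- inv_boxcox(rnorm(250, 2, 1), 0.06)
  est <- estimate_lambda(v)
  expect_equal(est, grid_lambda_oracle(v), tolerance = 2e-3)
  # cross-check against the canonical profile-likelihood implementation
  bc <- MASS::boxcox(v ~ 1, lambda = seq(-2, 2, by = 0.001), plotit = FALSE)
  expect_equal(est, bc$x[which.max(bc$y)], tolerance = 2e-3)
  expect_error(estimate_lambda(c(1, 2)), "at least 3")
  expect_error(estimate_lambda(rep(2, 10)), "degenerate")
  expect_error(estimate_lambda(c(-1, 1, 2)), "positive")
})

test_that("lambda recovery on inverse-transformed normal samples", {
  # lognormal data: lambda* = 0
  set.seed(67)
  est0 <- mean(vapply(1:40, function(i)
    estimate_lambda(exp(rnorm(250, 2, 1))), numeric(1)))
  expect_lt(abs(est0 - 0), 0.05)
  # planted lambda* = 0.06
  est06 <- mean(vapply(1:40, function(i) {
    z <- pmax(rnorm(250, 2, 1), (1e-3 - 1) / 0.06)
    estimate_lambda(inv_boxcox(z, 0.06))
  }, numeric(1)))
  expect_lt(abs(est06 - 0.06), 0.05)
  # already-normal positive data: optimum at least as good as lambda = 1
  set.seed(71)
  v <- rnorm(250, 10, 1)
  l <- estimate_lambda(v)
  ll <- function(lam) {
    z <- boxcox_transform(v, lam)
    -length(v) / 2 * log(mean((z - mean(z))^2)) + (lam - 1) * sum(log(v))
  }
  expect_gte(ll(l), ll(1) - 1e-9)
})

test_that("scaling the data shifts the profile but not the optimum", {
  set.seed(73)
  v <- exp(rnorm(200, 1, 0.8))
  expect_equal(estimate_lambda(v * exp(1)), estimate_lambda(v),
               tolerance = 1e-2)
})

test_that("the quadratic fit interpolates noise-free data exactly", {
  x <- 1:10
  y <- 1 + 2 * x + 3 * x^2
  fit <- fit_quadratic(x, y)
  expect_equal(unname(fit$coefficients), c(1, 2, 3), tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_false(fit$degenerate)

  # constant response: flagged, not an error
  fit0 <- fit_quadratic(x, rep(5, 10))
  expect_true(fit0$degenerate)
  expect_equal(fit0$r_squared, 0)
  expect_true(is.na(fit0$f_pvalue))

  expect_error(fit_quadratic(rep(1, 10), y), "constant")
  expect_error(fit_quadratic(1:3, 1:3), "more than 3")
})

test_that("fit diagnostics reconstruct R-squared and leverage identities", {
  set.seed(79)
  x <- runif(60, 0, 10)
  y <- 2 + 0.5 * x - 0.1 * x^2 + rnorm(60, 0, 0.5)
  fit <- fit_quadratic(x, y)
  d <- fit$diagnostics
  rss <- sum(d$residual^2)
  tss <- sum((y - mean(y))^2)
  expect_equal(fit$r_squared, 1 - rss / tss, tolerance = 1e-10)
  expect_true(all(d$leverage >= 0 & d$leverage <= 1))
  expect_equal(sum(d$leverage), 3, tolerance = 1e-8)  # p parameters
  expect_equal(d$fitted + d$residual, y, tolerance = 1e-10)
})

test_that("planted quadratic coefficients are recovered within 3 SE", {
  set.seed(83)
  n <- 250
  beta <- c(1.5, 0.8, -0.05)
  x <- runif(n, 0, 10)
  y <- beta[1] + beta[2] * x + beta[3] * x^2 + rnorm(n, 0, 1)
  fit <- fit_quadratic(x, y)
  expect_true(all(abs(fit$coefficients - beta) <= 3 * fit$std_errors))
  # population R^2 for this design, computed analytically:
  # var(f(X)) / (var(f(X)) + sigma^2) with X ~ U(0,10)
  fx_var <- var(beta[1] + beta[2] * x + beta[3] * x^2)
  pop_r2 <- fx_var / (fx_var + 1)
  expect_lt(abs(fit$r_squared - pop_r2), 0.08)
})

test_that("the association pipeline is deterministic and detects mismatches", {
  sim <- generate_proteome(synthetic_config(seed = 29, n_proteins = 60,
                                            length_range = c(60L, 150L)))
  ds <- summarize_disorder(sim$tracks, sim$proteins)
  a1 <- run_association(ds, sim$llps)
  a2 <- run_association(ds, sim$llps)
  expect_identical(a1$r_squared, a2$r_squared)
  expect_identical(a1$lambda, a2$lambda)
  expect_identical(a1$coefficients, a2$coefficients)

  bad <- sim$llps[-1, ]
  expect_error(run_association(ds, bad), "only in disorder summary")

  # fixed-lambda mode bypasses estimation
  af <- run_association(ds, sim$llps, fixed_lambda = 0.0606)
  expect_equal(af$lambda, 0.0606)
})

test_that("zero-coupling proteomes show no disorder-LLPS association", {
  sim <- generate_proteome(synthetic_config(seed = 37, n_proteins = 250,
                                            llps_coupling = c(0.5, 0, 0)))
  ds <- summarize_disorder(sim$tracks, sim$proteins)
  expect_lt(abs(cor(sim$truth$disorder_fraction, sim$llps$p_llps)), 0.15)
  a <- run_association(ds, sim$llps)
  expect_lt(a$r_squared, 0.05)
})
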