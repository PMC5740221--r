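test_that("the Legendre basis is orthonormal under the uniform measure", {
  # Gauss-Legendre-free check: dense trapezoid quadrature on [-1, 1]
  x <- seq(-1, 1, length.out = 20001)
  w <- rep(2 / (length(x) - 1), length(x)); w[c(1, length(x))] <- w[1] / 2
  L <- legendre_orthonormal(x, 5)
  G <- t(L) %*% (L * w) / 2  # uniform density 1/2
  expect_equal(unname(G), diag(6), tolerance = 1e-5)
})

test_that("a model inside the basis class is recovered exactly", {
  set.seed(1)
  cfg <- gpce_config(input_dimension = 1, input_low = -1, input_high = 1)
  x <- matrix(stats::runif(50, -1, 1), 50, 1)
  y <- 3 + 2 * sqrt(3) * x[, 1]  # 3 + 2 * L1(x), orthonormal L1
  fit <- fit_gpce(x, y, cfg)
  const <- which(rowSums(fit$multi) == 0)
  lin <- which(fit$multi[, 1] == 1)
  expect_equal(fit$coefficients[const], 3, tolerance = 1e-8)
  expect_equal(fit$coefficients[lin], 2, tolerance = 1e-8)
  expect_lte(fit$loo_error, 1e-10)
  # prediction matches the function at unseen points
  xn <- matrix(seq(-1, 1, length.out = 11), 11, 1)
  expect_equal(predict(fit, xn), 3 + 2 * sqrt(3) * xn[, 1],
               tolerance = 1e-8)
})

test_that("constant outputs produce the constant-only metamodel", {
  x <- matrix(stats::runif(40, 1, 149), 10, 4)
  fit <- fit_gpce(x, rep(7, 10), gpce_config())
  expect_equal(nrow(fit$multi), 1)
  expect_equal(fit$coefficients, 7)
  expect_equal(fit$loo_error, 0)
  s <- sobol_indices(fit)
  expect_true(s$degenerate)
  expect_equal(s$main_indices, rep(0, 4))
})

test_that("additive linear model yields analytic Sobol indices", {
  set.seed(2)
  cfg <- gpce_config(input_dimension = 4, input_low = -1, input_high = 1)
  z <- matrix(stats::runif(4 * 200, -1, 1), 200, 4)
  y <- z[, 1] + 2 * z[, 2] + 3 * z[, 3] + 4 * z[, 4]
  fit <- fit_gpce(z, y, cfg)
  s <- sobol_indices(fit)
  expect_equal(s$main_indices, oracle_additive_sobol(1:4), tolerance = 1e-6)
  expect_equal(sum(s$main_indices) + s$interaction_total, 1,
               tolerance = 1e-6)
  expect_equal(s$interaction_total, 0, tolerance = 1e-6)
})

test_that("pure interactions carry no main effect", {
  set.seed(3)
  cfg <- gpce_config(input_dimension = 2, input_low = -1, input_high = 1)
  z <- matrix(stats::runif(2 * 150, -1, 1), 150, 2)
  y <- z[, 1] * z[, 2]
  fit <- fit_gpce(z, y, cfg)
  expect_lte(fit$loo_error, 0.001)
  s <- sobol_indices(fit)
  expect_equal(s$main_indices, c(0, 0), tolerance = 1e-8)
  expect_equal(s$interaction_total, 1, tolerance = 1e-8)
  # a main-effect-only basis cannot explain the variance
  main_only <- plaqhet:::gpce_design(plaqhet:::map_to_unit(z, cfg),
                                     rbind(c(0, 0), c(1, 0), c(0, 1)))
  res <- stats::lm.fit(main_only, y)$residuals
  expect_gt(stats::var(res), 0.5 * stats::var(y))
  # metamodel fidelity on fresh points
  zt <- matrix(stats::runif(2e4, -1, 1), 1e4, 2)
  expect_lt(max(abs(predict(fit, zt) - zt[, 1] * zt[, 2])), 1e-7)
})

test_that("single-variable nonlinearity is fully attributed to it", {
  set.seed(4)
  cfg <- gpce_config(input_dimension = 4, input_low = -1, input_high = 1)
  z <- matrix(stats::runif(4 * 120, -1, 1), 120, 4)
  y <- z[, 1]^2
  s <- sobol_indices(fit_gpce(z, y, cfg))
  expect_equal(s$main_indices[1], 1, tolerance = 1e-8)
  expect_equal(s$main_indices[-1], rep(0, 3), tolerance = 1e-8)
})

test_that("LOO error is non-increasing along the accepted-term sequence", {
  set.seed(5)
  cfg <- gpce_config(input_dimension = 3, input_low = -1, input_high = 1)
  z <- matrix(stats::runif(3 * 150, -1, 1), 150, 3)
  y <- 1 + z[, 1] + 0.5 * z[, 2]^2 + 0.2 * z[, 1] * z[, 3] +
    0.01 * stats::rnorm(150)
  fit <- fit_gpce(z, y, cfg)
  expect_true(all(diff(fit$loo_trace) <= 1e-12))
  s <- sobol_indices(fit)
  expect_equal(sum(s$main_indices) + s$interaction_total, 1,
               tolerance = 1e-6)
  expect_true(all(s$main_indices >= 0 & s$main_indices <= 1))
})

test_that("variation in a single cluster modulus is attributed to it", {
  set.seed(6)
  n <- 60
  x <- matrix(75, n, 4)
  x[, 2] <- stats::runif(n, 1, 149)
  y <- 10 + 0.5 * x[, 2] + 1e-4 * x[, 2]^2
  s <- sobol_indices(fit_gpce(x, y, gpce_config()))
  expect_gte(s$main_indices[2], 0.99)
})

test_that("gPCE input validation works", {
  cfg <- gpce_config()
  expect_error(fit_gpce(matrix(200, 5, 4), stats::rnorm(5), cfg), "bounds")
  expect_error(fit_gpce(matrix(75, 5, 4), stats::rnorm(6), cfg), "mismatch")
})
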