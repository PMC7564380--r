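test_that("least squares recovers coefficients exactly on residual-free data", {
  B <- matrix(c(0.5, 0.2, -0.1, 0.3), 2, 2)
  y <- matrix(0, 2, 300)
  y[, 1] <- c(1, -1)
  for (t in 2:300) y[, t] <- B %*% y[, t - 1]
  fit <- fit_var(y, 1)
  expect_lt(max(abs(fit$model$coeffs[[1]] - B)), 1e-10)
  expect_lt(max(abs(fit$residuals)), 1e-10)
})

test_that("least squares is consistent on a univariate AR(1)", {
  # Monte-Carlo check of the example frozen from the asymptotic oracle:
  # sd(a_hat) ~ sqrt((1 - a^2)/N) ~ 0.006 at a = 0.8, N = 1e4
  m <- var_model(matrix(0.8), matrix(1))
  errs <- vapply(1:20, function(s) {
    tr <- simulate_var(m, 1e4, seed = s)
    abs(fit_var(tr, 1)$model$coeffs[[1]][1, 1] - 0.8)
  }, numeric(1))
  expect_true(all(errs < 0.02))
})

test_that("white-noise VAR coefficients stay within the asymptotic null band", {
  # each of the 25 coefficients is ~ N(0, 1/N) under the null, so ~99.7%
  # of entries fall inside the 3/sqrt(N) band
  inside <- vapply(1:100, function(s) {
    set.seed(s)
    y <- matrix(rnorm(5 * 1000), 5)
    mean(abs(fit_var(y, 1)$model$coeffs[[1]]) < 3 / sqrt(1000))
  }, numeric(1))
  expect_gte(mean(inside), 0.99)
})

test_that("fit_var validates its inputs", {
  expect_error(fit_var(matrix(rnorm(6), 2, 3), 1), "too few samples")
  y <- matrix(rnorm(200), 2)
  y[2, ] <- y[1, ]                       # collinear channels
  expect_error(fit_var(y, 1), "singular lag design")
})

test_that("SBC recovers the generative order and degenerates to p_min on noise", {
  m2 <- build_condition_model(2)
  hits <- vapply(1:25, function(s) {
    sel <- select_order(simulate_var(m2, 1000, seed = s), 1, 5)
    expect_true(all(is.finite(sel$sbc)))
    expect_equal(unname(sel$sbc[as.character(sel$p_opt)]), min(sel$sbc))
    sel$p_opt == 2L
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  ar1 <- var_model(matrix(0.9), matrix(1))
  hits1 <- vapply(1:25, function(s)
    select_order(simulate_var(ar1, 2000, seed = s), 1, 4)$p_opt == 1L,
    logical(1))
  expect_gte(mean(hits1), 0.9)

  set.seed(7)
  expect_identical(select_order(matrix(rnorm(3 * 2000), 3), 1, 4)$p_opt, 1L)
})

test_that("Li-McLeod test is calibrated under the null and detects color", {
  set.seed(11)
  pv <- replicate(500, licmcleod_whiteness(matrix(rnorm(5 * 1000), 5),
                                           p_fitted = 0, h = 20)$p_value)
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.02)
  expect_lt(suppressWarnings(
    stats::ks.test(pv, "punif")$statistic), 0.1)

  ar <- var_model(matrix(0.9), matrix(1))
  colored <- simulate_var(ar, 1000, seed = 1)$data
  expect_lt(licmcleod_whiteness(colored, 0, 20)$p_value, 0.05)
})

test_that("residuals of a correctly specified fit pass the whiteness test", {
  m2 <- build_condition_model(2)
  white <- vapply(1:20, function(s) {
    fit <- fit_var(simulate_var(m2, 1000, seed = 100 + s,
                                innovation = "power_supergaussian"), 2)
    licmcleod_whiteness(fit$residuals, 2, 20)$is_white
  }, logical(1))
  expect_gte(mean(white), 0.9)
})

test_that("simulate_var passes white noise through and honors the seed", {
  m0 <- var_model(matrix(0, 2, 2), diag(2))
  tr <- simulate_var(m0, 10000, seed = 5)
  expect_lt(max(abs(tcrossprod(tr$data) / 10000 - diag(2))), 0.1)
  tr2 <- simulate_var(m0, 10000, seed = 5)
  expect_identical(tr$data, tr2$data)
  unstable <- var_model(matrix(1.05), matrix(1))
  expect_error(simulate_var(unstable, 100, seed = 1), "unstable")
})

test_that("super-Gaussian innovations have positive excess kurtosis", {
  m0 <- var_model(matrix(0, 1, 1), matrix(1))
  kur <- vapply(1:20, function(s) {
    x <- simulate_var(m0, 5000, innovation = "power_supergaussian", g = 2,
                      seed = s)$data
    mean(x^4) / mean(x^2)^2 - 3
  }, numeric(1))
  expect_true(all(kur > 0))
  # analytic variance rescaling keeps unit variance
  x <- simulate_var(m0, 2e4, innovation = "power_supergaussian", g = 1.5,
                    seed = 3)$data
  expect_lt(abs(mean(x^2) - 1), 0.1)
})

test_that("oscillator design places the spectral peak at the target frequency", {
  expect_equal(design_oscillator(10, 125, 0.9),
               c(2 * 0.9 * cos(2 * pi * 10 / 125), -0.81), tolerance = 1e-12)
  expect_equal(design_oscillator(20, 100, 0), c(0, 0))
  expect_error(design_oscillator(80, 125, 0.9), "f_center")

  b <- design_oscillator(10, 125, 0.9)
  m <- var_model(list(matrix(b[1]), matrix(b[2])), matrix(1))
  x <- simulate_var(m, 8192, seed = 2, fs = 125)$data[1, ]
  expect_lt(abs(periodogram_peak(x, 125) - 10), 1)
})

test_that("simulate_var then fit_var round-trips the condition-2 model", {
  m2 <- build_condition_model(2)
  fit <- fit_var(simulate_var(m2, 1e4, innovation = "gaussian", seed = 9), 2)
  err <- max(abs(fit$model$coeffs[[1]] - m2$coeffs[[1]]),
             abs(fit$model$coeffs[[2]] - m2$coeffs[[2]]))
  expect_lt(err, 0.05)
})
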