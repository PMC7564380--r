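test_that("lag covariances match the AR(1) closed form", {
  # Gamma_k = a^k sigma^2 / (1 - a^2)
  g <- yule_walker_inverse(var_model(matrix(0.5), matrix(1)), qmax = 4)
  expect_equal(as.numeric(g$gammas[[1]]), 4 / 3, tolerance = 1e-10)
  expect_equal(as.numeric(g$gammas[[2]]), 2 / 3, tolerance = 1e-10)
  expect_equal(as.numeric(g$gammas[[3]]), 1 / 3, tolerance = 1e-10)
})

test_that("a white process has Gamma_0 = innovation covariance and zero lags", {
  Sig <- diag(c(1, 2, 0.5))
  g <- yule_walker_inverse(var_model(matrix(0, 3, 3), Sig), qmax = 3)
  expect_equal(g$gammas[[1]], Sig, tolerance = 1e-12)
  for (k in 2:4) expect_lt(max(abs(g$gammas[[k]])), 1e-12)
  expect_error(yule_walker_inverse(var_model(matrix(1.01), matrix(1))),
               "unstable")
})

test_that("analytic lag covariances match long-run sample autocovariances", {
  m2 <- build_condition_model(2)
  g <- yule_walker_inverse(m2, qmax = 5)
  x <- simulate_var(m2, 2e5, innovation = "gaussian", seed = 13)$data
  n <- ncol(x)
  for (k in 0:5) {
    emp <- tcrossprod(x[, (k + 1):n], x[, 1:(n - k)]) / (n - k)
    rel <- norm(emp - g$gammas[[k + 1]], "F") / norm(g$gammas[[k + 1]], "F")
    expect_lt(rel, 0.02)
  }
})

test_that("partial variances behave as prediction-error variances", {
  # white target: own past carries nothing
  gw <- yule_walker_inverse(var_model(matrix(0, 2, 2), diag(2)), qmax = 5)
  expect_equal(partial_variance(1, 1, gw, 5), 1, tolerance = 1e-10)
  # AR(1): own past reduces variance exactly to the innovation variance
  g1 <- yule_walker_inverse(var_model(matrix(0.5), matrix(1)), qmax = 5)
  expect_equal(partial_variance(1, 1, g1, 5), 1, tolerance = 1e-10)
  expect_equal(partial_variance(1, integer(0), g1, 5), 4 / 3,
               tolerance = 1e-10)
})

test_that("adding regressors never increases the partial variance", {
  set.seed(21)
  for (rep in 1:10) {
    repeat {
      B <- matrix(rnorm(16, sd = 0.25), 4)
      m <- var_model(B, crossprod(matrix(rnorm(16), 4)) / 4 + diag(4))
      if (m$stable) break
    }
    g <- yule_walker_inverse(m, qmax = 6)
    j <- sample(4, 1)
    sets <- list(j, c(j, sample(setdiff(1:4, j), 1)), 1:4)
    pvs <- vapply(sets, function(v) partial_variance(j, v, g, 6), numeric(1))
    expect_true(all(diff(pvs) <= 1e-10))
  }
})

test_that("information measures hit the AR(1) closed form and detect isolation", {
  m <- var_model(matrix(0.5), matrix(1))
  im <- information_measures(m, q = 10)
  expect_equal(im$storage, 0.5 * log(4 / 3), tolerance = 1e-10)
  expect_identical(im$total_transfer, 0)
  # zero-coefficient AR(1) stores nothing
  im0 <- information_measures(var_model(matrix(0), matrix(1)), q = 5)
  expect_equal(im0$storage, 0, tolerance = 1e-10)
})

test_that("uncoupled sources show zero transfer, the chain shows positive", {
  t1 <- theoretical_measures(1)
  expect_lt(max(t1$total_transfer), 1e-8)
  expect_lt(max(t1$cond_transfer, na.rm = TRUE), 1e-8)
  t2 <- theoretical_measures(2)
  chain <- t2$cond_transfer[cbind(1:4, 2:5)]
  expect_true(all(chain > 0.01))
  off <- t2$cond_transfer
  off[cbind(1:4, 2:5)] <- NA
  expect_lt(max(off, na.rm = TRUE), 1e-6)
  # total transfer dominates the best single-driver conditional transfer
  for (j in 1:5)
    expect_gte(t2$total_transfer[j],
               max(t2$cond_transfer[, j], na.rm = TRUE) - 1e-8)
})

test_that("information measures are invariant to positive rescaling", {
  m2 <- build_condition_model(2)
  D <- diag(c(2, 0.5, 3, 1, 10))
  resc <- var_model(lapply(m2$coeffs, function(B) D %*% B %*% solve(D)),
                    D %*% m2$innovation_cov %*% D)
  a <- information_measures(m2, q = 8)
  b <- information_measures(resc, q = 8)
  expect_equal(a$storage, b$storage, tolerance = 1e-10)
  expect_equal(a$total_transfer, b$total_transfer, tolerance = 1e-10)
  expect_equal(a$cond_transfer, b$cond_transfer, tolerance = 1e-10)
})

test_that("storage from true parameters is monotone in the sub-model lag", {
  m2 <- build_condition_model(2)
  s <- sapply(c(2, 4, 6, 8, 10), function(q)
    information_measures(m2, q = q)$storage)
  expect_true(all(apply(s, 1, function(r) all(diff(r) >= -1e-10))))
})

test_that("F-tested links require effective_N and count off-diagonal hits", {
  m2 <- build_condition_model(2)
  tr <- simulate_var(m2, 2000, seed = 3)
  fit <- fit_var(tr, 2)
  im <- information_measures(fit$model, q = 10, effective_N = 1998)
  expect_identical(im$n_links, sum(im$significant, na.rm = TRUE))
  expect_true(all(is.na(diag(im$significant))))
  expect_error(information_measures(fit$model, q = 10, effective_N = 40),
               "effective_N")
})

test_that("network summary averages nodes and ordered pairs", {
  ct <- matrix(NA_real_, 2, 2); ct[1, 2] <- 0.2; ct[2, 1] <- 0.4
  fake <- structure(list(storage = c(0.1, 0.3), total_transfer = c(0, 0.2),
                         cond_transfer = ct, n_links = 1L),
                    class = "info_measures")
  ns <- network_summary(fake)
  expect_equal(ns$mean_storage, 0.2)
  expect_equal(ns$mean_cond_transfer, 0.3)
  expect_identical(ns$n_links, 1L)
  # permutation invariance of the summaries
  pm <- c(2, 1)
  fake2 <- fake
  fake2$storage <- fake$storage[pm]
  fake2$total_transfer <- fake$total_transfer[pm]
  fake2$cond_transfer <- fake$cond_transfer[pm, pm]
  expect_equal(network_summary(fake2), ns)
})
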