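make_dataset <- function(trials1, trials2, fs = 125) {
  mk <- function(x, lbl, i) eeg_trial(x, fs, lbl, sprintf("%s_%d", lbl, i))
  eeg_dataset(c(mapply(mk, trials1, "h1", seq_along(trials1),
                       SIMPLIFY = FALSE),
                mapply(mk, trials2, "h2", seq_along(trials2),
                       SIMPLIFY = FALSE)))
}

test_that("class covariances are trace-normalized averages", {
  # orthogonal equal-power channels -> diag(1/D)
  n <- 400
  x <- rbind(sin(2 * pi * (1:n) / 8), cos(2 * pi * (1:n) / 8))
  ds <- make_dataset(list(x, x), list(x))
  P <- class_covariances(ds)
  expect_lt(max(abs(P$h1 - diag(2) / 2)), 0.02)
  # identical trials average to the single-trial value
  P1 <- class_covariances(make_dataset(list(x), list(x)))
  expect_equal(P$h1, P1$h1, tolerance = 1e-12)
  # unit trace to high precision on random trials
  set.seed(4)
  ds2 <- make_dataset(list(matrix(rnorm(5000), 5)),
                      list(matrix(rnorm(5000), 5)))
  P2 <- class_covariances(ds2)
  expect_lt(abs(sum(diag(P2$h1)) - 1), 1e-12)
  expect_lt(abs(sum(diag(P2$h2)) - 1), 1e-12)
})

test_that("zero-variance trials are rejected by name", {
  z <- matrix(0, 2, 50)
  x <- matrix(rnorm(100), 2)
  expect_error(class_covariances(make_dataset(list(z), list(x))), "h1_1")
})

test_that("generalized eigenvalues solve the hand-built diagonal example", {
  fs <- csp_filters(diag(c(2 / 3, 1 / 3)), diag(c(1 / 3, 2 / 3)))
  expect_equal(fs$eigenvalues, c(2 / 3, 1 / 3), tolerance = 1e-6)
  expect_equal(fs$fractional_distances, c(0.5, 0.5), tolerance = 1e-6)
})

test_that("identical classes give all eigenvalues 1/2 and no distance", {
  set.seed(1)
  A <- crossprod(matrix(rnorm(16), 4)); A <- A / sum(diag(A))
  expect_error(csp_filters(A, A), "degenerate")
})

test_that("CSP filters jointly diagonalize both class covariances", {
  set.seed(2)
  P1 <- crossprod(matrix(rnorm(25), 5)); P1 <- P1 / sum(diag(P1))
  P2 <- crossprod(matrix(rnorm(25), 5)); P2 <- P2 / sum(diag(P2))
  fs <- csp_filters(P1, P2, ridge = 0)
  D1 <- fs$full_filters %*% P1 %*% t(fs$full_filters)
  D2 <- fs$full_filters %*% P2 %*% t(fs$full_filters)
  expect_lt(max(abs(D1 - diag(diag(D1)))), 1e-8)
  expect_lt(max(abs(D2 - diag(diag(D2)))), 1e-8)
  expect_true(all(fs$eigenvalues >= 0 & fs$eigenvalues <= 1))
})

test_that("class swap maps eigenvalues to their complement, distances unchanged", {
  set.seed(3)
  P1 <- crossprod(matrix(rnorm(16), 4)); P1 <- P1 / sum(diag(P1))
  P2 <- crossprod(matrix(rnorm(16), 4)); P2 <- P2 / sum(diag(P2))
  a <- csp_filters(P1, P2, ridge = 0)
  b <- csp_filters(P2, P1, ridge = 0)
  expect_equal(sort(a$eigenvalues), sort(1 - b$eigenvalues),
               tolerance = 1e-6)
  expect_equal(sort(a$fractional_distances),
               sort(b$fractional_distances), tolerance = 1e-6)
})

test_that("fractional distances normalize, permute and flag degeneracy", {
  lam <- c(0.9, 0.7, 0.4, 0.2)
  d <- fractional_distances(lam)
  expect_equal(sum(d$delta), 1, tolerance = 1e-10)
  expect_true(all(d$delta >= 0))
  perm <- c(3, 1, 4, 2)
  expect_equal(fractional_distances(lam[perm])$delta, d$delta[perm])
  expect_equal(fractional_distances(c(0.9, 0.5))$delta, c(1, 0),
               tolerance = 1e-12)
  expect_error(fractional_distances(c(0.5, 0.5)), "degenerate")
})

fake_filterset <- function(delta) {
  d <- length(delta)
  lam <- 1 / (1 + exp(-sqrt(delta * 10)))   # arbitrary, unused by selection
  structure(list(full_filters = diag(d), eigenvalues = lam,
                 fractional_distances = delta, total_distance = 1,
                 selected = seq_len(d), pruned_filter = diag(d)),
            class = "spatial_filter_set")
}

test_that("filter selection accumulates sorted distances to the coverage", {
  fs <- fake_filterset(c(0.5, 0.3, 0.15, 0.05))
  expect_length(select_filters(fs, 0.9)$selected, 3L)
  expect_length(select_filters(fs, 1.0)$selected, 4L)
  # unsorted deltas are sorted before accumulation
  fs2 <- fake_filterset(c(0.05, 0.5, 0.3, 0.15))
  sel <- select_filters(fs2, 0.8)$selected
  expect_identical(sel, c(2L, 3L))
  # monotone in coverage
  qs <- vapply(seq(0.1, 1, by = 0.1), function(cv)
    length(select_filters(fs, cv)$selected), integer(1))
  expect_true(all(diff(qs) >= 0))
})

test_that("apply_filters performs the linear spatial transform", {
  x <- matrix(rnorm(40), 4)
  expect_equal(apply_filters(diag(4), x), x)
  expect_equal(as.numeric(apply_filters(matrix(1, 1, 4), x)), colSums(x))
  expect_error(apply_filters(diag(3), x), "mismatch")
  tr <- eeg_trial(x, 125, "h1", "t1")
  out <- apply_filters(matrix(1, 1, 4), tr)
  expect_s3_class(out, "eeg_trial")
  expect_identical(out$class_label, "h1")
  expect_identical(out$fs, 125)
})

test_that("the top-distance filter recovers a variance-contrast direction", {
  # two classes differing only in the variance of one latent direction
  set.seed(8)
  d <- 4; n <- 1e4
  dir <- c(1, -1, 2, 0.5); dir <- dir / sqrt(sum(dir^2))
  base <- qr.Q(qr(cbind(dir, matrix(rnorm(d * (d - 1)), d))))
  mk <- function(boost) {
    lat <- matrix(rnorm(d * n), d)
    lat[1, ] <- lat[1, ] * boost
    base %*% lat
  }
  # boost factor 2: under trace normalization a factor-3 boost makes the
  # boosted and unboosted eigenvalues equidistant in the squared-log metric
  ds <- make_dataset(list(mk(2), mk(2)), list(mk(1), mk(1)))
  P <- class_covariances(ds)
  fs <- select_filters(csp_filters(P$h1, P$h2), coverage = 0.5)
  # the dominant filter's pattern (column of the inverse transform) aligns
  # with the boosted direction
  pat <- solve(fs$full_filters)[, fs$selected[1]]
  cosang <- abs(sum(pat * dir)) / sqrt(sum(pat^2))
  expect_gt(cosang, 0.99)
})
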