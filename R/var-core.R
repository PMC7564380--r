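#' Construct a vector autoregressive (VAR) model
#'
#' A VAR(p) model for a Q-dimensional process \eqn{s_n = \sum_{k=1}^p B_k
#' s_{n-k} + e_n}, with lag-coefficient matrices \eqn{B_k} (entry (j, i) of
#' \eqn{B_k} is the effect of variable i at lag k on variable j) and
#' innovation covariance \eqn{\Sigma_e}.
#'
#' @param coeffs List of p square QxQ coefficient matrices, or a single
#'   matrix for p = 1 (a 1x1 matrix or scalar gives a univariate AR).
#' @param innovation_cov QxQ symmetric positive-semidefinite innovation
#'   covariance; defaults to the identity.
#' @return An object of class `var_model` with elements `coeffs`,
#'   `innovation_cov`, `order`, `n_vars`, `stable` (logical) and
#'   `spectral_radius` of the companion matrix.
#' @export
var_model <- function(coeffs, innovation_cov = NULL) {
  if (is.matrix(coeffs) || length(coeffs) == 1L && !is.list(coeffs))
    coeffs <- list(as.matrix(coeffs))
  coeffs <- lapply(coeffs, as.matrix)
  q <- nrow(coeffs[[1]])
  for (B in coeffs)
    if (nrow(B) != q || ncol(B) != q)
      stop("all coefficient matrices must be square with matching dimension")
  if (is.null(innovation_cov)) innovation_cov <- diag(q)
  innovation_cov <- as.matrix(innovation_cov)
  if (nrow(innovation_cov) != q || ncol(innovation_cov) != q)
    stop("innovation_cov dimension must match the coefficient matrices")
  if (max(abs(innovation_cov - t(innovation_cov))) > 1e-12)
    stop("innovation_cov must be symmetric (within 1e-12)")
  rho <- companion_spectral_radius(coeffs)
  structure(
    list(coeffs = coeffs, innovation_cov = innovation_cov,
         order = length(coeffs), n_vars = q,
         spectral_radius = rho, stable = rho < 1),
    class = "var_model")
}

#' @export
print.var_model <- function(x, ...) {
  cat(sprintf("<var_model> Q = %d, p = %d, spectral radius %.4f (%s)\n",
              x$n_vars, x$order, x$spectral_radius,
              if (x$stable) "stable" else "UNSTABLE"))
  invisible(x)
}

#' Companion matrix of a VAR coefficient list
#'
#' @param coeffs List of p QxQ lag-coefficient matrices.
#' @return The (pQ)x(pQ) companion-form transition matrix.
#' @export
companion_matrix <- function(coeffs) {
  p <- length(coeffs)
  q <- nrow(coeffs[[1]])
  top <- do.call(cbind, coeffs)
  if (p == 1L) return(top)
  rbind(top, cbind(diag((p - 1L) * q), matrix(0, (p - 1L) * q, q)))
}

companion_spectral_radius <- function(coeffs) {
  max(Mod(eigen(companion_matrix(coeffs), only.values = TRUE)$values))
}

#' Fit a VAR model by multivariate least squares
#'
#' Builds the lagged observation matrices Y (current samples) and Z (stacked
#' lags 1..p) and solves the compact regression Y = A Z + R by least squares,
#' \eqn{\hat A = Y Z^T (Z Z^T)^{-1}}, returning coefficients, residuals and
#' the residual covariance (divisor N - p by default).
#'
#' @param trial An [eeg_trial()] or a channels-by-samples numeric matrix.
#' @param p Model order (positive integer).
#' @param cov_divisor Either `"n-p"` (default) or `"n-p-pq"` (small-sample
#'   correction subtracting the pQ regression parameters per equation).
#' @return List with `model` (a [var_model()]) and `residuals`
#'   (Q x (N - p) matrix).
#' @export
fit_var <- function(trial, p, cov_divisor = c("n-p", "n-p-pq")) {
  cov_divisor <- match.arg(cov_divisor)
  y <- if (inherits(trial, "eeg_trial")) trial$data else as.matrix(trial)
  q <- nrow(y); n <- ncol(y)
  if (p < 1L) stop("order p must be >= 1")
  if (n <= p * q + p)
    stop("too few samples (N = ", n, ") to fit a VAR(", p, ") on ", q,
         " variables")
  Y <- y[, (p + 1L):n, drop = FALSE]
  Z <- do.call(rbind, lapply(seq_len(p), function(i)
    y[, (p - i + 1L):(n - i), drop = FALSE]))
  ZZt <- tcrossprod(Z)
  rc <- rcond(ZZt)
  if (!is.finite(rc) || rc < 1e-14)
    stop("singular lag design: reciprocal condition number of ZZ' is ",
         format(rc, digits = 3))
  A <- t(solve(ZZt, tcrossprod(Z, Y)))
  R <- Y - A %*% Z
  neff <- n - p
  div <- if (cov_divisor == "n-p") neff else neff - p * q
  if (div <= 0) stop("non-positive covariance divisor; increase N")
  sigma <- tcrossprod(R) / div
  sigma <- (sigma + t(sigma)) / 2
  coeffs <- lapply(seq_len(p), function(k)
    A[, ((k - 1L) * q + 1L):(k * q), drop = FALSE])
  list(model = var_model(coeffs, sigma), residuals = R)
}

#' Select the VAR order by the Schwarz Bayesian Criterion
#'
#' Each candidate order in `p_min:p_max` is fitted on the common effective
#' sample (observations `p_max + 1 .. N` as regression targets, so all
#' candidates are scored on identical data) and the order minimizing
#' \eqn{SBC(p) = \ln\det\hat\Sigma_p + p Q^2 \ln(n')/n'} is returned, where
#' n' is the common effective sample size.
#'
#' @param trial An [eeg_trial()] or numeric matrix (channels x samples).
#' @param p_min,p_max Candidate order range.
#' @return List with `p_opt` and the named vector `sbc` over candidates.
#' @export
select_order <- function(trial, p_min = 1L, p_max = 10L) {
  y <- if (inherits(trial, "eeg_trial")) trial$data else as.matrix(trial)
  q <- nrow(y); n <- ncol(y)
  if (p_min < 1L || p_min > p_max) stop("need 1 <= p_min <= p_max")
  neff <- n - p_max
  if (neff <= p_max * q + 1L)
    stop("p_max = ", p_max, " infeasible for N = ", n)
  Y <- y[, (p_max + 1L):n, drop = FALSE]
  sbc <- vapply(p_min:p_max, function(p) {
    Z <- do.call(rbind, lapply(seq_len(p), function(i)
      y[, (p_max - i + 1L):(n - i), drop = FALSE]))
    A <- t(solve(tcrossprod(Z), tcrossprod(Z, Y)))
    R <- Y - A %*% Z
    sig <- tcrossprod(R) / neff
    val <- determinant(sig, logarithm = TRUE)
    if (val$sign <= 0) return(Inf)
    as.numeric(val$modulus) + p * q^2 * log(neff) / neff
  }, numeric(1))
  names(sbc) <- p_min:p_max
  if (!all(is.finite(sbc))) stop("SBC not finite for some candidate order")
  list(p_opt = (p_min:p_max)[which.min(sbc)], sbc = sbc)
}

#' Li-McLeod portmanteau test for multivariate residual whiteness
#'
#' Computes the Li-McLeod statistic over the residual autocorrelations at
#' lags 1..h,
#' \eqn{Q_{LM} = n \sum_{l=1}^h tr(C_l^T C_0^{-1} C_l C_0^{-1}) +
#' Q^2 h (h+1) / (2n)}, referred to a chi-square distribution with
#' \eqn{Q^2 (h - p)} degrees of freedom. Whiteness is accepted when the
#' p-value exceeds 0.05.
#'
#' @param residuals Q x n residual matrix.
#' @param p_fitted Order of the VAR model the residuals come from.
#' @param h Maximum lag of the portmanteau sum (default 20).
#' @return List with `statistic`, `df`, `p_value` and `is_white`.
#' @export
licmcleod_whiteness <- function(residuals, p_fitted, h = 20L) {
  R <- as.matrix(residuals)
  q <- nrow(R); n <- ncol(R)
  if (h <= p_fitted) stop("need h > p_fitted")
  if (n <= h) stop("need more residual samples than lags h")
  R <- R - rowMeans(R)
  C0 <- tcrossprod(R) / n
  rc <- rcond(C0)
  if (!is.finite(rc) || rc < 1e-12)
    stop("degenerate residual covariance (rcond = ", format(rc, digits = 3),
         ")")
  C0inv <- solve(C0)
  s <- 0
  for (l in seq_len(h)) {
    Cl <- tcrossprod(R[, (l + 1L):n, drop = FALSE],
                     R[, 1L:(n - l), drop = FALSE]) / n
    s <- s + sum(diag(crossprod(Cl, C0inv %*% Cl %*% C0inv)))
  }
  stat <- n * s + q^2 * h * (h + 1) / (2 * n)
  df <- q^2 * (h - p_fitted)
  pval <- stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = pval, is_white = pval > 0.05)
}

# Variance of sign(w)|w|^g for standard Gaussian w: E|w|^{2g}
supergaussian_moment <- function(g) 2^g * gamma(g + 0.5) / sqrt(pi)

#' Simulate a stable VAR process
#'
#' Generates the VAR recursion after discarding a burn-in of
#' `max(1000, 10 p)` samples. Innovations are either Gaussian with the
#' model's covariance, or super-Gaussian obtained by the power transform
#' \eqn{e = sign(w) |w|^g} of standard Gaussian noise (g in \[1.2, 2\]),
#' rescaled analytically so each channel attains the variance prescribed by
#' the diagonal of the innovation covariance. The super-Gaussian option
#' assumes a diagonal innovation covariance (independent sources).
#'
#' @param model A stable [var_model()].
#' @param n Number of samples to return.
#' @param innovation `"gaussian"` or `"power_supergaussian"`.
#' @param g Exponent of the power transform; when `NULL` one value is drawn
#'   uniformly in \[1.2, 2\] for the trial.
#' @param seed Integer seed (mandatory; the global RNG state is restored on
#'   exit).
#' @param fs Sampling rate attached to the returned trial (Hz).
#' @param class_label,trial_id Metadata for the returned trial.
#' @return An [eeg_trial()] with Q rows and n columns.
#' @export
simulate_var <- function(model, n, innovation = c("gaussian",
                         "power_supergaussian"), g = NULL, seed,
                         fs = 125, class_label = "h1", trial_id = "t1") {
  innovation <- match.arg(innovation)
  stopifnot(inherits(model, "var_model"))
  if (!model$stable)
    stop("model is unstable (spectral radius ",
         format(model$spectral_radius, digits = 4), ")")
  if (missing(seed)) stop("seed is mandatory for simulate_var")
  q <- model$n_vars; p <- model$order
  burn <- max(1000L, 10L * p)
  ntot <- n + burn
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  if (innovation == "gaussian") {
    L <- t(chol(model$innovation_cov + 1e-15 * diag(q)))
    E <- L %*% matrix(stats::rnorm(q * ntot), q, ntot)
  } else {
    if (is.null(g)) g <- stats::runif(1, 1.2, 2)
    if (g < 1 || g > 3) stop("exponent g out of the supported range")
    W <- matrix(stats::rnorm(q * ntot), q, ntot)
    E <- sign(W) * abs(W)^g / sqrt(supergaussian_moment(g))
    E <- sqrt(diag(model$innovation_cov)) * E
  }
  S <- matrix(0, q, ntot)
  B <- model$coeffs
  for (t in seq_len(ntot)) {
    acc <- E[, t]
    for (k in seq_len(min(p, t - 1L)))
      acc <- acc + B[[k]] %*% S[, t - k]
    S[, t] <- acc
  }
  eeg_trial(S[, (burn + 1L):ntot, drop = FALSE], fs = fs,
            class_label = class_label, trial_id = trial_id)
}

#' AR(2) coefficients of a damped oscillator
#'
#' Places a complex-conjugate pole pair at radius `rho` and angle
#' \eqn{2\pi f / f_s}, giving the autoregressive pair
#' \eqn{b_1 = 2\rho\cos(2\pi f/f_s)}, \eqn{b_2 = -\rho^2} that produces an
#' autonomous oscillation centered at `f_center` Hz. Radii near 1 give a
#' narrowband rhythm, smaller radii a broadband one.
#'
#' @param f_center Center frequency in Hz (0 < f < fs/2).
#' @param fs Sampling rate in Hz.
#' @param rho Pole radius in (0, 1); `rho = 0` degenerates to white noise.
#' @return Numeric vector `c(b1, b2)`.
#' @export
design_oscillator <- function(f_center, fs, rho) {
  if (f_center <= 0 || f_center >= fs / 2)
    stop("f_center must lie strictly inside (0, fs/2)")
  if (rho < 0 || rho >= 1) stop("pole radius must be in [0, 1)")
  c(2 * rho * cos(2 * pi * f_center / fs), -rho^2)
}
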