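#' Autocovariance sequence of a stable VAR process (inverse Yule-Walker)
#'
#' Solves the discrete-time Lyapunov equation on the pQ x pQ companion form
#' to obtain the exact lag covariances Gamma_0 .. Gamma_{p-1} of the
#' process, then extends them to any lag k >= p through the Yule-Walker
#' recursion \eqn{\Gamma_k = \sum_{l=1}^p B_l \Gamma_{k-l}}.
#'
#' @param model A stable [var_model()].
#' @param qmax Maximum lag to compute (default 10).
#' @return Object of class `lag_covariance`: list `gammas` of `qmax + 1`
#'   QxQ matrices (lags 0..qmax; \eqn{\Gamma_k = E[s_n s_{n-k}^T]},
#'   \eqn{\Gamma_{-k} = \Gamma_k^T} implied) and `qmax`.
#' @export
yule_walker_inverse <- function(model, qmax = 10L) {
  stopifnot(inherits(model, "var_model"))
  if (!model$stable)
    stop("model is unstable (spectral radius ",
         format(model$spectral_radius, digits = 4), "); no stationary ",
         "covariance exists")
  p <- model$order; q <- model$n_vars
  Fc <- companion_matrix(model$coeffs)
  V <- matrix(0, p * q, p * q)
  V[1:q, 1:q] <- model$innovation_cov
  m <- p * q
  if (m <= 70L) {
    # vectorized solve of Sigma = F Sigma F' + V
    vecS <- solve(diag(m * m) - kronecker(Fc, Fc), as.vector(V))
    Sc <- matrix(vecS, m, m)
  } else {
    # Smith doubling iteration, geometric convergence for stable F
    Sc <- V; A <- Fc
    for (it in 1:60) {
      Snew <- Sc + A %*% Sc %*% t(A)
      A <- A %*% A
      if (max(abs(Snew - Sc)) < 1e-14 * max(1, max(abs(Snew)))) { Sc <- Snew; break }
      Sc <- Snew
    }
  }
  if (!all(is.finite(Sc))) stop("Lyapunov solve failed (non-finite result)")
  Sc <- (Sc + t(Sc)) / 2
  # companion state [s_n; ...; s_{n-p+1}]: block (1, k) = Gamma_{k-1}
  gammas <- vector("list", qmax + 1L)
  for (k in 0:(p - 1L))
    if (k <= qmax)
      gammas[[k + 1L]] <- Sc[1:q, (k * q + 1L):((k + 1L) * q), drop = FALSE]
  if (qmax >= p) {
    B <- model$coeffs
    getg <- function(k) {            # Gamma_k for any integer k
      if (k >= 0) gammas[[k + 1L]] else t(gammas[[-k + 1L]])
    }
    for (k in p:qmax) {
      acc <- matrix(0, q, q)
      for (l in seq_len(p)) acc <- acc + B[[l]] %*% getg(k - l)
      gammas[[k + 1L]] <- acc
    }
  }
  gammas[[1L]] <- (gammas[[1L]] + t(gammas[[1L]])) / 2
  structure(list(gammas = gammas, qmax = qmax, n_vars = q),
            class = "lag_covariance")
}

# Cross-covariance block Cov(s_{n-a}, s_{n-b}) for variable sets (rows ra,
# cols rb), a,b >= 0, from a lag_covariance object.
gamma_block <- function(cov, a, b, ra, rb) {
  k <- b - a
  G <- if (k >= 0) cov$gammas[[k + 1L]] else t(cov$gammas[[-k + 1L]])
  G[ra, rb, drop = FALSE]
}

#' Partial variance of a target given lagged regressors
#'
#' Prediction-error variance of the linear regression of the present of
#' target j on the q past values of the variables in `vars`, computed as the
#' Schur complement \eqn{\Sigma_j - \Sigma_{j,V} \Sigma_V^{-1}
#' \Sigma_{j,V}^T} of the model's lag-covariance matrix. No data regression
#' is performed; covariances come from the analytic (or model-implied) lag
#' covariances.
#'
#' @param j Target variable index.
#' @param vars Integer vector of variable indices whose q past values form
#'   the regressor set V (may or may not include j; empty vector gives the
#'   unconditional variance).
#' @param cov A `lag_covariance` from [yule_walker_inverse()].
#' @param q Number of past lags (<= `cov$qmax`).
#' @return Scalar partial variance in (0, Sigma_j\].
#' @export
partial_variance <- function(j, vars, cov, q) {
  stopifnot(inherits(cov, "lag_covariance"))
  if (q > cov$qmax) stop("q exceeds the available lags (qmax = ",
                         cov$qmax, ")")
  sj <- cov$gammas[[1L]][j, j]
  if (length(vars) == 0L) return(sj)
  nv <- length(vars)
  m <- nv * q
  SV <- matrix(0, m, m)
  SjV <- numeric(m)
  for (a in seq_len(q)) {
    ia <- ((a - 1L) * nv + 1L):(a * nv)
    SjV[ia] <- gamma_block(cov, 0L, a, j, vars)
    for (b in seq_len(q)) {
      ib <- ((b - 1L) * nv + 1L):(b * nv)
      SV[ia, ib] <- gamma_block(cov, a, b, vars, vars)
    }
  }
  sol <- try(solve(SV, SjV), silent = TRUE)
  if (inherits(sol, "try-error")) {
    jit <- 1e-10 * sum(diag(SV)) / m
    SVj <- SV + jit * diag(m)
    k <- kappa(SVj)
    if (!is.finite(k) || k > 1e10)
      stop("singular regressor covariance (condition number ",
           format(k, digits = 3), ")")
    sol <- solve(SVj, SjV)
  }
  pv <- sj - sum(SjV * sol)
  if (pv < -1e-10 * max(1, sj))
    stop("negative partial variance (", format(pv, digits = 4),
         "): inconsistent covariance sequence")
  max(pv, .Machine$double.xmin)
}

#' Information storage, transfer and significant links of a VAR network
#'
#' From the model-implied lag covariances, computes for every target j the
#' information storage \eqn{S_j = \frac12 \ln(\Sigma_j / \Sigma_{j|j})},
#' the total information transfer (total Granger causality)
#' \eqn{T_j = \frac12 \ln(\Sigma_{j|j} / \Sigma_{j|i,j,k})} with all other
#' processes as drivers, and for every ordered pair (i, j) the conditional
#' information transfer \eqn{T_{i \to j|k} = \frac12 \ln(\Sigma_{j|j,k} /
#' \Sigma_{j|i,j,k})}, all in nats. When `effective_N` is supplied, each
#' pairwise transfer is tested against zero with the F statistic for the
#' nested regressions,
#' \eqn{F = ((\Sigma_{j|j,k} - \Sigma_{j|i,j,k})/q) /
#' (\Sigma_{j|i,j,k}/(N_{eff} - Q q))}, with (q, N_eff - Q q) degrees of
#' freedom at level `alpha`.
#'
#' @param model A stable [var_model()].
#' @param q Number of past lags in the sub-models (default 10).
#' @param effective_N Effective regression sample size for the F-test
#'   (typically N - p); `NULL` (default) skips significance testing, as
#'   appropriate for true-parameter (theoretical) measures.
#' @param alpha Significance level of the F-test (default 0.05).
#' @return Object of class `info_measures`: `storage` and `total_transfer`
#'   (length-Q vectors), `cond_transfer` (QxQ, `[i, j]` = transfer i -> j,
#'   diagonal NA), `f_stats`, `p_values`, `significant`, `n_links`, plus
#'   `q`, `alpha`, `effective_N`.
#' @export
information_measures <- function(model, q = 10L, effective_N = NULL,
                                 alpha = 0.05) {
  stopifnot(inherits(model, "var_model"))
  Q <- model$n_vars
  cov <- yule_walker_inverse(model, qmax = q)
  clip0 <- function(x) { x[x < 0 & x > -1e-10] <- 0; x }
  storage <- numeric(Q); total <- numeric(Q)
  condT <- matrix(NA_real_, Q, Q)
  fst <- matrix(NA_real_, Q, Q); pv <- matrix(NA_real_, Q, Q)
  do_test <- !is.null(effective_N)
  if (do_test && effective_N <= Q * q)
    stop("effective_N must exceed Q * q for the F-test")
  for (j in seq_len(Q)) {
    s_j <- partial_variance(j, integer(0), cov, q)
    s_own <- partial_variance(j, j, cov, q)
    s_full <- partial_variance(j, seq_len(Q), cov, q)
    storage[j] <- clip0(0.5 * log(s_j / s_own))
    total[j] <- clip0(0.5 * log(s_own / s_full))
    for (i in seq_len(Q)[-j]) {
      rest <- setdiff(seq_len(Q), i)       # j and the conditioning set k
      s_rest <- partial_variance(j, rest, cov, q)
      condT[i, j] <- clip0(0.5 * log(s_rest / s_full))
      if (do_test) {
        fst[i, j] <- ((s_rest - s_full) / q) /
          (s_full / (effective_N - Q * q))
        pv[i, j] <- stats::pf(max(fst[i, j], 0), q, effective_N - Q * q,
                              lower.tail = FALSE)
      }
    }
  }
  if (any(storage < 0) || any(total < 0) || any(condT < 0, na.rm = TRUE))
    stop("negative information measure beyond tolerance: inconsistent ",
         "covariances")
  sig <- if (do_test) pv < alpha else matrix(NA, Q, Q)
  n_links <- if (do_test) sum(sig, na.rm = TRUE) else NA_integer_
  structure(
    list(storage = storage, total_transfer = total, cond_transfer = condT,
         f_stats = fst, p_values = pv, significant = sig, n_links = n_links,
         q = q, alpha = alpha, effective_N = effective_N),
    class = "info_measures")
}

#' @export
print.info_measures <- function(x, ...) {
  cat(sprintf(
    "<info_measures> Q = %d, q = %d | mean S = %.4f, mean T = %.4f%s\n",
    length(x$storage), x$q, mean(x$storage), mean(x$total_transfer),
    if (!is.null(x$effective_N)) sprintf(", links = %d", x$n_links) else ""))
  invisible(x)
}

#' Scalar network summaries of an `info_measures` object
#'
#' Node averages of storage and total transfer, the pair average of the
#' conditional transfer over the Q(Q-1) ordered pairs, and the significant
#' link count, as used to reduce a network to one value per trial.
#'
#' @param measures An [information_measures()] result.
#' @return Named list `mean_storage`, `mean_transfer`, `mean_cond_transfer`,
#'   `n_links`.
#' @export
network_summary <- function(measures) {
  stopifnot(inherits(measures, "info_measures"))
  list(mean_storage = mean(measures$storage),
       mean_transfer = mean(measures$total_transfer),
       mean_cond_transfer = mean(measures$cond_transfer, na.rm = TRUE),
       n_links = measures$n_links)
}
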