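# Shared test helpers: independent oracles and small samplers.

# Explicit-regression oracle for the information measures: fits the full and
# restricted least-squares regressions on an actual realization (time in
# rows of S) via normal equations on the lagged design, independent of the
# package's analytic Lyapunov/Yule-Walker path.
regression_oracle <- function(S, q) {
  Q <- ncol(S); N <- nrow(S)
  y_all <- S[(q + 1):N, , drop = FALSE]
  X_all <- do.call(cbind, lapply(1:q, function(a)
    S[(q + 1 - a):(N - a), , drop = FALSE]))
  cols <- function(vars) as.vector(outer(vars, (0:(q - 1)) * Q, "+"))
  G <- crossprod(X_all)
  GY <- crossprod(X_all, y_all)
  yy <- colSums(y_all^2)
  n <- nrow(y_all)
  pv <- function(j, vars) {
    if (!length(vars)) return(yy[j] / n)
    cc <- cols(vars)
    b <- solve(G[cc, cc], GY[cc, j])
    (yy[j] - sum(GY[cc, j] * b)) / n
  }
  st <- numeric(Q); tt <- numeric(Q); ct <- matrix(NA_real_, Q, Q)
  for (j in 1:Q) {
    s0 <- pv(j, integer(0)); sj <- pv(j, j); sf <- pv(j, 1:Q)
    st[j] <- 0.5 * log(s0 / sj)
    tt[j] <- 0.5 * log(sj / sf)
    for (i in setdiff(1:Q, j))
      ct[i, j] <- 0.5 * log(pv(j, setdiff(1:Q, i)) / sf)
  }
  list(storage = st, total_transfer = tt, cond_transfer = ct)
}

# standard Laplace sample (unit scale)
rlaplace <- function(n) sign(stats::runif(n, -1, 1)) * -log(stats::runif(n))

# largest |power| frequency of a series, in Hz
periodogram_peak <- function(x, fs) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0,
                          plot = FALSE, spans = 11)
  sp$freq[which.max(sp$spec)]
}
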