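#' Concatenate per-trial VAR residual blocks
#'
#' Column-wise concatenation of the residual matrices of all trials, class 1
#' trials first (in stored order) then class 2, yielding the pooled Q x M
#' residual matrix used for a single ICA decomposition. Pooling across
#' trials and conditions assumes the instantaneous volume-conduction mixing
#' is stationary over the recording.
#'
#' @param residual_list List of Q x n_k residual matrices.
#' @return Q x M matrix, M the summed block widths.
#' @export
concatenate_residuals <- function(residual_list) {
  residual_list <- lapply(residual_list, as.matrix)
  q <- vapply(residual_list, nrow, integer(1))
  if (length(unique(q)) != 1L)
    stop("all residual blocks must have the same number of rows")
  do.call(cbind, residual_list)
}

# Excess kurtosis of each row of a matrix
row_kurtosis <- function(X) {
  X <- X - rowMeans(X)
  m2 <- rowMeans(X^2)
  rowMeans(X^4) / m2^2 - 3
}

#' Amari index between an unmixing and a mixing matrix
#'
#' Permutation- and scale-invariant separation error of the product
#' P = W_unmix M_mix; 0 for a perfect (signed, scaled, permuted)
#' identification, larger values indicate residual mixing. Normalized to
#' \[0, 1\] by 2 Q (Q - 1).
#'
#' @param W_unmix Estimated Q x Q unmixing matrix.
#' @param M_mix True Q x Q mixing matrix.
#' @return Scalar Amari separation index.
#' @export
amari_index <- function(W_unmix, M_mix) {
  P <- abs(W_unmix %*% M_mix)
  q <- nrow(P)
  r <- sum(rowSums(P) / apply(P, 1, max) - 1)
  c <- sum(colSums(P) / apply(P, 2, max) - 1)
  (r + c) / (2 * q * (q - 1))
}

# One Infomax run (natural-gradient logistic rule, suited to super-Gaussian
# sources) on pre-whitened data. Returns the unmixing matrix acting on the
# whitened data, or NULL on non-convergence. The learning rate adapts:
# gentle growth while the gradient shrinks, back-off when it grows.
infomax_core <- function(Xw, max_iter = 600L, tol = 1e-9, lrate = 0.5) {
  q <- nrow(Xw); n <- ncol(Xw)
  W <- qr.Q(qr(matrix(stats::rnorm(q * q), q, q)))
  prev <- Inf; delta <- Inf
  for (it in seq_len(max_iter)) {
    U <- W %*% Xw
    # fixed point: E[(1 - 2 sigmoid(u)) u'] = -I
    G <- diag(q) + ((1 - 2 / (1 + exp(-U))) %*% t(U)) / n
    delta <- max(abs(G))
    if (!is.finite(delta) || delta > 1e3) return(NULL)
    lrate <- if (delta > prev) lrate * 0.9 else min(lrate * 1.02, 1)
    prev <- delta
    W <- W + lrate * G %*% W
    if (delta < tol) break
  }
  if (delta > 1e-4) return(NULL)
  W
}

#' Estimate the instantaneous mixing of VAR residuals by Infomax ICA
#'
#' Runs an Infomax-type ICA (natural-gradient extended rule, super-Gaussian
#' branch) `n_restarts` times from different seeded random orthogonal
#' initializations on the pre-whitened, demeaned residuals, and keeps the
#' restart whose recovered components have the largest mean absolute excess
#' kurtosis (independence proxy for super-Gaussian sources). The returned
#' mixing matrix W (residuals = W e, e independent) is normalized to
#' unit-Euclidean-norm columns with the largest-magnitude entry of each
#' column positive, fixing ICA's scale/sign indeterminacy.
#'
#' @param R Q x M residual matrix (M >= 20 Q^2 recommended).
#' @param n_restarts Number of seeded restarts (default 10).
#' @param seed Base integer seed; restart r uses `seed + r - 1`.
#' @return Object of class `source_decomposition` with elements `W`
#'   (mixing), `W_inv` (unmixing of the reduced components), `kurtosis`
#'   (per selected component), `restart_scores`, `near_gaussian` flag and
#'   `condition_number` of W.
#' @export
estimate_ica <- function(R, n_restarts = 10L, seed = 0L) {
  R <- as.matrix(R)
  if (!all(is.finite(R))) stop("residual matrix contains non-finite values")
  q <- nrow(R); n <- ncol(R)
  if (n < 20 * q^2)
    warning("few residual samples for ICA (M = ", n, " < 20 Q^2)")
  R <- R - rowMeans(R)
  # pre-whitening
  C <- tcrossprod(R) / n
  es <- eigen((C + t(C)) / 2, symmetric = TRUE)
  if (min(es$values) <= 1e-12 * max(es$values))
    stop("residual covariance is singular; cannot whiten for ICA")
  K <- t(es$vectors) / sqrt(es$values)       # Q x Q whitening matrix
  Xw <- K %*% R
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  best <- NULL; best_score <- -Inf; scores <- rep(NA_real_, n_restarts)
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    Wr <- infomax_core(Xw)
    if (is.null(Wr)) next
    U <- Wr %*% Xw
    score <- mean(abs(row_kurtosis(U)))
    scores[r] <- score
    if (score > best_score) { best_score <- score; best <- Wr }
  }
  if (is.null(best)) stop("ICA failed to converge on all restarts")
  unmix <- best %*% K                        # components e = unmix %*% R
  W <- solve(unmix)                          # R = W e
  # normalization convention: unit-norm columns, dominant entry positive
  cn <- sqrt(colSums(W^2))
  sgn <- vapply(seq_len(q), function(j) {
    col <- W[, j]
    sign(col[which.max(abs(col))])
  }, numeric(1))
  W <- sweep(W, 2, cn * sgn, `/`)
  unmix <- solve(W)
  kur <- row_kurtosis(unmix %*% R)
  near_gauss <- all(abs(kur) < 0.1)
  if (near_gauss)
    warning("all component kurtoses within 0.1 of zero: near-Gaussian ",
            "residuals, mixing matrix may be non-identifiable")
  structure(
    list(W = W, W_inv = unmix, kurtosis = kur, restart_scores = scores,
         near_gaussian = near_gauss, condition_number = kappa(W)),
    class = "source_decomposition")
}

#' @export
print.source_decomposition <- function(x, ...) {
  cat(sprintf(
    "<source_decomposition> Q = %d, cond(W) = %.2f, mean |kurtosis| = %.3f%s\n",
    nrow(x$W), x$condition_number, mean(abs(x$kurtosis)),
    if (x$near_gaussian) " [near-Gaussian warning]" else ""))
  invisible(x)
}

#' Assemble the overall scalp-to-source unmixing matrix
#'
#' Combines the ICA mixing matrix W of the reduced components and the CSP
#' filter matrix C into the Q x D unmixing U = W^{-1} C, which reconstructs
#' the source time series directly from the scalp signals (s = U x).
#'
#' @param W Q x Q invertible ICA mixing matrix.
#' @param C Q x D spatial filter matrix.
#' @return Q x D unmixing matrix U.
#' @export
assemble_unmixing <- function(W, C) {
  W <- as.matrix(W); C <- as.matrix(C)
  if (nrow(W) != ncol(W) || nrow(W) != nrow(C))
    stop("W must be square with as many rows as C")
  k <- kappa(W)
  if (!is.finite(k) || k > 1e8)
    stop("ill-conditioned mixing matrix W (condition number ",
         format(k, digits = 3), ")")
  solve(W, C)
}

#' Reconstruct source time series from scalp signals
#'
#' Applies the overall unmixing matrix sample-wise, s = U x, preserving
#' trial metadata.
#'
#' @param U Q x D unmixing matrix from [assemble_unmixing()].
#' @param x An [eeg_trial()], [eeg_dataset()] or D x N matrix.
#' @return Same kind of object with Q source rows.
#' @export
reconstruct_sources <- function(U, x) {
  if (inherits(x, "eeg_dataset")) {
    trials <- lapply(x$trials, function(tr) reconstruct_sources(U, tr))
    return(eeg_dataset(trials, classes = x$classes))
  }
  if (inherits(x, "eeg_trial")) {
    out <- apply_filters(U, x)
    out$channel_names <- paste0("s", seq_len(nrow(out$data)))
    return(out)
  }
  apply_filters(U, x)
}

#' Map VAR parameters from reduced components to the source domain
#'
#' Given the VAR parameters (A_k, Sigma_r) of the reduced components and the
#' ICA mixing W, the source-domain parameters follow by similarity
#' transform: \eqn{B_k = W^{-1} A_k W} and
#' \eqn{\Sigma_e = W^{-1} \Sigma_r W^{-T}}. For an exact decomposition
#' Sigma_e is diagonal; its off-diagonal energy is returned as a diagnostic
#' of unmixing quality.
#'
#' @param A_list List of Q x Q lag-coefficient matrices of the reduced
#'   components.
#' @param Sigma_r Residual covariance of the reduced-component VAR.
#' @param W Q x Q invertible ICA mixing matrix.
#' @return List with `model` (a [var_model()] of the sources) and
#'   `offdiag_fraction` (off-diagonal Frobenius energy fraction of Sigma_e).
#' @export
transform_parameters <- function(A_list, Sigma_r, W) {
  W <- as.matrix(W)
  if (kappa(W) > 1e8) stop("singular or ill-conditioned W")
  Winv <- solve(W)
  B <- lapply(A_list, function(A) Winv %*% A %*% W)
  Sigma_e <- Winv %*% Sigma_r %*% t(Winv)
  Sigma_e <- (Sigma_e + t(Sigma_e)) / 2
  off <- Sigma_e; diag(off) <- 0
  offfrac <- sqrt(sum(off^2)) / sqrt(sum(Sigma_e^2))
  list(model = var_model(B, Sigma_e), offdiag_fraction = offfrac)
}
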