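#' Trace-normalized class covariance matrices
#'
#' For each class, averages the per-trial spatial covariance
#' \eqn{x x^T / tr(x x^T)} over all trials of the class, yielding two
#' unit-trace D x D matrices. Trace normalization removes per-trial power
#' differences so that CSP compares spatial variance patterns only.
#'
#' @param dataset An [eeg_dataset()] with two classes.
#' @return List with unit-trace matrices `P_h1` and `P_h2` (named by class)
#'   and the class labels.
#' @export
class_covariances <- function(dataset) {
  stopifnot(inherits(dataset, "eeg_dataset"))
  one <- function(lbl) {
    trs <- class_trials(dataset, lbl)
    mats <- lapply(trs, function(tr) {
      if (ncol(tr$data) <= nrow(tr$data))
        stop("trial '", tr$trial_id, "' has too few samples (N <= D)")
      S <- tcrossprod(tr$data)
      tr_s <- sum(diag(S))
      if (tr_s <= 0)
        stop("zero-variance trial: '", tr$trial_id, "'")
      S / tr_s
    })
    P <- Reduce(`+`, mats) / length(mats)
    (P + t(P)) / 2
  }
  out <- list(one(dataset$classes[1]), one(dataset$classes[2]))
  names(out) <- dataset$classes
  out
}

#' Common Spatial Patterns filters from two class covariances
#'
#' Solves the generalized eigenproblem \eqn{P_{h1} c_j = \lambda_j (P_{h1} +
#' P_{h2}) c_j}. Eigenvalues lie in \[0, 1\]; large (small) values mark
#' filters with high variance in class 1 (class 2). The filters jointly
#' diagonalize both class covariances. Eigenvalues are clamped away from 0
#' and 1 before the Riemannian fractional distances are computed.
#'
#' @param P_h1,P_h2 Symmetric D x D class covariance matrices
#'   (from [class_covariances()]).
#' @param ridge Relative ridge added to `P_h1 + P_h2` before the eigensolve
#'   (scaled by `tr(P)/D`), guarding near-singularity.
#' @return An object of class `spatial_filter_set`: `full_filters` (D x D,
#'   filters as rows, lambda-descending), `eigenvalues`,
#'   `fractional_distances`, `total_distance`, `selected` (initially all),
#'   `pruned_filter`.
#' @export
csp_filters <- function(P_h1, P_h2, ridge = 1e-8) {
  P_h1 <- as.matrix(P_h1); P_h2 <- as.matrix(P_h2)
  d <- nrow(P_h1)
  if (max(abs(P_h1 - t(P_h1))) > 1e-8 || max(abs(P_h2 - t(P_h2))) > 1e-8)
    stop("class covariance matrices must be symmetric")
  S <- P_h1 + P_h2
  S <- S + ridge * sum(diag(S)) / d * diag(d)
  es <- eigen(S, symmetric = TRUE)
  if (min(es$values) <= 0)
    stop("P_h1 + P_h2 is singular even after ridge regularization")
  Sisq <- es$vectors %*% (t(es$vectors) / sqrt(es$values))
  M <- Sisq %*% P_h1 %*% Sisq
  ew <- eigen((M + t(M)) / 2, symmetric = TRUE)
  lambda <- pmin(pmax(ew$values, 1e-9), 1 - 1e-9)
  filters <- t(Sisq %*% ew$vectors)      # rows are the spatial filters c_j
  fd <- fractional_distances(lambda)
  structure(
    list(full_filters = filters, eigenvalues = lambda,
         fractional_distances = fd$delta, total_distance = fd$total,
         selected = seq_len(d), pruned_filter = filters),
    class = "spatial_filter_set")
}

#' @export
print.spatial_filter_set <- function(x, ...) {
  cat(sprintf(
    "<spatial_filter_set> D = %d, Q = %d selected, total sq. distance %.4f\n",
    nrow(x$full_filters), length(x$selected), x$total_distance))
  invisible(x)
}

#' Fractional Riemannian distances of CSP eigenvalues
#'
#' The affine-invariant Riemannian distance between the two SPD class
#' covariances decomposes over the generalized eigenvalues as
#' \eqn{\sum_j \ln^2(\lambda_j / (1 - \lambda_j))}. Each filter's fractional
#' contribution is \eqn{\delta_j = \ln^2(\lambda_j/(1-\lambda_j)) / \sum_i
#' \ln^2(\lambda_i/(1-\lambda_i))}; the deltas are nonnegative and sum to 1.
#'
#' @param lambda Eigenvalues strictly inside (0, 1).
#' @return List with `delta` (fractions summing to 1) and `total` (total
#'   squared distance).
#' @export
fractional_distances <- function(lambda) {
  if (any(lambda <= 0 | lambda >= 1))
    stop("eigenvalues must lie strictly inside (0, 1)")
  l <- log(lambda / (1 - lambda))
  if (max(abs(l)) < 1e-5)
    stop("degenerate classes: all eigenvalues equal 0.5 (zero distance)")
  w <- l^2
  tot <- sum(w)
  list(delta = w / tot, total = tot)
}

#' Prune CSP filters by cumulative fractional distance
#'
#' Sorts filters by fractional distance (descending, ties broken by original
#' index) and keeps the smallest prefix whose cumulative distance reaches
#' the requested coverage of the total Riemannian distance.
#'
#' @param filterset A `spatial_filter_set` from [csp_filters()].
#' @param coverage Fraction of the total squared distance to cover,
#'   in (0, 1\]; default 0.90.
#' @return The filter set with `selected` (ordered indices into the full
#'   set) and `pruned_filter` (Q x D matrix C) updated.
#' @export
select_filters <- function(filterset, coverage = 0.90) {
  stopifnot(inherits(filterset, "spatial_filter_set"))
  if (coverage <= 0 || coverage > 1) stop("coverage must be in (0, 1]")
  delta <- filterset$fractional_distances
  ord <- order(-delta, seq_along(delta))
  qsel <- which(cumsum(delta[ord]) >= coverage - 1e-12)[1]
  if (is.na(qsel)) qsel <- length(delta)
  sel <- ord[seq_len(qsel)]
  filterset$selected <- sel
  filterset$pruned_filter <- filterset$full_filters[sel, , drop = FALSE]
  filterset
}

#' Apply a spatial filter matrix to a trial or dataset
#'
#' Computes the reduced components y = C x sample-wise, preserving sampling
#' rate and class labels.
#'
#' @param C Q x D filter matrix (e.g. `pruned_filter` of a filter set).
#' @param x An [eeg_trial()], an [eeg_dataset()], or a D x N matrix.
#' @return Object of the same kind with Q rows per trial.
#' @export
apply_filters <- function(C, x) {
  C <- as.matrix(C)
  if (inherits(x, "eeg_dataset")) {
    trials <- lapply(x$trials, function(tr) apply_filters(C, tr))
    return(eeg_dataset(trials, classes = x$classes))
  }
  if (inherits(x, "eeg_trial")) {
    if (ncol(C) != nrow(x$data))
      stop("filter matrix expects ", ncol(C), " channels, trial has ",
           nrow(x$data))
    return(eeg_trial(C %*% x$data, fs = x$fs, class_label = x$class_label,
                     trial_id = x$trial_id,
                     channel_names = paste0("y", seq_len(nrow(C)))))
  }
  x <- as.matrix(x)
  if (ncol(C) != nrow(x)) stop("dimension mismatch")
  C %*% x
}
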