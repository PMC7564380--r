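#' Five-source VAR(2) model of one simulation condition
#'
#' Builds the generative source model of the two-condition benchmark:
#' five coupled damped oscillators at 125 Hz, VAR order 2, diagonal
#' (identity) innovation covariance.
#'
#' Condition 1 (no connectivity): autonomous alpha rhythms (10 Hz,
#' narrowband) on sources 1, 4 and 5 and beta rhythms (23 Hz, broadband) on
#' sources 2 and 3; all off-diagonal coefficients zero. Condition 2 (alpha
#' propagation): alpha on source 1, beta on sources 2-5, and causal chain
#' couplings s1 -> s2 -> s3 -> s4 -> s5 imposed by setting the lag-1
#' coefficients (2,1), (3,2), (4,3) and (5,4) to 0.5.
#'
#' @param condition 1 or 2.
#' @param rho_alpha Pole radius of the narrowband alpha oscillators
#'   (default 0.9).
#' @param rho_beta Pole radius of the broadband beta oscillators
#'   (default 0.7).
#' @param fs Sampling rate in Hz (default 125).
#' @return A stable [var_model()] with Q = 5, p = 2.
#' @export
build_condition_model <- function(condition, rho_alpha = 0.9,
                                  rho_beta = 0.7, fs = 125) {
  if (!condition %in% c(1L, 2L)) stop("condition must be 1 or 2")
  alpha <- design_oscillator(10, fs, rho_alpha)
  beta <- design_oscillator(23, fs, rho_beta)
  bands <- if (condition == 1L) list(alpha, beta, beta, alpha, alpha)
           else list(alpha, beta, beta, beta, beta)
  B1 <- diag(vapply(bands, `[`, numeric(1), 1L))
  B2 <- diag(vapply(bands, `[`, numeric(1), 2L))
  if (condition == 2L)
    for (j in 2:5) B1[j, j - 1L] <- 0.5
  model <- var_model(list(B1, B2), diag(5))
  if (!model$stable)
    stop("constructed condition-", condition, " model is unstable")
  model
}

#' Tridiagonal volume-conduction mixing matrix
#'
#' The 5x5 instantaneous mixing used to turn the simulated sources into
#' scalp signals: ones on the diagonal and 0.5 on the sub- and
#' super-diagonals, so each source spreads over two or three neighboring
#' electrodes. The matrix is symmetric and invertible.
#'
#' @return 5x5 numeric matrix.
#' @export
volume_conduction_mixing <- function() {
  M <- diag(5)
  for (i in 1:4) { M[i, i + 1L] <- 0.5; M[i + 1L, i] <- 0.5 }
  M
}

#' Generate the two-condition synthetic scalp EEG dataset
#'
#' For each condition, simulates `n_trials` source realizations of length
#' `n` samples from the condition's VAR(2) model with super-Gaussian
#' innovations (power transform, exponent drawn uniformly in \[1.2, 2\] per
#' trial), mixes them through the volume-conduction matrix (x = M s) and
#' labels the trials by condition. The true source series are kept alongside
#' the dataset so estimated sources can be matched against ground truth.
#'
#' @param seed Base integer seed; trial t of condition c uses
#'   `seed + (c - 1) * n_trials + t - 1`.
#' @param n_trials Trials per condition (default 10).
#' @param n Samples per trial (default 1000).
#' @param fs Sampling rate in Hz (default 125).
#' @param rho_alpha,rho_beta Oscillator pole radii, passed to
#'   [build_condition_model()].
#' @return List with `dataset` (two-class [eeg_dataset()] of mixed scalp
#'   signals, classes `"cond1"`, `"cond2"`), `sources` (list of true source
#'   trials, parallel to `dataset$trials`), `models` (the two true
#'   [var_model()]s) and `mixing` (the matrix M).
#' @export
generate_dataset <- function(seed = 0L, n_trials = 10L, n = 1000L, fs = 125,
                             rho_alpha = 0.9, rho_beta = 0.7) {
  M <- volume_conduction_mixing()
  models <- list(build_condition_model(1L, rho_alpha, rho_beta, fs),
                 build_condition_model(2L, rho_alpha, rho_beta, fs))
  trials <- list(); sources <- list()
  idx <- 0L
  for (c in 1:2) {
    lbl <- paste0("cond", c)
    for (t in seq_len(n_trials)) {
      idx <- idx + 1L
      id <- sprintf("%s_t%02d", lbl, t)
      src <- simulate_var(models[[c]], n,
                          innovation = "power_supergaussian",
                          seed = seed + (c - 1L) * n_trials + t - 1L,
                          fs = fs, class_label = lbl, trial_id = id)
      sources[[idx]] <- src
      trials[[idx]] <- eeg_trial(M %*% src$data, fs = fs, class_label = lbl,
                                 trial_id = id)
    }
  }
  list(dataset = eeg_dataset(trials, classes = c("cond1", "cond2")),
       sources = sources, models = models, mixing = M)
}

#' Theoretical information measures of a simulation condition
#'
#' Computes the exact information storage and transfer implied by the true
#' VAR parameters of a condition (no estimation step), used as ground truth
#' for the estimation pipeline. Significance fields are omitted: they apply
#' to estimated, not true, parameters.
#'
#' @param condition 1 or 2.
#' @param q Number of past lags (default 10).
#' @param ... Passed to [build_condition_model()].
#' @return An [information_measures()] result without significance fields.
#' @export
theoretical_measures <- function(condition, q = 10L, ...) {
  information_measures(build_condition_model(condition, ...), q = q,
                       effective_N = NULL)
}

#' Match estimated sources to reference sources by exhaustive permutation
#'
#' ICA recovers sources up to permutation and sign. This helper finds, by
#' exhaustive search over all Q! permutations, the assignment of estimated
#' to reference rows maximizing the summed absolute Pearson correlation,
#' and returns the permutation together with the matched correlations.
#' `perm[k]` is the estimated row assigned to reference row k.
#'
#' @param est Q x N matrix (or [eeg_trial()]) of estimated sources.
#' @param ref Q x N matrix (or [eeg_trial()]) of reference sources.
#' @return List with `perm` (integer vector), `correlations` (signed, per
#'   reference row) and `mean_abs_cor`.
#' @export
match_sources <- function(est, ref) {
  E <- if (inherits(est, "eeg_trial")) est$data else as.matrix(est)
  R <- if (inherits(ref, "eeg_trial")) ref$data else as.matrix(ref)
  q <- nrow(R)
  if (nrow(E) != q || ncol(E) != ncol(R))
    stop("estimated and reference sources must have matching dimensions")
  cc <- stats::cor(t(R), t(E))               # cc[k, j] = cor(ref k, est j)
  perms <- all_permutations(q)
  score <- apply(perms, 1L, function(p) sum(abs(cc[cbind(seq_len(q), p)])))
  best <- unname(perms[which.max(score), ])
  r <- cc[cbind(seq_len(q), best)]
  list(perm = best, correlations = r, mean_abs_cor = mean(abs(r)))
}

# all permutations of 1..n as rows (n small)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (k in seq_len(n)) {
    block <- cbind(k, matrix(ifelse(sub >= k, sub + 1L, sub), nrow(sub)))
    out <- rbind(out, block)
  }
  out
}
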