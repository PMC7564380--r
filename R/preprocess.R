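#' Preprocess a scalp EEG trial
#'
#' Standard conditioning before network analysis: anti-aliased decimation to
#' the target rate (125 Hz by default), zero-phase (forward-backward)
#' Butterworth band-pass filtering, and per-channel normalization to zero
#' mean and unit variance. The anti-aliasing low-pass cuts at 0.8 times the
#' target Nyquist frequency; the forward-backward pass doubles the
#' effective filter order and cancels the phase response.
#'
#' @param trial An [eeg_trial()] (or [eeg_dataset()], processed trial-wise).
#' @param target_fs Target sampling rate in Hz (default 125). Trials already
#'   at the target rate are not resampled.
#' @param band Band-pass cutoff frequencies in Hz (default `c(0.5, 42)`);
#'   `NULL` skips filtering.
#' @param butter_order Butterworth order per pass (default 4).
#' @param normalize Z-score each channel after filtering (default TRUE).
#' @return The preprocessed object of the same kind.
#' @export
preprocess <- function(trial, target_fs = 125, band = c(0.5, 42),
                       butter_order = 4L, normalize = TRUE) {
  if (inherits(trial, "eeg_dataset")) {
    trials <- lapply(trial$trials, preprocess, target_fs = target_fs,
                     band = band, butter_order = butter_order,
                     normalize = normalize)
    return(eeg_dataset(trials, classes = trial$classes))
  }
  stopifnot(inherits(trial, "eeg_trial"))
  x <- trial$data
  fs <- trial$fs
  if (fs < target_fs) stop("sampling rate ", fs, " Hz below the target ",
                           target_fs, " Hz")
  if (fs > target_fs) {
    r <- fs / target_fs
    if (abs(r - round(r)) > 1e-9) {
      warning("fs = ", fs, " is not an integer multiple of ", target_fs,
              " Hz; using polyphase resampling")
      x <- t(apply(x, 1L, function(ch)
        signal::resample(ch, p = round(target_fs), q = round(fs))))
    } else {
      r <- round(r)
      aa <- signal::butter(8L, 0.8 / r, type = "low")
      x <- t(apply(x, 1L, function(ch)
        signal::filtfilt(aa, ch)[seq(1L, length(ch), by = r)]))
    }
    fs <- target_fs
  }
  if (ncol(x) < 12L * (butter_order + 1L))
    stop("trial too short for stable zero-phase filtering")
  if (!is.null(band)) {
    bf <- signal::butter(butter_order, band / (fs / 2), type = "pass")
    x <- t(apply(x, 1L, function(ch) signal::filtfilt(bf, ch)))
  }
  if (normalize) {
    x <- x - rowMeans(x)
    sdv <- sqrt(rowMeans(x^2))
    if (any(sdv == 0)) stop("zero-variance channel after filtering")
    x <- x / sdv
  }
  eeg_trial(x, fs = fs, class_label = trial$class_label,
            trial_id = trial$trial_id, channel_names = trial$channel_names)
}
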