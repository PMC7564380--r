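#' Construct a single EEG trial
#'
#' A trial is a channel-by-sample numeric matrix with a sampling rate, a
#' class label (experimental condition) and an identifier. All downstream
#' operations (spatial filtering, VAR modeling, source reconstruction)
#' act on this container.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param fs Sampling rate in Hz.
#' @param class_label Condition label (character scalar).
#' @param trial_id Opaque identifier (character scalar).
#' @param channel_names Optional character vector of channel names; defaults
#'   to `ch1..chD`.
#' @return An object of class `eeg_trial`.
#' @export
eeg_trial <- function(data, fs, class_label = "h1", trial_id = "t1",
                      channel_names = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data) || nrow(data) < 1L || ncol(data) < 1L)
    stop("trial data must be a non-empty numeric matrix (channels x samples)")
  if (!all(is.finite(data)))
    stop("trial '", trial_id, "' contains non-finite values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar (Hz)")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stop("channel_names length must match the number of rows")
  structure(
    list(data = data, fs = fs, class_label = as.character(class_label),
         trial_id = as.character(trial_id), channel_names = channel_names),
    class = "eeg_trial")
}

#' @export
print.eeg_trial <- function(x, ...) {
  cat(sprintf("<eeg_trial '%s'> %d channels x %d samples @ %g Hz, class '%s'\n",
              x$trial_id, nrow(x$data), ncol(x$data), x$fs, x$class_label))
  invisible(x)
}

#' Construct a two-class EEG dataset
#'
#' Bundles trials recorded under exactly two experimental conditions.
#' All trials must share channel count and sampling rate.
#'
#' @param trials List of [eeg_trial()] objects.
#' @param classes Optional character vector of the two class labels; inferred
#'   from the trials when omitted.
#' @return An object of class `eeg_dataset` with elements `trials`,
#'   `classes`, `channel_names`, `n_channels`, `fs` and per-class counts.
#' @export
eeg_dataset <- function(trials, classes = NULL) {
  if (length(trials) < 2L) stop("need at least one trial per class")
  stopifnot(all(vapply(trials, inherits, logical(1), "eeg_trial")))
  d <- vapply(trials, function(t) nrow(t$data), integer(1))
  fs <- vapply(trials, function(t) t$fs, numeric(1))
  if (length(unique(d)) != 1L) stop("all trials must share the channel count")
  if (length(unique(fs)) != 1L) stop("all trials must share the sampling rate")
  labs <- vapply(trials, function(t) t$class_label, character(1))
  if (is.null(classes)) classes <- sort(unique(labs))
  if (length(classes) != 2L)
    stop("an eeg_dataset holds exactly two classes, got: ",
         paste(unique(labs), collapse = ", "))
  counts <- c(sum(labs == classes[1]), sum(labs == classes[2]))
  if (any(counts < 1L)) stop("each class needs at least one trial")
  structure(
    list(trials = trials, classes = classes,
         channel_names = trials[[1]]$channel_names,
         n_channels = d[1], fs = fs[1], counts = counts),
    class = "eeg_dataset")
}

#' @export
print.eeg_dataset <- function(x, ...) {
  cat(sprintf("<eeg_dataset> %d trials (%s: %d, %s: %d), %d channels @ %g Hz\n",
              length(x$trials), x$classes[1], x$counts[1],
              x$classes[2], x$counts[2], x$n_channels, x$fs))
  invisible(x)
}

#' Trials of one class
#'
#' @param dataset An [eeg_dataset()].
#' @param class_label One of the dataset's two class labels.
#' @return List of trials belonging to the class, in stored order.
#' @export
class_trials <- function(dataset, class_label) {
  stopifnot(inherits(dataset, "eeg_dataset"))
  if (!class_label %in% dataset$classes)
    stop("unknown class label: ", class_label)
  keep <- vapply(dataset$trials, function(t) t$class_label == class_label,
                 logical(1))
  dataset$trials[keep]
}

#' Write a dataset as delimited-text matrices plus a JSON manifest
#'
#' One CSV file per trial (rows = channels, first row = channel names) and a
#' `manifest.json` recording class labels, sampling rate and file names.
#'
#' @param dataset An [eeg_dataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "eeg_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  entries <- lapply(dataset$trials, function(tr) {
    file <- paste0(tr$trial_id, ".csv")
    df <- as.data.frame(t(tr$data))
    names(df) <- tr$channel_names
    utils::write.csv(df, file.path(dir, file), row.names = FALSE)
    list(trial_id = tr$trial_id, class = tr$class_label, fs = tr$fs,
         file = file)
  })
  manifest <- list(classes = as.list(dataset$classes),
                   channel_names = as.list(dataset$channel_names),
                   fs = dataset$fs, trials = entries)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing `manifest.json` and the trial CSV files.
#' @return An [eeg_dataset()].
#' @export
read_dataset <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(path, simplifyVector = TRUE)
  trials <- lapply(seq_len(nrow(manifest$trials)), function(i) {
    e <- manifest$trials[i, ]
    df <- utils::read.csv(file.path(dir, e$file), check.names = FALSE)
    eeg_trial(t(as.matrix(df)), fs = e$fs, class_label = e$class,
              trial_id = e$trial_id, channel_names = names(df))
  })
  eeg_dataset(trials, classes = manifest$classes)
}
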