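#' Labeled multichannel EEG trials for one session
#'
#' A `trial_set` is the pipeline's unit of I/O: a numeric array of
#' channels x samples x trials together with its sampling rate, montage,
#' per-trial class labels and artifact flags.
#'
#' @param data numeric array, channels x samples x trials (microvolts).
#' @param fs sampling frequency in Hz.
#' @param montage character vector of unique channel labels, one per row
#'   of `data`, in recording order.
#' @param labels class label per trial (coerced to character).
#' @param artifact_flags logical per trial; flagged trials are excluded by
#'   [drop_artifact_trials()]. Defaults to all `FALSE`.
#' @param session_id identifier for the recording session.
#' @param time_zero trial-relative time (s) of sample 1; 0 means the trial
#'   array starts at trial onset.
#'
#' @return An object of class `trial_set`.
#' @seealso [extract_epoch()], [preprocess_trials()], [write_trialset()]
#' @export
trial_set <- function(data, fs, montage, labels,
                      artifact_flags = NULL, session_id = "S1",
                      time_zero = 0) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3-d array (channels x samples x trials)")
  }
  storage.mode(data) <- "double"
  n_trials <- dim(data)[3L]
  if (is.null(artifact_flags)) artifact_flags <- rep(FALSE, n_trials)
  x <- structure(
    list(data = data, fs = fs, montage = as.character(montage),
         labels = as.character(labels),
         artifact_flags = as.logical(artifact_flags),
         session_id = session_id, time_zero = as.numeric(time_zero)),
    class = "trial_set")
  validate_trial_set(x)
  x
}

validate_trial_set <- function(x) {
  d <- dim(x$data)
  if (length(x$montage) != d[1L]) stop("montage length != channel count")
  if (anyDuplicated(x$montage)) stop("montage labels must be unique")
  if (length(x$labels) != d[3L]) stop("labels length != trial count")
  if (length(x$artifact_flags) != d[3L]) stop("artifact_flags length != trial count")
  if (!is.numeric(x$fs) || length(x$fs) != 1L || x$fs <= 0) stop("fs must be a positive scalar")
  invisible(x)
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<trial_set> session %s: %d channels x %d samples x %d trials @ %g Hz\n",
              x$session_id, d[1L], d[2L], d[3L], x$fs))
  tab <- table(x$labels)
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  artifact-flagged trials: %d\n", sum(x$artifact_flags)))
  invisible(x)
}

#' Windowed, preprocessed epochs
#'
#' An `epoch_set` holds the analysis window of each clean trial after
#' preprocessing. Structure mirrors [trial_set()] plus the analysis
#' `window` (seconds, trial-relative, half-open).
#'
#' @param data channels x samples x epochs array.
#' @param fs sampling rate, Hz.
#' @param montage channel labels.
#' @param labels class per epoch.
#' @param window numeric length-2, `(start_s, end_s)`.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, montage, labels, window) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3-d array (channels x samples x epochs)")
  }
  storage.mode(data) <- "double"
  x <- structure(
    list(data = data, fs = fs, montage = as.character(montage),
         labels = as.character(labels), window = as.numeric(window)),
    class = "epoch_set")
  d <- dim(data)
  if (length(x$montage) != d[1L]) stop("montage length != channel count")
  if (length(x$labels) != d[3L]) stop("labels length != epoch count")
  x
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d channels x %d samples x %d epochs @ %g Hz, window [%g, %g) s\n",
              d[1L], d[2L], d[3L], x$fs, x$window[1L], x$window[2L]))
  invisible(x)
}

#' Write / read the portable trial-tensor container
#'
#' Serializes a [trial_set()] (data tensor plus all metadata) to a single
#' portable file using R's native serialization. The round trip is
#' bit-identical for both data and metadata.
#'
#' @param ts a `trial_set`.
#' @param path file path.
#' @return `write_trialset()` returns `path` invisibly; `read_trialset()`
#'   returns the restored `trial_set`.
#' @export
write_trialset <- function(ts, path) {
  validate_trial_set(ts)
  saveRDS(ts, path, version = 3)
  invisible(path)
}

#' @rdname write_trialset
#' @export
read_trialset <- function(path) {
  ts <- readRDS(path)
  if (!inherits(ts, "trial_set")) stop("file does not contain a trial_set")
  validate_trial_set(ts)
  ts
}
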