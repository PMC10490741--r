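#' Zero-phase Butterworth band-pass filter
#'
#' Applies an order-`order` Butterworth band-pass twice, once forward and
#' once in reverse (a filtfilt pass), so the output has zero phase
#' distortion and the effective magnitude response is the squared one-pass
#' response. Edges are handled by odd-symmetric reflection padding, which
#' keeps startup transients off the retained samples.
#'
#' @param x numeric vector, a single-channel time series.
#' @param fs sampling rate, Hz.
#' @param low,high band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param order filter order of each pass (default 4).
#' @return Filtered series, same length as `x`.
#' @export
bandpass_zero_phase <- function(x, fs, low = 8, high = 30, order = 4) {
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("band edges must satisfy 0 < low < high < fs/2")
  }
  bt <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  filtfilt_reflect(bt$b, bt$a, x)
}

# Forward-backward IIR filtering with odd-symmetric reflection padding of
# length 3 * (filter state length), then cropping back to the original
# extent. Mirrors standard filtfilt practice.
filtfilt_reflect <- function(b, a, x) {
  nfilt <- max(length(a), length(b))
  padlen <- 3L * (nfilt - 1L)
  n <- length(x)
  if (n <= padlen) {
    stop(sprintf("series too short for stable forward-backward filtering (need > %d samples)", padlen))
  }
  left <- 2 * x[1L] - x[seq(padlen + 1L, 2L, by = -1L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - padlen, by = -1L)]
  xp <- c(left, x, right)
  y <- signal::filter(b, a, xp)
  y <- rev(signal::filter(b, a, rev(y)))
  y[(padlen + 1L):(padlen + n)]
}

#' Baseline correction
#'
#' Subtracts, per channel, the mean over a baseline window from the whole
#' trial, removing slow drifts and DC offsets.
#'
#' @param trial numeric matrix, channels x samples.
#' @param baseline_window numeric length-2, `(start_s, end_s)` relative to
#'   the trial's time axis.
#' @param fs sampling rate, Hz.
#' @param time_zero time (s) of sample 1 (default 0).
#' @return The corrected channels x samples matrix.
#' @export
baseline_correct <- function(trial, baseline_window, fs, time_zero = 0) {
  idx <- window_samples(baseline_window, fs, ncol(trial), time_zero)
  if (length(idx) == 0L) stop("empty baseline window")
  trial - rowMeans(trial[, idx, drop = FALSE])
}

#' Common average reference
#'
#' Subtracts the instantaneous cross-channel mean from every channel at
#' every sample.
#'
#' @param X numeric matrix, channels x samples.
#' @return Re-referenced matrix with zero cross-channel mean at each sample.
#' @export
car_reference <- function(X) {
  if (nrow(X) < 2L) stop("CAR requires at least 2 channels")
  sweep(X, 2L, colMeans(X))
}

# Half-open [start, end) sample index range, 0-based sample times, 1-based
# R indices. Errors if the window leaves the trial extent.
window_samples <- function(window, fs, n_samples, time_zero = 0) {
  start <- round((window[1L] - time_zero) * fs)
  end <- round((window[2L] - time_zero) * fs)
  if (end <= start) stop("window must have positive duration")
  if (start < 0 || end > n_samples) stop("window outside trial extent")
  seq.int(start + 1L, end)
}

#' Extract the analysis epoch from each trial
#'
#' Cuts the half-open window `[start, end)` (in seconds relative to trial
#' onset) out of every trial. With the defaults used for motor-imagery
#' analysis, `(2.5, 5.0)` s at 250 Hz, each epoch has exactly 625 samples.
#'
#' @param ts a [trial_set()].
#' @param window numeric length-2 `(start_s, end_s)`, default `c(2.5, 5)`.
#' @return An [epoch_set()].
#' @export
extract_epoch <- function(ts, window = c(2.5, 5)) {
  validate_trial_set(ts)
  idx <- window_samples(window, ts$fs, dim(ts$data)[2L], ts$time_zero)
  epoch_set(ts$data[, idx, , drop = FALSE], fs = ts$fs,
            montage = ts$montage, labels = ts$labels, window = window)
}

#' Remove artifact-flagged trials
#'
#' Drops every trial whose artifact flag is set, keeping labels and flags
#' aligned with the retained trials.
#'
#' @param ts a [trial_set()].
#' @return A `trial_set` containing only clean trials.
#' @export
drop_artifact_trials <- function(ts) {
  validate_trial_set(ts)
  keep <- !ts$artifact_flags
  trial_set(ts$data[, , keep, drop = FALSE], fs = ts$fs, montage = ts$montage,
            labels = ts$labels[keep], artifact_flags = ts$artifact_flags[keep],
            session_id = ts$session_id, time_zero = ts$time_zero)
}

#' Full preprocessing chain for one session
#'
#' Applies, in order: artifact-trial exclusion, zero-phase Butterworth
#' band-pass (default 8-30 Hz, covering the mu and beta bands), baseline
#' correction over the fixation period, common average re-referencing,
#' and extraction of the motor-imagery analysis epoch.
#'
#' @param ts a [trial_set()].
#' @param band numeric length-2 band edges in Hz (default `c(8, 30)`).
#' @param order Butterworth order per pass (default 4).
#' @param baseline_window baseline interval in s (default `c(0, 2)`, the
#'   fixation period).
#' @param window analysis epoch in s (default `c(2.5, 5)`).
#' @return An [epoch_set()] of clean, filtered, CAR-referenced epochs.
#' @export
preprocess_trials <- function(ts, band = c(8, 30), order = 4,
                              baseline_window = c(0, 2),
                              window = c(2.5, 5)) {
  ts <- drop_artifact_trials(ts)
  d <- dim(ts$data)
  out <- ts$data
  for (tr in seq_len(d[3L])) {
    m <- out[, , tr]
    for (ch in seq_len(d[1L])) {
      m[ch, ] <- bandpass_zero_phase(m[ch, ], ts$fs, band[1L], band[2L], order)
    }
    m <- baseline_correct(m, baseline_window, ts$fs, ts$time_zero)
    m <- car_reference(m)
    out[, , tr] <- m
  }
  ts$data <- out
  extract_epoch(ts, window)
}
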