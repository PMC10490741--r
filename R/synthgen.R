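#' Standard 22-channel motor-imagery montage
#'
#' Channel labels of the widely used 22-electrode cue-based motor-imagery
#' montage (BCI Competition IV dataset IIa layout), in recording order.
#'
#' @return Character vector of 22 labels.
#' @export
mi_montage <- function() {
  c("Fz", "FC3", "FC1", "FCz", "FC2", "FC4",
    "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
    "CP3", "CP1", "CPz", "CP2", "CP4",
    "P1", "Pz", "P2", "POz")
}

#' Cue-based motor-imagery paradigm configuration
#'
#' Describes the recording paradigm the synthetic generator emulates:
#' 7.5 s cue-based trials sampled at 250 Hz, four balanced classes (left
#' hand, right hand, feet, tongue) with 72 trials each per session, and a
#' motor-imagery analysis window of 2.5-5 s after trial onset.
#'
#' @param n_channels channel count (default 22).
#' @param fs sampling rate in Hz (default 250); must exceed twice the
#'   highest generated oscillation frequency.
#' @param trial_duration trial length in seconds (default 7.5).
#' @param mi_window motor-imagery window `(start_s, end_s)` inside the
#'   trial (default `c(2.5, 5)`).
#' @param classes ordered class labels (default `c("LH","RH","F","T")`).
#' @param trials_per_class trials per class per session (default 72).
#' @param n_sessions number of sessions (default 2).
#' @param artifact_rate fraction of trials flagged as artifacts, in
#'   \[0, 1\] (default 0).
#' @param noise_sd standard deviation of the background noise components
#'   in signal units (default 0.5).
#' @param montage channel labels; defaults to [mi_montage()] when
#'   `n_channels == 22`, else `ch1..chN`.
#' @return A list of class `paradigm_config`.
#' @export
paradigm_config <- function(n_channels = 22, fs = 250, trial_duration = 7.5,
                            mi_window = c(2.5, 5),
                            classes = c("LH", "RH", "F", "T"),
                            trials_per_class = 72, n_sessions = 2,
                            artifact_rate = 0, noise_sd = 0.5,
                            montage = NULL) {
  if (is.null(montage)) {
    montage <- if (n_channels == 22L) mi_montage() else paste0("ch", seq_len(n_channels))
  }
  if (length(montage) != n_channels) stop("montage length != n_channels")
  if (mi_window[1L] < 0 || mi_window[2L] > trial_duration ||
      mi_window[1L] >= mi_window[2L]) {
    stop("mi_window must lie inside [0, trial_duration]")
  }
  if (artifact_rate < 0 || artifact_rate > 1) stop("artifact_rate must be in [0, 1]")
  if (fs <= 2 * 30) stop("fs must exceed twice the highest generated oscillation frequency (30 Hz)")
  structure(list(n_channels = as.integer(n_channels), fs = fs,
                 trial_duration = trial_duration, mi_window = mi_window,
                 classes = as.character(classes),
                 trials_per_class = as.integer(trials_per_class),
                 n_sessions = as.integer(n_sessions),
                 artifact_rate = artifact_rate, noise_sd = noise_sd,
                 montage = as.character(montage)),
            class = "paradigm_config")
}

#' Class-dependent generative signature
#'
#' Defines what makes one motor-imagery class statistically different from
#' another in the generated EEG: channel-local event-related
#' desynchronization (ERD; a fractional drop of band-limited oscillation
#' amplitude on specific channels during the MI window) and inter-channel
#' phase-lag coupling (a shared band-limited phase process injected into
#' both channels of a pair with a fixed lag).
#'
#' @param erd_channels channel labels whose oscillation desynchronizes.
#' @param erd_band `(low, high)` Hz of the desynchronizing rhythm
#'   (default mu band, `c(8, 12)`).
#' @param erd_depth fractional amplitude drop in \[0, 1\] during the MI
#'   window (default 0.5).
#' @param coupling_pairs list of [coupling_pair()] entries.
#' @param carrier_freq center frequency (Hz) of the ERD-modulated
#'   oscillation (default 10).
#' @param coupling_freq center frequency (Hz) of the shared coupling
#'   process (default 20, beta band).
#' @return A list of class `class_signature`.
#' @export
class_signature <- function(erd_channels = character(), erd_band = c(8, 12),
                            erd_depth = 0.5, coupling_pairs = list(),
                            carrier_freq = 10, coupling_freq = 20) {
  for (cp in coupling_pairs) {
    if (cp$strength < 0 || cp$strength > 1) stop("coupling_strength must be in [0, 1]")
    if (cp$lag <= -pi || cp$lag > pi) stop("phase_lag must be in (-pi, pi]")
  }
  if (erd_depth < 0 || erd_depth > 1) stop("erd_depth must be in [0, 1]")
  structure(list(erd_channels = as.character(erd_channels),
                 erd_band = erd_band, erd_depth = erd_depth,
                 coupling_pairs = coupling_pairs,
                 carrier_freq = carrier_freq, coupling_freq = coupling_freq),
            class = "class_signature")
}

#' @param ch_i,ch_j channel labels of the coupled pair.
#' @param lag phase lag in radians, in `(-pi, pi]`.
#' @param strength coupling strength in \[0, 1\].
#' @rdname class_signature
#' @export
coupling_pair <- function(ch_i, ch_j, lag = pi / 4, strength = 1) {
  list(ch_i = as.character(ch_i), ch_j = as.character(ch_j),
       lag = lag, strength = strength)
}

#' Default class signatures for the four-class paradigm
#'
#' Hand imagery desynchronizes the contralateral central channel (RH on
#' C3, LH on C4), foot imagery the midline Cz, tongue imagery the
#' fronto-central midline; each class additionally carries one
#' class-specific phase-coupled pair. These signatures are generative
#' stand-ins chosen to mirror classic sensorimotor ERD topography; they
#' are not fitted to any recorded data.
#'
#' @param coupling_strength strength shared by all planted pairs
#'   (default 0.8).
#' @param erd_depth ERD depth shared by all classes (default 0.5).
#' @return Named list of [class_signature()]s for LH, RH, F, T.
#' @export
default_signatures <- function(coupling_strength = 0.8, erd_depth = 0.5) {
  list(
    LH = class_signature(erd_channels = c("C4", "C2"), erd_depth = erd_depth,
      coupling_pairs = list(coupling_pair("FC4", "CP4", lag = pi / 4, strength = coupling_strength))),
    RH = class_signature(erd_channels = c("C3", "C1"), erd_depth = erd_depth,
      coupling_pairs = list(coupling_pair("FC3", "CP3", lag = -pi / 3, strength = coupling_strength))),
    F = class_signature(erd_channels = "Cz", erd_depth = erd_depth,
      coupling_pairs = list(coupling_pair("CP1", "CP2", lag = pi / 2, strength = coupling_strength))),
    T = class_signature(erd_channels = "FCz", erd_depth = erd_depth,
      coupling_pairs = list(coupling_pair("FC1", "FC2", lag = 2 * pi / 5, strength = coupling_strength)))
  )
}

# Run code under a local RNG seed without disturbing the caller's stream.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Smooth 0->1->0 envelope over the MI window with raised-cosine ramps.
mi_envelope <- function(nt, fs, window, ramp = 0.2) {
  t <- (seq_len(nt) - 1L) / fs
  e <- numeric(nt)
  r <- min(ramp, (window[2L] - window[1L]) / 2)
  up <- t >= window[1L] & t < window[1L] + r
  on <- t >= window[1L] + r & t < window[2L] - r
  dn <- t >= window[2L] - r & t < window[2L]
  e[up] <- 0.5 * (1 - cos(pi * (t[up] - window[1L]) / r))
  e[on] <- 1
  e[dn] <- 0.5 * (1 + cos(pi * (t[dn] - (window[2L] - r)) / r))
  e
}

# Narrow-band oscillation with per-trial frequency jitter inside `band`,
# phase diffusion and mild amplitude modulation. The frequency jitter is
# essential: independent channels at one shared fixed frequency would
# hold a near-constant phase difference over a short epoch and show
# spurious synchrony.
nb_oscillation <- function(nt, fs, band, amp = 1, phase_jitter = 0.1) {
  freq <- stats::runif(1, band[1L], band[2L])
  theta <- 2 * pi * freq * (seq_len(nt) - 1L) / fs +
    stats::runif(1, 0, 2 * pi) + cumsum(stats::rnorm(nt, 0, phase_jitter))
  am <- 1 + 0.2 * as.numeric(stats::filter(stats::rnorm(nt), 0.99, "recursive")) / 7
  amp * am * cos(theta)
}

#' Generate one synthetic motor-imagery trial
#'
#' Every channel receives 1/f-like background noise (white plus low-order
#' autoregressive), a mu-band oscillation at the class's carrier
#' frequency and a weaker beta oscillation. During the MI window the
#' carrier amplitude on the signature's ERD channels is scaled by
#' `(1 - erd_depth)`, and each coupling pair receives a shared
#' band-limited phase process injected into both channels with the stated
#' lag, amplitude-mixed by the coupling strength.
#'
#' @param class_label one of the configured classes; must have a
#'   signature.
#' @param signatures named list of [class_signature()]s.
#' @param cfg a [paradigm_config()].
#' @param seed optional integer; fixing it makes the trial reproducible
#'   without disturbing the caller's RNG stream.
#' @return Numeric matrix, channels x samples, rownames = montage.
#' @export
generate_trial <- function(class_label, signatures, cfg, seed = NULL) {
  if (!class_label %in% names(signatures)) {
    stop(sprintf("unknown class label '%s'", class_label))
  }
  sig <- signatures[[class_label]]
  miss <- setdiff(c(sig$erd_channels,
                    unlist(lapply(sig$coupling_pairs, function(p) c(p$ch_i, p$ch_j)))),
                  cfg$montage)
  if (length(miss)) {
    stop(sprintf("signature references channel(s) not in montage: %s",
                 paste(unique(miss), collapse = ", ")))
  }
  with_local_seed(seed, {
    nt <- round(cfg$trial_duration * cfg$fs)
    nc <- cfg$n_channels
    env <- mi_envelope(nt, cfg$fs, cfg$mi_window)
    X <- matrix(0, nc, nt, dimnames = list(cfg$montage, NULL))
    erd_idx <- match(sig$erd_channels, cfg$montage)
    for (c_i in seq_len(nc)) {
      pink <- as.numeric(stats::filter(stats::rnorm(nt), 0.95, "recursive")) *
        cfg$noise_sd * 0.35
      white <- stats::rnorm(nt, 0, cfg$noise_sd)
      cb <- c(max(sig$erd_band[1L], sig$carrier_freq - 2),
              min(sig$erd_band[2L], sig$carrier_freq + 2))
      carrier <- nb_oscillation(nt, cfg$fs, cb, amp = 1)
      if (c_i %in% erd_idx) {
        carrier <- carrier * (1 - sig$erd_depth * env)
      }
      beta <- nb_oscillation(nt, cfg$fs, c(18, 22), amp = 0.4)
      X[c_i, ] <- pink + white + carrier + beta
    }
    for (cp in sig$coupling_pairs) {
      theta <- 2 * pi * sig$coupling_freq * (seq_len(nt) - 1L) / cfg$fs +
        stats::runif(1, 0, 2 * pi) + cumsum(stats::rnorm(nt, 0, 0.05))
      # at full strength the shared process dominates the channels' phase
      # in its band, forcing a near-constant observed lag
      amp_c <- 3 * cp$strength * env
      i <- match(cp$ch_i, cfg$montage); j <- match(cp$ch_j, cfg$montage)
      X[i, ] <- X[i, ] + amp_c * cos(theta)
      X[j, ] <- X[j, ] + amp_c * cos(theta - cp$lag)
    }
    X
  })
}

#' Generate a full synthetic session
#'
#' Produces `trials_per_class x |classes|` trials in randomized order with
#' balanced class counts, artifact flags drawn at the configured rate, and
#' all metadata populated. The same seed always yields a bit-identical
#' session.
#'
#' @param cfg a [paradigm_config()].
#' @param signatures named list of [class_signature()]s covering every
#'   configured class.
#' @param seed integer session seed; all randomness flows from it.
#' @param session_id identifier stored in the result (default `"S1"`).
#' @return A [trial_set()] with attribute `seed`.
#' @export
generate_session <- function(cfg, signatures = default_signatures(),
                             seed = 1, session_id = "S1") {
  missing_sig <- setdiff(cfg$classes, names(signatures))
  if (length(missing_sig)) {
    stop(sprintf("no signature for class(es): %s", paste(missing_sig, collapse = ", ")))
  }
  with_local_seed(seed, {
    n <- cfg$trials_per_class * length(cfg$classes)
    labels <- sample(rep(cfg$classes, each = cfg$trials_per_class))
    flags <- stats::runif(n) < cfg$artifact_rate
    trial_seeds <- sample.int(.Machine$integer.max - 1L, n)
    nt <- round(cfg$trial_duration * cfg$fs)
    data <- array(0, dim = c(cfg$n_channels, nt, n))
    for (k in seq_len(n)) {
      data[, , k] <- generate_trial(labels[k], signatures, cfg, seed = trial_seeds[k])
    }
    ts <- trial_set(data, fs = cfg$fs, montage = cfg$montage, labels = labels,
                    artifact_flags = flags, session_id = session_id,
                    time_zero = 0)
    attr(ts, "seed") <- seed
    ts
  })
}

#' Machine-readable description of the planted class structure
#'
#' Summarizes which channels/bands (ERD) and channel pairs (coupling)
#' separate which classes, for use as ground truth in recovery tests.
#' Classes whose signatures are identical are flagged as non-separable.
#'
#' @param signatures named list of [class_signature()]s.
#' @return List with data frames `erd` (class, channel, band, depth) and
#'   `coupling` (class, ch_i, ch_j, lag, strength), plus
#'   `nonseparable` (two-column data frame of class pairs).
#' @export
planted_truth <- function(signatures) {
  erd <- do.call(rbind, lapply(names(signatures), function(cl) {
    s <- signatures[[cl]]
    if (length(s$erd_channels) == 0L || s$erd_depth == 0) return(NULL)
    data.frame(class = cl, channel = s$erd_channels,
               band_low = s$erd_band[1L], band_high = s$erd_band[2L],
               depth = s$erd_depth)
  }))
  coupling <- do.call(rbind, lapply(names(signatures), function(cl) {
    s <- signatures[[cl]]
    rows <- Filter(function(p) p$strength > 0, s$coupling_pairs)
    if (length(rows) == 0L) return(NULL)
    do.call(rbind, lapply(rows, function(p) {
      data.frame(class = cl, ch_i = p$ch_i, ch_j = p$ch_j,
                 lag = p$lag, strength = p$strength)
    }))
  }))
  cls <- names(signatures)
  nonsep <- NULL
  if (length(cls) >= 2L) {
    for (a in seq_along(cls)) for (b in seq_along(cls)) {
      if (a < b && identical(unclass(signatures[[a]]), unclass(signatures[[b]]))) {
        nonsep <- rbind(nonsep, data.frame(class_a = cls[a], class_b = cls[b]))
      }
    }
  }
  empty_erd <- data.frame(class = character(), channel = character(),
                          band_low = numeric(), band_high = numeric(),
                          depth = numeric())
  empty_cpl <- data.frame(class = character(), ch_i = character(),
                          ch_j = character(), lag = numeric(), strength = numeric())
  empty_ns <- data.frame(class_a = character(), class_b = character())
  list(erd = if (is.null(erd)) empty_erd else erd,
       coupling = if (is.null(coupling)) empty_cpl else coupling,
       nonseparable = if (is.null(nonsep)) empty_ns else nonsep)
}
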