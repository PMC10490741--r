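# Shared small-scale fixtures. Everything is generated in code; the
# reduced montage / trial counts keep the suite fast while preserving the
# sensorimotor labels the channel subset logic expects.

small_montage <- function() {
  c("FC1", "FCz", "FC2", "C3", "Cz", "C4", "CP3", "CPz", "CP4", "Pz")
}

small_cfg <- function(trials_per_class = 12, ...) {
  paradigm_config(n_channels = 10, montage = small_montage(),
                  trials_per_class = trials_per_class, ...)
}

# class information only in phase coupling, on pairs outside the TIF
# channel subset used by small_scat_cfg()
coupling_only_signatures <- function(strength = 1) {
  list(
    LH = class_signature(erd_depth = 0, coupling_pairs = list(
      coupling_pair("CP3", "CPz", lag = pi / 4, strength = strength))),
    RH = class_signature(erd_depth = 0, coupling_pairs = list(
      coupling_pair("CPz", "CP4", lag = -pi / 3, strength = strength))),
    F = class_signature(erd_depth = 0, coupling_pairs = list(
      coupling_pair("FC1", "FC2", lag = pi / 2, strength = strength))),
    T = class_signature(erd_depth = 0, coupling_pairs = list(
      coupling_pair("CP3", "CP4", lag = 2 * pi / 5, strength = strength))))
}

# class information only in channel-local band power (ERD topography)
spectral_only_signatures <- function(depth = 0.6) {
  list(
    LH = class_signature(erd_channels = "C4", erd_depth = depth),
    RH = class_signature(erd_channels = "C3", erd_depth = depth),
    F = class_signature(erd_channels = "Cz", erd_depth = depth),
    T = class_signature(erd_channels = "FCz", erd_depth = depth))
}

# identical for every class: no planted information at all
null_signatures <- function() {
  base <- class_signature(erd_depth = 0)
  list(LH = base, RH = base, F = base, T = base)
}

small_scat_cfg <- function(fs = 250) {
  scattering_config(fs, channel_subset = c("C3", "Cz", "C4"))
}

small_grid <- function() {
  classifier_grid(cost = c(1, 32), gamma = c(0.001, 0.01),
                  n_features = c(20, 60))
}

# translated band-limited noise packet with content away from the epoch
# edges; used by the shift-invariance checks
shift_packet <- function(noise, shift, fs = 250, n = 625) {
  t <- (0:(n - 1)) / fs - shift
  noise[round(t * fs) + n / 2] * exp(-(t - 1.25)^2 / (2 * 0.35^2))
}

# one cached preprocessed session pair used by several test files
cached_sessions <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- small_cfg()
      sig <- coupling_only_signatures()
      cache <<- list(
        cfg = cfg, sig = sig,
        s1 = generate_session(cfg, sig, seed = 101, session_id = "S1"),
        s2 = generate_session(cfg, sig, seed = 102, session_id = "S2"))
    }
    cache
  }
})
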