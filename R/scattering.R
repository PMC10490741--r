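#' Configuration for the wavelet-scattering feature extractor
#'
#' The scattering cascade iterates wavelet convolution, complex modulus
#' and low-pass averaging to produce features invariant to translations
#' up to the invariance scale `T` (seconds). Defaults follow common
#' one-dimensional scattering practice: Morlet-type filters, 8 wavelets
#' per octave at order 1, 1 per octave at order 2, two orders.
#'
#' @param fs sampling rate, Hz.
#' @param invariance_scale invariance scale T in seconds (default 2).
#' @param orders maximum scattering order, 1 or 2 (default 2).
#' @param q integer length-2, wavelets per octave for orders 1 and 2
#'   (default `c(8, 1)`); must satisfy `Q1 >= Q2 >= 1`.
#' @param f_min lowest wavelet center frequency in Hz; default
#'   `fs / 2^J` with `J = round(log2(T * fs))`.
#' @param channel_subset channel selection spec passed to
#'   [select_channels()] by [tif_extract()] (default `"default11"`).
#' @return A list of class `scattering_config`.
#' @export
scattering_config <- function(fs, invariance_scale = 2, orders = 2,
                              q = c(8, 1), f_min = NULL,
                              channel_subset = "default11") {
  if (!orders %in% c(1L, 2L)) stop("orders must be 1 or 2")
  if (length(q) != 2L || q[1L] < q[2L] || q[2L] < 1) {
    stop("q must be (Q1, Q2) with Q1 >= Q2 >= 1")
  }
  J <- round(log2(invariance_scale * fs))
  if (is.null(f_min)) f_min <- fs / 2^J
  if (f_min >= fs / 2) stop("invariance scale too large: no wavelet fits below Nyquist")
  structure(list(fs = fs, invariance_scale = invariance_scale,
                 orders = as.integer(orders), q = as.integer(q),
                 J = J, f_min = f_min, channel_subset = channel_subset),
            class = "scattering_config")
}

#' Build the Morlet filter bank for a scattering configuration
#'
#' Center frequencies tile geometrically from `0.4 * fs` down to
#' `cfg$f_min` with Q1 (order 1) and Q2 (order 2) wavelets per octave.
#' Wavelets are zero-mean Gaussian band-pass (Morlet-type) filters defined
#' in the frequency domain on positive frequencies (analytic); the
#' low-pass averaging filter is a Gaussian of time support
#' `invariance_scale` (standard deviation T/4, so +/-2 sd spans T).
#' All band-pass responses are rescaled by a common factor so that the
#' Littlewood-Paley sum `|phi|^2 + sum |psi|^2` never exceeds 1, which
#' makes the whole cascade non-expansive.
#'
#' @param cfg a [scattering_config()].
#' @return A list of class `filter_bank` with per-order center
#'   frequencies/bandwidths, the low-pass width and the common scale.
#' @export
build_filter_bank <- function(cfg) {
  xi_max <- 0.4 * cfg$fs
  geom_freqs <- function(Q) {
    k <- 0L
    out <- numeric(0)
    repeat {
      xi <- xi_max * 2^(-k / Q)
      if (xi < cfg$f_min) break
      out <- c(out, xi)
      k <- k + 1L
    }
    out
  }
  bw <- function(xi, Q) xi * (2^(1 / Q) - 1) / 1.177
  xi1 <- geom_freqs(cfg$q[1L])
  xi2 <- geom_freqs(cfg$q[2L])
  if (length(xi1) == 0L) stop("no wavelet fits between f_min and Nyquist")
  sigma_t <- cfg$invariance_scale / 4               # seconds
  sigma_phi <- 1 / (2 * pi * sigma_t)               # Hz
  bank <- list(cfg = cfg,
               xi1 = xi1, sigma1 = bw(xi1, cfg$q[1L]),
               xi2 = xi2, sigma2 = bw(xi2, cfg$q[2L]),
               sigma_t = sigma_t, sigma_phi = sigma_phi,
               psi_scale = 1)
  lp <- lp_sum_raw(bank)
  if (max(lp) > 1) bank$psi_scale <- 1 / sqrt(max(lp))
  class(bank) <- "filter_bank"
  bank
}

# Gaussian band-pass profile with zero-mean (Morlet) correction.
psi_hat_profile <- function(f, xi, sigma) {
  g <- exp(-(f - xi)^2 / (2 * sigma^2))
  g - exp(-xi^2 / (2 * sigma^2)) * exp(-f^2 / (2 * sigma^2))
}

phi_hat_profile <- function(f, sigma_phi) exp(-f^2 / (2 * sigma_phi^2))

# Littlewood-Paley sum over [0, fs/2] before the common rescaling.
lp_sum_raw <- function(bank, n_points = 4096L) {
  f <- seq(0, bank$cfg$fs / 2, length.out = n_points)
  s <- phi_hat_profile(f, bank$sigma_phi)^2
  for (k in seq_along(bank$xi1)) {
    s <- s + psi_hat_profile(f, bank$xi1[k], bank$sigma1[k])^2
  }
  s
}

#' Littlewood-Paley sum of a filter bank
#'
#' Evaluates `|phi(f)|^2 + sum_k |psi_k(f)|^2` (after the bank's common
#' rescaling) on a dense grid over `[0, fs/2]`. A bank is admissible for a
#' non-expansive cascade when this never exceeds 1 (numerically, 1 plus a
#' small epsilon).
#'
#' @param bank a [build_filter_bank()] result.
#' @param n_points grid resolution (default 4096).
#' @return Data frame with columns `freq` and `lp`.
#' @export
littlewood_paley <- function(bank, n_points = 4096L) {
  f <- seq(0, bank$cfg$fs / 2, length.out = n_points)
  s <- phi_hat_profile(f, bank$sigma_phi)^2
  for (k in seq_along(bank$xi1)) {
    s <- s + (bank$psi_scale * psi_hat_profile(f, bank$xi1[k], bank$sigma1[k]))^2
  }
  data.frame(freq = f, lp = s)
}

# Reflection padding by mirror tiling; handles pad lengths beyond the
# signal length.
reflect_pad <- function(x, left, right) {
  n <- length(x)
  tile <- c(x, rev(x))  # period 2n, even reflection
  idx_left <- ((-(left:1)) %% (2 * n)) + 1L
  idx_right <- ((n + seq_len(right) - 1L) %% (2 * n)) + 1L
  c(tile[idx_left], x, tile[idx_right])
}

# Precompute everything that depends only on the epoch length: padded
# length, materialized frequency responses, second-order path table and
# the averaging weight matrix. The epoch is tiled into
# floor(n / (T * fs)) frames (at least one); each frame's weight column
# is its uniform window convolved with the Gaussian low-pass and
# normalized to sum 1, so each path's low-passed output is reduced to
# one time average per invariance window in a single matrix product.
# With the default T = 2 s on a 2.5 s epoch this is one scalar per path.
scatter_plan <- function(n_samples, bank) {
  cfg <- bank$cfg
  pad <- ceiling(cfg$invariance_scale * cfg$fs)
  M <- stats::nextn(n_samples + 2L * pad, 2L)
  left <- (M - n_samples) %/% 2L
  right <- M - n_samples - left
  f <- (seq_len(M) - 1L) / M * cfg$fs
  pos <- f <= cfg$fs / 2  # analytic filters live on nonnegative freqs
  mat_psi <- function(xi, sigma) {
    P <- matrix(0, M, length(xi))
    for (k in seq_along(xi)) {
      P[pos, k] <- bank$psi_scale * psi_hat_profile(f[pos], xi[k], sigma[k])
    }
    P
  }
  Psi1 <- mat_psi(bank$xi1, bank$sigma1)
  Psi2 <- if (cfg$orders >= 2L) mat_psi(bank$xi2, bank$sigma2) else NULL
  # Gaussian averaging kernel (time domain, circular, normalized).
  tau <- pmin(seq_len(M) - 1L, M - (seq_len(M) - 1L))
  g <- exp(-(tau / cfg$fs)^2 / (2 * bank$sigma_t^2))
  g <- g / sum(g)
  G <- stats::fft(g)
  n_frames <- max(1L, floor(n_samples / (cfg$invariance_scale * cfg$fs)))
  bounds <- round(seq(0L, n_samples, length.out = n_frames + 1L))
  W <- matrix(0, M, n_frames)
  for (r in seq_len(n_frames)) {
    ind <- numeric(M)
    ind[left + seq.int(bounds[r] + 1L, bounds[r + 1L])] <- 1
    wr <- Re(stats::fft(stats::fft(ind) * G, inverse = TRUE)) / M
    wr <- pmax(wr, 0)
    W[, r] <- wr / sum(wr)
  }
  # frequency-decreasing second-order paths: xi2 strictly below xi1
  paths2 <- NULL
  if (cfg$orders >= 2L && length(bank$xi2)) {
    paths2 <- which(outer(bank$xi2, bank$xi1, `<`), arr.ind = TRUE)
    colnames(paths2) <- c("k2", "k1")
  }
  path_table <- data.frame(order = 0L, f1 = NA_real_, f2 = NA_real_)
  if (length(bank$xi1)) {
    path_table <- rbind(path_table,
      data.frame(order = 1L, f1 = bank$xi1, f2 = NA_real_))
  }
  if (!is.null(paths2) && nrow(paths2)) {
    path_table <- rbind(path_table,
      data.frame(order = 2L, f1 = bank$xi1[paths2[, "k1"]],
                 f2 = bank$xi2[paths2[, "k2"]]))
  }
  list(bank = bank, n = n_samples, M = M, left = left, right = right,
       Psi1 = Psi1, Psi2 = Psi2, W = W, n_frames = n_frames,
       paths2 = paths2, path_table = path_table)
}

scatter_apply <- function(x, plan) {
  if (!all(is.finite(x))) stop("non-finite input")
  if (length(x) != plan$n) stop("epoch length does not match plan")
  xp <- reflect_pad(x, plan$left, plan$right)
  X <- stats::fft(xp)
  s0 <- drop(crossprod(plan$W, xp))          # one average per frame
  s1 <- numeric(0)
  s2 <- numeric(0)
  if (ncol(plan$Psi1)) {
    U1 <- Mod(stats::mvfft(plan$Psi1 * X, inverse = TRUE)) / plan$M
    s1 <- as.vector(crossprod(plan$W, U1))   # frames vary fastest per path
    if (!is.null(plan$paths2) && nrow(plan$paths2)) {
      s2 <- matrix(0, plan$n_frames, nrow(plan$paths2))
      for (k1 in unique(plan$paths2[, "k1"])) {
        rows <- which(plan$paths2[, "k1"] == k1)
        F2 <- stats::fft(U1[, k1])
        V <- Mod(stats::mvfft(plan$Psi2[, plan$paths2[rows, "k2"], drop = FALSE] * F2,
                              inverse = TRUE)) / plan$M
        s2[, rows] <- crossprod(plan$W, V)
      }
      s2 <- as.vector(s2)
    }
  }
  c(s0, s1, s2)
}

#' Scattering coefficients of a single-channel epoch
#'
#' Computes the time-averaged scattering coefficients of `x`: order 0 is
#' the low-pass average of the signal; order 1 the averaged modulus of
#' each wavelet convolution; order 2 the averaged modulus of a second
#' wavelet convolution applied to each first-order modulus, kept only for
#' frequency-decreasing paths. Because the analysis epoch barely exceeds
#' the invariance scale, each path's low-passed output is reduced to a
#' single scalar, its time mean over the epoch.
#'
#' @param x numeric vector, single-channel epoch.
#' @param bank a [build_filter_bank()] result.
#' @return Numeric vector of coefficients with attribute `paths` (data
#'   frame: order, first/second-order center frequencies).
#' @export
scatter <- function(x, bank) {
  plan <- scatter_plan(length(x), bank)
  out <- scatter_apply(x, plan)
  attr(out, "paths") <- expand_path_table(plan)
  out
}

# one row per emitted coefficient: paths expanded by frame index
expand_path_table <- function(plan) {
  pt <- plan$path_table[rep(seq_len(nrow(plan$path_table)),
                            each = plan$n_frames), , drop = FALSE]
  pt$frame <- rep(seq_len(plan$n_frames), nrow(plan$path_table))
  rownames(pt) <- NULL
  pt
}

#' Resolve a channel-subset specification against a montage
#'
#' @param montage ordered channel labels.
#' @param subset_spec `"all"`, `"default11"` (the midline-centered
#'   fronto-central/central/centro-parietal subset, see
#'   [mi_channel_subset()]), or a character vector of labels.
#' @return Integer indices into `montage`, in montage order.
#' @export
select_channels <- function(montage, subset_spec = "default11") {
  labels <- if (identical(subset_spec, "all")) {
    montage
  } else if (identical(subset_spec, "default11")) {
    mi_channel_subset()
  } else {
    as.character(subset_spec)
  }
  idx <- match(labels, montage)
  if (anyNA(idx)) {
    stop(sprintf("unknown channel label(s): %s",
                 paste(labels[is.na(idx)], collapse = ", ")))
  }
  sort(idx)
}

#' Default sensorimotor channel subset
#'
#' The 11-channel midline-centered set of fronto-central, central and
#' centro-parietal electrodes used for channel-based feature extraction
#' over sensorimotor cortex. Note the common description of this subset as
#' "the central, fronto-central and centro-parietal rows" is ambiguous on
#' a 22-channel montage (those full rows contain 17 electrodes); this
#' package fixes the subset to the 11 electrodes closest to the midline
#' motor strip and lets any other choice be passed explicitly.
#'
#' @return Character vector of 11 channel labels.
#' @export
mi_channel_subset <- function() {
  c("FC1", "FCz", "FC2", "C3", "C1", "Cz", "C2", "C4", "CP1", "CPz", "CP2")
}

#' Translation-invariant feature matrix for an epoch set
#'
#' Applies the scattering cascade to every selected channel of every
#' epoch and concatenates coefficients in (channel, path) order.
#'
#' @param es an [epoch_set()].
#' @param cfg a [scattering_config()]; its `fs` must match the epoch set.
#' @return A [feature_matrix()] with tags
#'   `"tif:<channel>:o<order>:<f1>[:<f2>]"` and attribute `paths`.
#' @export
tif_extract <- function(es, cfg = scattering_config(es$fs)) {
  if (cfg$fs != es$fs) stop("scattering config fs does not match epoch set")
  bank <- build_filter_bank(cfg)
  d <- dim(es$data)
  plan <- scatter_plan(d[2L], bank)
  ch_idx <- select_channels(es$montage, cfg$channel_subset)
  pt <- expand_path_table(plan)
  path_tag <- ifelse(pt$order == 0L, "o0",
               ifelse(pt$order == 1L, sprintf("o1:%.3g", pt$f1),
                      sprintf("o2:%.3g:%.3g", pt$f1, pt$f2)))
  if (plan$n_frames > 1L) path_tag <- paste0(path_tag, ":t", pt$frame)
  tags <- as.vector(vapply(es$montage[ch_idx],
                           function(ch) paste0("tif:", ch, ":", path_tag),
                           character(length(path_tag))))
  X <- matrix(0, d[3L], length(tags))
  for (k in seq_len(d[3L])) {
    X[k, ] <- as.vector(vapply(ch_idx,
      function(ci) scatter_apply(es$data[ci, , k], plan),
      numeric(nrow(pt))))
  }
  fm <- feature_matrix(X, tags = tags, labels = es$labels)
  attr(fm, "paths") <- pt
  fm
}
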