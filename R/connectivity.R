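#' Analytic-signal decomposition of a single-channel epoch
#'
#' Builds the discrete analytic signal z(t) = x(t) + i xH(t), where xH is
#' the discrete Hilbert transform computed by the frequency-domain
#' construction (negative frequencies zeroed, positive doubled), and
#' returns the instantaneous amplitude A(t) = |z(t)| and instantaneous
#' phase phi(t) = atan2(xH, x), wrapped to (-pi, pi].
#'
#' The phase uses the four-quadrant arctangent: a two-quadrant arctan of
#' xH/x would discard the signs of the two components and destroy phase
#' continuity, so it is deliberately not used.
#'
#' @param x numeric vector, a finite, non-empty single-channel epoch.
#' @return A list with components `amplitude`, `phase` and `analytic`
#'   (the complex analytic signal), class `analytic_decomposition`.
#' @export
analytic_signal <- function(x) {
  if (length(x) == 0L || !all(is.finite(x))) {
    stop("input must be finite and non-empty")
  }
  if (all(x == 0)) {
    stop("degenerate all-zero signal: instantaneous phase is undefined")
  }
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[2:(n / 2)] <- 2
    h[n / 2 + 1L] <- 1
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  z <- stats::fft(stats::fft(x) * h, inverse = TRUE) / n
  phase <- atan2(Im(z), Re(z))
  phase[phase <= -pi] <- pi  # wrap convention (-pi, pi]
  structure(list(amplitude = Mod(z), phase = phase, analytic = z),
            class = "analytic_decomposition")
}

# Wrap angles to (-pi, pi].
wrap_phase <- function(d) {
  d <- (d + pi) %% (2 * pi) - pi
  d[d <= -pi] <- pi
  d
}

#' Phase lag index
#'
#' PLI = | mean_t sign(wrapped(phi_i(t) - phi_j(t))) | with sign(0) = 0.
#' The phase difference is wrapped to (-pi, pi] before taking the sign.
#' The PLI lies in \[0, 1\]; it is blind to zero-lag (volume-conduction)
#' coupling and maximal when one signal consistently leads the other.
#'
#' @param phi_i,phi_j equal-length numeric vectors of instantaneous
#'   phases (radians).
#' @return Scalar in \[0, 1\].
#' @export
pli <- function(phi_i, phi_j) {
  if (length(phi_i) != length(phi_j)) stop("phase series must have equal length")
  if (length(phi_i) < 1L) stop("need at least one sample")
  abs(mean(sign(wrap_phase(phi_i - phi_j))))
}

#' Phase correlation
#'
#' Pearson product-moment correlation between two instantaneous-phase
#' series, cov(phi_i, phi_j) / sqrt(var(phi_i) var(phi_j)). The ratio is
#' identical under sample or population variance normalization; phases are
#' used as produced (wrapped) unless `unwrap = TRUE`.
#'
#' @param phi_i,phi_j equal-length phase series (radians), each with
#'   nonzero variance.
#' @param unwrap if `TRUE`, unwrap both series before correlating.
#' @return Scalar in \[-1, 1\].
#' @export
phase_correlation <- function(phi_i, phi_j, unwrap = FALSE) {
  if (length(phi_i) != length(phi_j)) stop("phase series must have equal length")
  if (unwrap) {
    phi_i <- unwrap_angles(phi_i)
    phi_j <- unwrap_angles(phi_j)
  }
  if (stats::var(phi_i) == 0 || stats::var(phi_j) == 0) {
    stop("zero-variance phase series: correlation undefined")
  }
  stats::cor(phi_i, phi_j)
}

unwrap_angles <- function(p) {
  dp <- wrap_phase(diff(p))
  cumsum(c(p[1L], dp))
}

#' Pearson correlation between two signal series
#'
#' Plain Pearson correlation of two (band-passed) amplitude time series.
#'
#' @param x_i,x_j equal-length numeric vectors with nonzero variance.
#' @return Scalar in \[-1, 1\].
#' @export
pearson <- function(x_i, x_j) {
  if (length(x_i) != length(x_j)) stop("series must have equal length")
  if (stats::var(x_i) == 0 || stats::var(x_j) == 0) {
    stop("zero-variance series: correlation undefined")
  }
  stats::cor(x_i, x_j)
}

#' Per-epoch connectivity adjacency matrix
#'
#' Computes the symmetric nc x nc functional-connectivity matrix of one
#' epoch under the chosen metric. Each unordered channel pair is computed
#' once, so symmetry is exact. Diagonal is 1 for PC/Pearson (a signal is
#' perfectly correlated with itself) and 0 for PLI (no lag with itself).
#'
#' @param epoch numeric matrix, channels x samples (preprocessed).
#' @param metric one of `"pc"` (phase correlation), `"pearson"`, `"pli"`.
#' @param montage optional channel labels for dimnames and error messages.
#' @return A symmetric matrix of class `connectivity_matrix` with
#'   attribute `metric`.
#' @export
adjacency <- function(epoch, metric = c("pc", "pearson", "pli"),
                      montage = rownames(epoch)) {
  metric <- match.arg(metric)
  nc <- nrow(epoch)
  if (is.null(montage)) montage <- paste0("ch", seq_len(nc))
  v <- apply(epoch, 1L, stats::var)
  if (any(v == 0)) {
    stop(sprintf("degenerate zero-variance channel: %s",
                 paste(montage[v == 0], collapse = ", ")))
  }
  if (metric %in% c("pc", "pli")) {
    phases <- t(apply(epoch, 1L, function(ch) analytic_signal(ch)$phase))
  }
  M <- matrix(if (metric == "pli") 0 else 1, nc, nc,
              dimnames = list(montage, montage))
  for (i in seq_len(nc - 1L)) {
    for (j in seq.int(i + 1L, nc)) {
      val <- switch(metric,
        pli = pli(phases[i, ], phases[j, ]),
        pc = phase_correlation(phases[i, ], phases[j, ]),
        pearson = pearson(epoch[i, ], epoch[j, ]))
      M[i, j] <- M[j, i] <- val
    }
  }
  structure(M, metric = metric, class = c("connectivity_matrix", "matrix", "array"))
}

#' Vectorize the strict upper triangle of a connectivity matrix
#'
#' Flattens a symmetric nc x nc matrix into its nc(nc-1)/2 off-diagonal
#' values in row-major upper-triangle order (pairs (1,2), (1,3), ...,
#' (nc-1,nc)), the brain-connectivity feature (BCF) vector of one epoch.
#'
#' @param M symmetric square matrix.
#' @return Named numeric vector of length `nc*(nc-1)/2` with attribute
#'   `pairs` (a 2-column index matrix mapping entries back to channels).
#' @export
vectorize_upper <- function(M) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) stop("input must be a square matrix")
  nc <- nrow(M)
  pairs <- which(upper.tri(M), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  v <- M[pairs]
  labs <- rownames(M)
  if (is.null(labs)) labs <- paste0("ch", seq_len(nc))
  names(v) <- paste(labs[pairs[, 1L]], labs[pairs[, 2L]], sep = "-")
  attr(v, "pairs") <- unname(pairs)
  v
}

#' Re-fold a BCF vector into a symmetric matrix
#'
#' Inverse of [vectorize_upper()] (diagonal filled with `diag_value`).
#'
#' @param v vector produced by [vectorize_upper()].
#' @param nc matrix dimension.
#' @param diag_value value for the diagonal (default 0).
#' @return nc x nc symmetric matrix.
#' @export
fold_upper <- function(v, nc, diag_value = 0) {
  if (length(v) != nc * (nc - 1) / 2) stop("length(v) != nc*(nc-1)/2")
  M <- matrix(diag_value, nc, nc)
  pairs <- which(upper.tri(M), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  M[pairs] <- v
  M[pairs[, c(2L, 1L), drop = FALSE]] <- v
  M
}

#' Z-scored grand-average connectivity by class
#'
#' Standardizes each epoch's connectivity matrix over its off-diagonal
#' entries (mean 0, sd 1 within the matrix), then averages the
#' standardized matrices across epochs of each class. Class differences
#' are elementwise subtractions of the class averages, highlighting which
#' connections separate two motor-imagery tasks.
#'
#' @param matrices list of symmetric connectivity matrices, one per epoch.
#' @param labels class label per epoch.
#' @return A list with `average` (one matrix per class) and `difference`
#'   (one matrix per ordered class pair, named "A-B").
#' @export
zscore_grand_average <- function(matrices, labels) {
  labels <- as.character(labels)
  stopifnot(length(matrices) == length(labels))
  classes <- unique(labels)
  if (any(table(labels) < 2L)) stop("need at least 2 epochs per class")
  zs <- lapply(matrices, function(M) {
    off <- M[upper.tri(M) | lower.tri(M)]
    s <- stats::sd(off)
    if (s == 0) stop("zero within-matrix variance: cannot Z-score")
    Z <- (M - mean(off)) / s
    diag(Z) <- 0
    Z
  })
  avg <- lapply(classes, function(cl) {
    Reduce(`+`, zs[labels == cl]) / sum(labels == cl)
  })
  names(avg) <- classes
  diffs <- list()
  for (a in classes) for (b in classes) {
    if (a != b) diffs[[paste(a, b, sep = "-")]] <- avg[[a]] - avg[[b]]
  }
  list(average = avg, difference = diffs)
}

#' Brain-connectivity feature matrix for an epoch set
#'
#' Computes the per-epoch adjacency under `metric` on all channels and
#' stacks the vectorized upper triangles into an epochs x features matrix
#' tagged with the channel-pair each feature came from.
#'
#' @param es an [epoch_set()].
#' @param metric `"pc"`, `"pearson"` or `"pli"`.
#' @return A [feature_matrix()] with tags `"bcf:<metric>:<chi>-<chj>"`.
#' @export
bcf_extract <- function(es, metric = c("pc", "pearson", "pli")) {
  metric <- match.arg(metric)
  n_ep <- dim(es$data)[3L]
  rows <- vector("list", n_ep)
  for (k in seq_len(n_ep)) {
    M <- adjacency(es$data[, , k], metric, montage = es$montage)
    rows[[k]] <- vectorize_upper(M)
  }
  X <- do.call(rbind, rows)
  tags <- paste0("bcf:", metric, ":", colnames(X))
  feature_matrix(X, tags = tags, labels = es$labels)
}
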