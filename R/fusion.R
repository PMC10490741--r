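#' Epochs x features matrix with provenance tags
#'
#' Thin container coupling a numeric feature matrix with a provenance tag
#' per feature (e.g. `"tif:C3:o1:20"` or `"bcf:pc:C3-C4"`) and a class
#' label per epoch, so fused feature sets remain interpretable and can be
#' sliced back into their sources.
#'
#' @param values numeric matrix, epochs x features (no NAs).
#' @param tags character vector, one per feature.
#' @param labels class label per epoch.
#' @return Matrix of class `feature_matrix` with attributes `tags` and
#'   `labels`.
#' @export
feature_matrix <- function(values, tags, labels) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("feature matrix must not contain NA")
  if (length(tags) != ncol(values)) stop("tags length != feature count")
  if (length(labels) != nrow(values)) stop("labels length != epoch count")
  structure(values, tags = as.character(tags), labels = as.character(labels),
            class = c("feature_matrix", "matrix", "array"))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d epochs x %d features\n", nrow(x), ncol(x)))
  src <- sub(":.*$", "", attr(x, "tags"))
  tab <- table(src)
  cat("  sources:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

feature_tags <- function(x) attr(x, "tags")
feature_labels <- function(x) attr(x, "labels")

#' Serial feature fusion
#'
#' Concatenates two feature matrices computed on the same epochs: if the
#' first is n-dimensional and the second m-dimensional, the fused vector
#' is (n+m)-dimensional. Tags are concatenated, so the fusion can be
#' sliced back into its components.
#'
#' @param a,b [feature_matrix()] objects over the same epochs in the same
#'   order (labels must agree elementwise).
#' @return The fused `feature_matrix`.
#' @export
fuse <- function(a, b) {
  if (nrow(a) != nrow(b)) stop("epoch count mismatch")
  if (!identical(feature_labels(a), feature_labels(b))) {
    stop("epoch labels/order mismatch between feature sets")
  }
  feature_matrix(cbind(unclass(a), unclass(b)),
                 tags = c(feature_tags(a), feature_tags(b)),
                 labels = feature_labels(a))
}

#' Multiclass Fisher score per feature
#'
#' For feature j with per-class means mu_k(j), per-class population
#' standard deviations sigma_k(j), class sizes n_k and grand mean mu(j):
#' \deqn{F(X_j) = \frac{\sum_k n_k (\mu_k(j) - \mu(j))^2}
#'                    {\sum_k n_k \sigma_k(j)^2}}
#' the ratio of between-class to within-class scatter. If the denominator
#' is 0 the score is 0 when the numerator is 0 (a constant feature) and
#' `Inf` otherwise (a zero-variance feature that separates classes is
#' maximally discriminative).
#'
#' @param X epochs x features numeric matrix (or [feature_matrix()]).
#' @param labels class per epoch; defaults to the matrix's own labels.
#' @return Numeric vector of nonnegative scores, one per feature.
#' @export
fisher_score <- function(X, labels = feature_labels(X)) {
  labels <- as.character(labels)
  if (is.null(labels)) stop("labels required")
  classes <- unique(labels)
  if (length(classes) < 2L) stop("need at least 2 classes")
  cnt <- table(labels)
  if (any(cnt < 2L)) stop("every class needs at least 2 epochs")
  X <- unclass(X)
  mu <- colMeans(X)
  num <- den <- numeric(ncol(X))
  for (cl in classes) {
    Xk <- X[labels == cl, , drop = FALSE]
    nk <- nrow(Xk)
    muk <- colMeans(Xk)
    vark <- colMeans(Xk^2) - muk^2      # population variance
    vark[vark < 0] <- 0
    num <- num + nk * (muk - mu)^2
    den <- den + nk * vark
  }
  sc <- ifelse(den > 0, num / den, ifelse(num == 0, 0, Inf))
  pmax(sc, 0)
}

#' Select the top-scoring features
#'
#' Indices of the `s` largest scores in descending score order; ties are
#' broken by ascending feature index, so selection is deterministic.
#'
#' @param scores numeric score vector (from [fisher_score()]).
#' @param s number of features to keep, `1 <= s <= length(scores)`.
#' @return Integer vector of `s` feature indices.
#' @export
select_top <- function(scores, s) {
  nf <- length(scores)
  if (s < 1 || s > nf) stop("s out of range")
  order(-scores, seq_len(nf))[seq_len(s)]
}

#' Standardize features with training-set statistics
#'
#' Z-scores every column of `apply_to` using the per-feature mean and
#' (sample) standard deviation of `train` only, so no test-set statistics
#' leak into the transform. Zero-variance training features are centered
#' but left unscaled.
#'
#' @param train numeric matrix whose columns define the statistics.
#' @param apply_to matrix to transform (defaults to `train`).
#' @return List with `values` (transformed `apply_to`), `center`, `scale`.
#' @export
standardize <- function(train, apply_to = train) {
  train <- unclass(train); A <- unclass(apply_to)
  if (ncol(train) != ncol(A)) stop("feature count mismatch")
  ctr <- colMeans(train)
  scl <- apply(train, 2L, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(values = sweep(sweep(A, 2L, ctr), 2L, scl, "/"),
       center = ctr, scale = scl)
}
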