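#' Session-to-session transfer split
#'
#' All epochs of session 1 train, all epochs of session 2 test.
#'
#' @param session1,session2 [epoch_set()]s (or [trial_set()]s) of the two
#'   recording days; montages and class sets must match and session ids
#'   must differ when available.
#' @return A list of class `split_plan` with `strategy`, `train`/`test`
#'   index vectors into the concatenation `c(session1, session2)` and the
#'   per-class counts of each part.
#' @export
sst_split <- function(session1, session2) {
  check_sessions(session1, session2)
  n1 <- length(session1$labels); n2 <- length(session2$labels)
  plan(strategy = "SST", train = seq_len(n1), test = n1 + seq_len(n2),
       labels = c(session1$labels, session2$labels))
}

#' Calibration-session transfer split
#'
#' Session 1 plus, per class, the chronologically first
#' `floor(fraction * n_class)` epochs of session 2 train; the remaining
#' session-2 epochs test. The calibration subset is balanced per class
#' within the rounding of the floor rule.
#'
#' @param session1,session2 as in [sst_split()].
#' @param fraction calibration fraction of session 2, in (0, 1)
#'   (default 0.40).
#' @return A `split_plan`; test indices are drawn only from session 2.
#' @export
cst_split <- function(session1, session2, fraction = 0.40) {
  check_sessions(session1, session2)
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n1 <- length(session1$labels)
  lab2 <- session2$labels
  calib <- integer(0)
  for (cl in unique(lab2)) {
    idx <- which(lab2 == cl)           # chronological (recording) order
    k <- floor(fraction * length(idx))
    calib <- c(calib, idx[seq_len(k)])
  }
  calib <- sort(calib)
  test2 <- setdiff(seq_along(lab2), calib)
  plan(strategy = "CST", train = c(seq_len(n1), n1 + calib),
       test = n1 + test2, labels = c(session1$labels, lab2),
       calibration_fraction = fraction)
}

check_sessions <- function(a, b) {
  if (!identical(a$montage, b$montage)) stop("montage mismatch between sessions")
  if (!setequal(unique(a$labels), unique(b$labels))) {
    stop("class mismatch between sessions")
  }
  ida <- a$session_id; idb <- b$session_id
  if (!is.null(ida) && !is.null(idb) && identical(ida, idb)) {
    stop("sessions must have different session ids")
  }
  invisible(NULL)
}

plan <- function(strategy, train, test, labels, calibration_fraction = NULL) {
  structure(list(strategy = strategy, train = train, test = test,
                 train_counts = table(labels[train]),
                 test_counts = table(labels[test]),
                 calibration_fraction = calibration_fraction),
            class = "split_plan")
}

# Stratified fold assignment: within each class, epochs are dealt to the
# folds in a seeded random order, keeping folds class-balanced.
stratified_folds <- function(labels, n_folds, seed = 1701) {
  with_local_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
}

# One-vs-rest ensemble of binary RBF-SVMs; decision by argmax of the
# per-class decision values.
fit_ovr_svm <- function(X, labels, cost, gamma) {
  classes <- sort(unique(labels))
  models <- lapply(classes, function(cl) {
    y <- factor(ifelse(labels == cl, "pos", "rest"), levels = c("pos", "rest"))
    e1071::svm(X, y, type = "C-classification", kernel = "radial",
               cost = cost, gamma = gamma, scale = FALSE)
  })
  names(models) <- classes
  structure(list(classes = classes, models = models), class = "ovr_svm")
}

predict_ovr <- function(fit, X) {
  dv <- vapply(fit$models, function(m) {
    p <- stats::predict(m, X, decision.values = TRUE)
    d <- drop(attr(p, "decision.values"))
    # decision values are signed towards the first factor level ("pos")
    if (colnames(attr(p, "decision.values"))[1L] == "rest/pos") -d else d
  }, numeric(nrow(X)))
  if (is.null(dim(dv))) dv <- matrix(dv, nrow = 1L)
  fit$classes[max.col(dv, ties.method = "first")]
}

#' Default hyperparameter grid for the transfer classifier
#'
#' Log-2 spaced SVM cost and RBF-width grids searched jointly with the
#' number of selected features.
#'
#' @param cost SVM cost values (default `2^(-3..9)`, step 2 octaves).
#' @param gamma RBF gamma values (default `2^(-11..1)`, step 2 octaves).
#' @param n_features candidate selected-feature counts
#'   (default `c(50, 100, 200, 400)`; values above the available feature
#'   count are dropped at fit time).
#' @return List with components `cost`, `gamma`, `n_features`.
#' @export
classifier_grid <- function(cost = 2^seq(-3, 9, by = 2),
                            gamma = 2^seq(-11, 1, by = 2),
                            n_features = c(50, 100, 200, 400)) {
  list(cost = cost, gamma = gamma, n_features = n_features)
}

#' Train the multiclass motor-imagery classifier
#'
#' For every (cost, gamma, S) triple on the grid, runs stratified k-fold
#' cross-validation on the training set; inside each fold the Fisher
#' scores are recomputed on the fold's training part only, the top-S
#' features selected, and standardization fitted on the same part, so no
#' information leaks from the held-out fold. The triple with the best
#' mean CV accuracy (ties: first in grid order) is refit on the full
#' training set; the reported validation accuracy is that best CV mean.
#'
#' @param features epochs x features [feature_matrix()] (training set).
#' @param labels class per epoch; defaults to the matrix's labels.
#' @param grid a [classifier_grid()].
#' @param n_folds CV folds (default 10); every class must have at least
#'   `n_folds` epochs.
#' @param fold_seed seed fixing the fold assignment (default 1701).
#' @param standardize_features z-score with training statistics before
#'   the SVM (default `TRUE`).
#' @return A `mi_classifier`: fitted OVR ensemble, selection and
#'   standardization state, chosen hyperparameters, validation accuracy
#'   and the full CV grid table.
#' @export
train_model <- function(features, labels = feature_labels(features),
                        grid = classifier_grid(), n_folds = 10,
                        fold_seed = 1701, standardize_features = TRUE) {
  labels <- as.character(labels)
  X <- unclass(features)
  cnt <- table(labels)
  if (any(cnt < n_folds)) {
    stop(sprintf("every class needs >= %d epochs for %d-fold CV", n_folds, n_folds))
  }
  s_grid <- unique(pmin(grid$n_features, ncol(X)))
  fold <- stratified_folds(labels, n_folds, fold_seed)
  combos <- expand.grid(s = s_grid, gamma = grid$gamma, cost = grid$cost,
                        KEEP.OUT.ATTRS = FALSE)
  acc <- numeric(nrow(combos))
  # Pre-compute per-fold selection + standardization once per S.
  fold_prep <- lapply(seq_len(n_folds), function(f) {
    tr <- fold != f
    sc <- fisher_score(X[tr, , drop = FALSE], labels[tr])
    list(tr = tr, score = sc)
  })
  for (si in seq_along(s_grid)) {
    s <- s_grid[si]
    fold_data <- lapply(fold_prep, function(fp) {
      keep <- select_top(fp$score, s)
      Xtr <- X[fp$tr, keep, drop = FALSE]
      Xte <- X[!fp$tr, keep, drop = FALSE]
      if (standardize_features) {
        st <- standardize(Xtr)
        Xtr <- st$values
        Xte <- sweep(sweep(Xte, 2L, st$center), 2L, st$scale, "/")
      }
      list(Xtr = Xtr, Xte = Xte, ytr = labels[fp$tr], yte = labels[!fp$tr])
    })
    rows <- which(combos$s == s)
    for (r in rows) {
      hits <- 0L; tot <- 0L
      for (fd in fold_data) {
        fit <- fit_ovr_svm(fd$Xtr, fd$ytr, combos$cost[r], combos$gamma[r])
        pred <- predict_ovr(fit, fd$Xte)
        hits <- hits + sum(pred == fd$yte)
        tot <- tot + length(fd$yte)
      }
      acc[r] <- 100 * hits / tot
    }
  }
  best <- which.max(acc)  # first maximum in grid order
  sc_full <- fisher_score(X, labels)
  keep <- select_top(sc_full, combos$s[best])
  Xsel <- X[, keep, drop = FALSE]
  st <- if (standardize_features) standardize(Xsel) else
    list(values = Xsel, center = rep(0, ncol(Xsel)), scale = rep(1, ncol(Xsel)))
  fit <- fit_ovr_svm(st$values, labels, combos$cost[best], combos$gamma[best])
  structure(list(fit = fit, selected = keep,
                 selected_tags = feature_tags(features)[keep],
                 center = st$center, scale = st$scale,
                 cost = combos$cost[best], gamma = combos$gamma[best],
                 n_features = combos$s[best],
                 validation_accuracy = acc[best],
                 cv_table = cbind(combos, cv_accuracy = acc),
                 classes = sort(unique(labels))),
            class = "mi_classifier")
}

#' @export
print.mi_classifier <- function(x, ...) {
  cat(sprintf("<mi_classifier> OVR RBF-SVM over %d classes\n", length(x$classes)))
  cat(sprintf("  C = %g, gamma = %g, S = %d features; validation accuracy %.2f%%\n",
              x$cost, x$gamma, x$n_features, x$validation_accuracy))
  invisible(x)
}

#' Predict class labels for new epochs
#'
#' @param object a trained `mi_classifier`.
#' @param newdata epochs x features matrix with the same feature columns
#'   the model was trained on (selection and standardization are applied
#'   internally).
#' @param ... unused.
#' @return Character vector of predicted labels.
#' @export
predict.mi_classifier <- function(object, newdata, ...) {
  X <- unclass(newdata)
  if (ncol(X) < max(object$selected)) stop("feature count mismatch with trained model")
  Xs <- sweep(sweep(X[, object$selected, drop = FALSE], 2L, object$center),
              2L, object$scale, "/")
  predict_ovr(object$fit, Xs)
}

#' Evaluate a trained model on a test set
#'
#' @param model a `mi_classifier`.
#' @param test epochs x features [feature_matrix()] of held-out epochs.
#' @param labels true labels (defaults to the matrix's labels).
#' @return K x K confusion matrix (rows = true, columns = predicted).
#' @export
evaluate <- function(model, test, labels = feature_labels(test)) {
  if (nrow(test) == 0L) stop("empty test set")
  pred <- predict(model, test)
  confusion_matrix(labels, pred, classes = model$classes)
}

#' Confusion matrix with fixed class order
#'
#' @param truth,pred equal-length label vectors.
#' @param classes class order (default: sorted union).
#' @return Integer matrix, rows = true, columns = predicted.
#' @export
confusion_matrix <- function(truth, pred, classes = sort(unique(c(truth, pred)))) {
  t_f <- factor(truth, levels = classes)
  p_f <- factor(pred, levels = classes)
  unclass(table(true = t_f, predicted = p_f))
}

#' Classification accuracy of a confusion matrix
#'
#' @param cm confusion matrix (rows = true, columns = predicted).
#' @return Percent correct, `100 * trace / total`.
#' @export
accuracy <- function(cm) {
  tot <- sum(cm)
  if (tot == 0) stop("empty confusion matrix")
  100 * sum(diag(cm)) / tot
}

#' Cohen's kappa of a confusion matrix
#'
#' Chance-corrected agreement `(po - pe) / (1 - pe)` with observed
#' agreement `po = trace/total` and expected agreement
#' `pe = sum(row marginals x column marginals) / total^2`.
#'
#' @param cm confusion matrix.
#' @return Scalar in \[-1, 1\].
#' @export
cohen_kappa <- function(cm) {
  tot <- sum(cm)
  if (tot == 0) stop("empty confusion matrix")
  po <- sum(diag(cm)) / tot
  pe <- sum(rowSums(cm) * colSums(cm)) / tot^2
  if (pe >= 1) stop("degenerate confusion matrix: expected agreement is 1")
  (po - pe) / (1 - pe)
}

#' Macro-averaged precision and recall
#'
#' Per-class one-vs-rest precision `TP/(TP+FP)` and recall `TP/(TP+FN)`,
#' averaged over classes. A class never predicted (or never present)
#' contributes 0 to the respective average.
#'
#' @param cm confusion matrix.
#' @return Named numeric vector `c(precision = ..., recall = ...)`.
#' @export
precision_recall <- function(cm) {
  if (sum(cm) == 0) stop("empty confusion matrix")
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  c(precision = mean(prec), recall = mean(rec))
}

#' Exact two-sided Wilcoxon signed-rank test
#'
#' Computes the exact two-sided p-value for paired samples by full
#' enumeration of the 2^n sign assignments (via the standard
#' shift-algorithm over the rank distribution). Zero differences are
#' dropped; tied absolute differences receive midranks. Suitable for the
#' small-n regime (n <= 25 after dropping zeros).
#'
#' @param a,b equal-length paired numeric vectors; differences are
#'   `b - a`.
#' @return List with `statistic` (`W`, the smaller of the signed-rank
#'   sums), `n` (pairs after dropping zeros) and `p.value`.
#' @export
wilcoxon_signed_rank_exact <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  d <- b - a
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all differences are zero; p = 1 by convention")
    return(list(statistic = 0, n = 0L, p.value = 1))
  }
  if (n > 25L) stop("exact enumeration supported for n <= 25")
  r <- rank(abs(d))                      # midranks for ties
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  ir <- as.integer(round(2 * r))         # doubled midranks are integers
  # distribution of 2*W+ over all 2^n equally likely sign vectors
  counts <- c(1, numeric(sum(ir)))       # counts[v+1] = #assignments with sum v
  for (rk in ir) {
    shifted <- c(numeric(rk), counts[seq_len(length(counts) - rk)])
    counts <- counts + shifted
  }
  total <- 2^n
  wp2 <- round(2 * w_pos)
  p_le <- sum(counts[seq_len(wp2 + 1L)]) / total
  p_ge <- sum(counts[seq.int(wp2 + 1L, length(counts))]) / total
  p <- min(1, 2 * min(p_le, p_ge))
  list(statistic = min(w_pos, w_neg), n = n, p.value = p)
}

#' Aggregate per-subject results into a cross-subject report
#'
#' @param per_subject data frame with one row per subject; every numeric
#'   column is aggregated.
#' @param digits rounding applied to the displayed summary (default 2).
#' @return List of class `evaluation_report` with the per-subject table
#'   and a `summary` data frame holding the arithmetic mean and sample
#'   standard deviation (n-1 denominator) of each numeric column; with a
#'   single subject the SD is reported as `NA`.
#' @export
aggregate_report <- function(per_subject, digits = 2) {
  if (nrow(per_subject) < 1L) stop("need at least one subject")
  num <- vapply(per_subject, is.numeric, logical(1L))
  m <- vapply(per_subject[num], mean, numeric(1L))
  s <- if (nrow(per_subject) > 1L) {
    vapply(per_subject[num], stats::sd, numeric(1L))
  } else {
    rep(NA_real_, sum(num))
  }
  structure(list(per_subject = per_subject,
                 summary = data.frame(statistic = c("Average", "SD"),
                                      rbind(round(m, digits), round(s, digits)),
                                      check.names = FALSE)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d subject(s)\n", nrow(x$per_subject)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
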