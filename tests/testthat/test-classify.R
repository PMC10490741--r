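fake_session <- function(labels, id) {
  list(montage = c("C3", "C4"), labels = labels, session_id = id)
}

test_that("SST split uses session 1 to train and session 2 to test", {
  s1 <- fake_session(rep(c("A", "B"), 6), "S1")
  s2 <- fake_session(rep(c("A", "B"), 5), "S2")
  sp <- sst_split(s1, s2)
  expect_equal(sp$train, 1:12)
  expect_equal(sp$test, 13:22)
  expect_error(sst_split(s1, fake_session(rep("A", 4), "S2")), "class mismatch")
  expect_error(sst_split(s1, fake_session(rep(c("A", "B"), 5), "S1")),
               "different session ids")
  bad <- fake_session(rep(c("A", "B"), 5), "S2"); bad$montage <- c("C3", "Cz")
  expect_error(sst_split(s1, bad), "montage")
})

test_that("CST split takes the chronologically first fraction per class", {
  s1 <- fake_session(rep(c("A", "B"), each = 10), "S1")
  lab2 <- rep(c("A", "B"), 10)
  s2 <- fake_session(lab2, "S2")
  sp <- cst_split(s1, s2, fraction = 0.40)
  # floor(0.4 * 10) = 4 calibration epochs per class, earliest first
  calib2 <- setdiff(sp$train, 1:20) - 20
  expect_equal(calib2, sort(c(which(lab2 == "A")[1:4], which(lab2 == "B")[1:4])))
  expect_equal(length(sp$test), 12)
  expect_true(all(sp$test > 20))                    # test only from session 2
  expect_length(intersect(sp$train, sp$test), 0)
  expect_equal(as.vector(sp$test_counts), c(6, 6))
  # 72 clean epochs per class: 28 calibrate, 44 test
  b1 <- fake_session(rep(c("A", "B"), each = 72), "S1")
  b2 <- fake_session(rep(c("A", "B"), 72), "S2")
  spb <- cst_split(b1, b2)
  expect_equal(as.vector(spb$train_counts), c(100, 100))  # 72 + floor(28.8)
  expect_equal(as.vector(spb$test_counts), c(44, 44))
  expect_error(cst_split(s1, s2, fraction = 0), "fraction")
})

test_that("confusion-matrix metrics match their closed forms", {
  cm <- matrix(c(30, 10, 10, 30), 2, byrow = TRUE)
  expect_equal(accuracy(cm), 75)
  expect_equal(cohen_kappa(cm), 0.5)        # po = .75, pe = .5
  pr <- precision_recall(cm)
  expect_equal(unname(pr["precision"]), 0.75)
  expect_equal(unname(pr["recall"]), 0.75)
  diag4 <- diag(c(10, 20, 5, 7))
  expect_equal(accuracy(diag4), 100)
  expect_equal(cohen_kappa(diag4), 1)
  expect_equal(unname(precision_recall(diag4)), c(1, 1))
  unif <- matrix(5, 4, 4)
  expect_equal(accuracy(unif), 25)
  expect_equal(cohen_kappa(unif), 0, tolerance = 1e-12)
  # a never-predicted class contributes 0 to macro precision
  cm0 <- matrix(c(5, 0, 5, 0), 2, byrow = TRUE)
  expect_equal(unname(precision_recall(cm0)["precision"]), 0.25)
  expect_error(accuracy(matrix(0, 2, 2)), "empty")
  expect_error(cohen_kappa(matrix(c(4, 0, 0, 0), 2)), "degenerate")
})

test_that("kappa is 1 exactly when off-diagonal mass is 0", {
  set.seed(41)
  for (rep in 1:20) {
    cm <- matrix(rpois(16, 5), 4)
    if (sum(diag(cm)) == sum(cm)) next
    k <- cohen_kappa(cm)
    expect_lt(k, 1)
    expect_gte(k, -1)
  }
  expect_equal(cohen_kappa(diag(c(3, 1, 2, 9))), 1)
})

test_that("exact Wilcoxon matches full enumeration for n <= 12", {
  set.seed(42)
  for (n in c(1, 2, 5, 8, 10, 12)) {
    for (rep in 1:4) {
      a <- sample(-6:6, n, replace = TRUE)
      b <- sample(-6:6, n, replace = TRUE)
      got <- wilcoxon_signed_rank_exact(a, b)
      expect_equal(got$p.value, wilcoxon_oracle(a, b), tolerance = 1e-12,
                   label = sprintf("n=%d rep=%d", n, rep))
    }
  }
  # single nonzero pair: both sign assignments equally extreme
  expect_equal(wilcoxon_signed_rank_exact(0, 3)$p.value, 1.0)
  expect_warning(p0 <- wilcoxon_signed_rank_exact(c(1, 2), c(1, 2)), "zero")
  expect_equal(p0$p.value, 1)
})

test_that("per-subject aggregation reports mean and n-1 standard deviation", {
  df <- data.frame(subject = 1:3, acc = c(50, 60, 70), kappa = c(0.2, 0.4, 0.6))
  rep_ <- aggregate_report(df)
  expect_equal(rep_$summary$acc, c(60, 10))
  expect_equal(rep_$summary$kappa, c(0.4, 0.2))
  one <- aggregate_report(data.frame(acc = 55))
  expect_true(is.na(one$summary$acc[2]))
  same <- aggregate_report(data.frame(acc = c(40, 40, 40)))
  expect_equal(same$summary$acc[2], 0)
})

test_that("published benchmark columns reproduce the reported aggregates", {
  ref <- reference_session_transfer()
  expect_equal(nrow(ref), 9)
  expect_equal(aggregate_report(ref)$summary$sst_fused_test[1], 56.10)
  expect_equal(aggregate_report(ref)$summary$cst_fused_test[1], 71.67)
  w_sst <- wilcoxon_signed_rank_exact(ref$sst_tif_test, ref$sst_fused_test)
  expect_equal(round(w_sst$p.value, 4), 0.0039)
  w_cst <- wilcoxon_signed_rank_exact(ref$cst_tif_test, ref$cst_fused_test)
  expect_equal(round(w_cst$p.value, 4), 0.0156)
})

sep_features <- function(n_per_class, classes = c("A", "B", "C", "D"), sd = 0.05,
                         p_noise = 5) {
  n <- n_per_class * length(classes)
  labs <- rep(classes, each = n_per_class)
  centers <- diag(length(classes))
  X <- centers[as.integer(factor(labs)), ] +
    matrix(rnorm(n * length(classes), 0, sd), n)
  X <- cbind(X, matrix(rnorm(n * p_noise), n))
  feature_matrix(X, paste0("f", seq_len(ncol(X))), labs)
}

test_that("the OVR grid search separates separable classes and is deterministic", {
  set.seed(43)
  fm <- sep_features(12)
  grid <- classifier_grid(cost = c(1, 10), gamma = c(0.05, 0.5), n_features = 9)
  m1 <- train_model(fm, grid = grid, n_folds = 4)
  expect_equal(m1$validation_accuracy, 100)
  m2 <- train_model(fm, grid = grid, n_folds = 4)
  expect_equal(c(m1$cost, m1$gamma, m1$n_features),
               c(m2$cost, m2$gamma, m2$n_features))
  cm <- evaluate(m1, fm)
  expect_equal(accuracy(cm), 100)
  expect_true(all(cm[upper.tri(cm) | lower.tri(cm)] == 0))
  # three-class mode is plain class subsetting: 3x3 confusion matrix
  fm3 <- sep_features(12, classes = c("A", "B", "C"))
  m3 <- train_model(fm3, grid = grid, n_folds = 4)
  expect_equal(dim(evaluate(m3, fm3)), c(3, 3))
  expect_error(train_model(sep_features(3), grid = grid, n_folds = 4), "folds|epochs")
})

test_that("shuffled labels give chance-level validation accuracy", {
  set.seed(44)
  fm <- sep_features(12)
  shuffled <- feature_matrix(unclass(fm), attr(fm, "tags"),
                             sample(attr(fm, "labels")))
  m <- train_model(shuffled, grid = classifier_grid(cost = 1, gamma = 0.1,
                                                    n_features = 9),
                   n_folds = 4)
  # binomial 99% band around 25% for n = 48
  half <- 2.576 * sqrt(0.25 * 0.75 / 48) * 100
  expect_gt(m$validation_accuracy, 25 - half)
  expect_lt(m$validation_accuracy, 25 + half)
})
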