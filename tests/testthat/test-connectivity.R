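test_that("analytic signal recovers amplitude and phase of a cosine", {
  fs <- 250
  t <- (0:624) / fs
  ad <- analytic_signal(cos(2 * pi * 10 * t))
  ctr <- 63:562  # central 80%
  expect_true(all(ad$amplitude[ctr] >= 0.95 & ad$amplitude[ctr] <= 1.05))
  ph <- cumsum(c(ad$phase[1], diff(ad$phase) -
                   2 * pi * round(diff(ad$phase) / (2 * pi))))
  slope <- coef(lm(ph[ctr] ~ t[ctr]))[[2]]
  expect_equal(slope, 2 * pi * 10, tolerance = 0.02)
  # amplitude scales linearly
  ad3 <- analytic_signal(3 * cos(2 * pi * 10 * t))
  expect_equal(mean(ad3$amplitude[ctr]), 3, tolerance = 0.01)
  expect_true(all(ad$phase > -pi & ad$phase <= pi))
  expect_true(all(ad$amplitude >= 0))
})

test_that("analytic signal rejects degenerate input", {
  expect_error(analytic_signal(numeric(0)), "finite and non-empty")
  expect_error(analytic_signal(c(1, NA, 2)), "finite")
  expect_error(analytic_signal(numeric(100)), "all-zero")
})

test_that("PLI follows the sign-of-lag definition", {
  set.seed(3)
  phi <- runif(500, -pi, pi)
  expect_equal(pli(phi, phi + pi / 4), 1.0)     # constant lead
  expect_equal(pli(phi, phi), 0.0)              # sign(0) = 0
  set.seed(31)
  dphi <- runif(1e4, -pi, pi)
  expect_lt(pli(numeric(1e4), dphi), 0.05)      # null coupling ~ 1/sqrt(N)
  expect_error(pli(1:3, 1:4), "equal length")
})

test_that("phase and Pearson correlations hit their closed-form cases", {
  set.seed(5)
  phi <- rnorm(200)
  expect_equal(phase_correlation(phi, phi), 1.0)
  expect_equal(phase_correlation(phi, -phi), -1.0)
  expect_equal(phase_correlation(c(-1, 0, 1, 2), c(-2, -1, 0, 4)),
               0.93267, tolerance = 5e-4)  # frozen from the loop oracle
  expect_error(phase_correlation(rep(1, 10), phi[1:10]), "zero-variance")
  x <- rnorm(200)
  expect_equal(pearson(x, x), 1.0)
  expect_equal(pearson(x, -x), -1.0)
  set.seed(6)
  expect_lt(abs(pearson(rnorm(1e4), rnorm(1e4))), 0.05)
})

test_that("connectivity measures match per-sample loop oracles", {
  set.seed(7)
  for (n in c(16, 33, 64)) {
    phi_i <- runif(n, -pi, pi)
    phi_j <- runif(n, -pi, pi)
    expect_equal(pli(phi_i, phi_j), pli_oracle(phi_i, phi_j), tolerance = 1e-12)
    expect_equal(phase_correlation(phi_i, phi_j), cor_oracle(phi_i, phi_j),
                 tolerance = 1e-12)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(pearson(x, y), cor_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("connectivity invariants hold on fuzzed inputs", {
  set.seed(8)
  for (rep in 1:25) {
    phi_i <- runif(50, -pi, pi)
    phi_j <- runif(50, -pi, pi)
    v <- pli(phi_i, phi_j)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(v, pli(phi_j, phi_i))                       # symmetry
    off <- runif(1, -pi, pi)
    expect_equal(v, pli(phi_i + off, phi_j + off), tolerance = 1e-12)
    r <- phase_correlation(phi_i, phi_j)
    expect_gte(r, -1); expect_lte(r, 1)
    expect_equal(r, phase_correlation(phi_j, phi_i), tolerance = 1e-12)
  }
})

test_that("adjacency matrices satisfy the per-metric structure", {
  set.seed(9)
  ep <- matrix(rnorm(5 * 200), 5, dimnames = list(paste0("ch", 1:5), NULL))
  for (m in c("pc", "pearson", "pli")) {
    M <- adjacency(ep, m)
    expect_true(isSymmetric(unclass(M)))
    if (m == "pli") {
      expect_equal(unname(diag(M)), rep(0, 5))
      expect_true(all(M >= 0 & M <= 1))
    } else {
      expect_equal(unname(diag(M)), rep(1, 5))
      expect_true(all(M >= -1 & M <= 1))
    }
  }
  # identical channels: Pearson 1 off-diagonal, PLI 0
  two <- rbind(a = ep[1, ], b = ep[1, ])
  expect_equal(adjacency(two, "pearson")[1, 2], 1.0)
  expect_equal(adjacency(two, "pli")[1, 2], 0.0)
  flat <- ep; flat[3, ] <- 2
  expect_error(adjacency(flat, "pearson"), "ch3")
})

test_that("upper-triangle vectorization and re-folding are exact inverses", {
  expect_equal(length(vectorize_upper(diag(22))), 231)
  expect_equal(length(vectorize_upper(diag(2))), 1)
  expect_equal(length(vectorize_upper(diag(5))), 10)
  set.seed(10)
  A <- matrix(rnorm(36), 6); A <- A + t(A); diag(A) <- 0
  v <- vectorize_upper(A)
  expect_equal(fold_upper(v, 6), A, ignore_attr = TRUE)
  # row-major order: first nc-1 entries are row 1
  expect_equal(unname(v[1:5]), A[1, 2:6])
  expect_error(vectorize_upper(matrix(1, 2, 3)), "square")
})

test_that("Z-scored grand averages localize a planted coupling difference", {
  set.seed(11)
  base <- function() { M <- matrix(runif(36), 6); M <- (M + t(M)) / 2; diag(M) <- 0; M }
  mats_a <- replicate(6, { M <- base(); M[2, 5] <- M[5, 2] <- M[2, 5] + 3; M },
                      simplify = FALSE)
  mats_b <- replicate(6, base(), simplify = FALSE)
  res <- zscore_grand_average(c(mats_a, mats_b), rep(c("A", "B"), each = 6))
  d <- res$difference[["A-B"]]
  expect_equal(d[2, 5], max(d))  # planted pair attains the maximum entry
  expect_equal(res$difference[["A-B"]], -res$difference[["B-A"]])
  # identical matrices in a class: average equals the Z-score of any one
  same <- replicate(3, mats_b[[1]], simplify = FALSE)
  r2 <- zscore_grand_average(c(same, mats_b[1:3]), rep(c("C", "D"), each = 3))
  off <- mats_b[[1]][upper.tri(mats_b[[1]]) | lower.tri(mats_b[[1]])]
  z1 <- (mats_b[[1]] - mean(off)) / sd(off); diag(z1) <- 0
  expect_equal(r2$average$C, z1)
  expect_error(zscore_grand_average(mats_a, c("A", rep("B", 5))), "2 epochs")
})

test_that("bcf extraction tags features by metric and channel pair", {
  ses <- cached_sessions()
  ep <- preprocess_trials(subset_classes(ses$s1, c("LH", "RH")))
  small <- epoch_set(ep$data[, , 1:4], ep$fs, ep$montage, ep$labels[1:4], ep$window)
  fm <- bcf_extract(small, "pli")
  expect_equal(ncol(fm), 45)  # 10 channels -> 45 pairs
  expect_equal(nrow(fm), 4)
  expect_true(all(startsWith(attr(fm, "tags"), "bcf:pli:")))
  expect_true(all(fm >= 0 & fm <= 1))
})
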