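test_that("paradigm configuration enforces its invariants", {
  expect_error(paradigm_config(mi_window = c(5, 8)), "mi_window")
  expect_error(paradigm_config(mi_window = c(3, 2.5)), "mi_window")
  expect_error(paradigm_config(artifact_rate = 1.2), "artifact_rate")
  expect_error(paradigm_config(fs = 50), "twice")
  expect_error(paradigm_config(n_channels = 10, montage = c("a", "b")),
               "montage length")
  cfg <- paradigm_config()
  expect_equal(cfg$trials_per_class * length(cfg$classes), 288)
})

test_that("class signatures validate coupling parameters", {
  expect_error(class_signature(coupling_pairs = list(
    coupling_pair("C3", "C4", strength = 1.5))), "coupling_strength")
  expect_error(class_signature(coupling_pairs = list(
    coupling_pair("C3", "C4", lag = 3 * pi / 2))), "phase_lag")
  expect_error(class_signature(erd_depth = -0.1), "erd_depth")
})

test_that("trial generation rejects unknown labels and missing channels", {
  cfg <- small_cfg()
  sig <- coupling_only_signatures()
  expect_error(generate_trial("XX", sig, cfg), "unknown class")
  bad <- list(LH = class_signature(coupling_pairs = list(
    coupling_pair("C3", "NOPE"))))
  expect_error(generate_trial("LH", bad, cfg), "not in montage")
  bad2 <- list(LH = class_signature(erd_channels = "ZZ"))
  expect_error(generate_trial("LH", bad2, cfg), "not in montage")
})

test_that("generation is deterministic and leaves the caller's RNG alone", {
  cfg <- small_cfg(trials_per_class = 2)
  sig <- coupling_only_signatures()
  a <- generate_trial("LH", sig, cfg, seed = 7)
  b <- generate_trial("LH", sig, cfg, seed = 7)
  expect_identical(a, b)
  set.seed(99)
  expected_draw <- rnorm(1)
  set.seed(99)
  invisible(generate_session(cfg, sig, seed = 3))
  expect_identical(rnorm(1), expected_draw)
  s1 <- generate_session(cfg, sig, seed = 3)
  s2 <- generate_session(cfg, sig, seed = 3)
  expect_identical(s1$data, s2$data)
  expect_identical(s1$labels, s2$labels)
})

test_that("sessions are balanced, finite and sized by the paradigm", {
  cfg <- small_cfg(trials_per_class = 5, artifact_rate = 0)
  ses <- generate_session(cfg, coupling_only_signatures(), seed = 11)
  expect_equal(dim(ses$data)[3], 20)
  expect_true(all(table(ses$labels) == 5))
  expect_true(all(is.finite(ses$data)))
  expect_false(any(ses$artifact_flags))
  one <- generate_session(small_cfg(trials_per_class = 1),
                          coupling_only_signatures(), seed = 1)
  expect_equal(length(one$labels), 4)
})

test_that("artifact flags are drawn at the configured rate", {
  cfg <- small_cfg(trials_per_class = 40, artifact_rate = 0.5)
  ses <- generate_session(cfg, null_signatures(), seed = 5)
  expect_gt(sum(ses$artifact_flags), 40)  # 160 trials, rate 0.5
  expect_lt(sum(ses$artifact_flags), 120)
})

test_that("full coupling strength forces near-constant phase lag (PLI ~ 1)", {
  # shared-phase construction at strength 1, lag pi/4: PLI on the planted
  # pair over the MI window should be >= 0.9 on average over 100 trials
  cfg <- small_cfg()
  sig <- list(LH = class_signature(erd_depth = 0, coupling_pairs = list(
    coupling_pair("C3", "C4", lag = pi / 4, strength = 1))))
  i <- match("C3", cfg$montage); j <- match("C4", cfg$montage)
  win <- round(cfg$mi_window * cfg$fs)
  idx <- (win[1] + 1):win[2]
  vals <- vapply(seq_len(100), function(k) {
    tr <- generate_trial("LH", sig, cfg, seed = 1000 + k)
    xi <- bandpass_zero_phase(tr[i, ], cfg$fs)
    xj <- bandpass_zero_phase(tr[j, ], cfg$fs)
    pli(analytic_signal(xi[idx])$phase, analytic_signal(xj[idx])$phase)
  }, numeric(1))
  expect_gte(mean(vals), 0.9)
})

test_that("zero-depth, zero-strength signatures leave classes indistinguishable", {
  # band power in the MI window should not differ between two classes
  cfg <- small_cfg()
  sig <- null_signatures()
  win <- round(cfg$mi_window * cfg$fs)
  idx <- (win[1] + 1):win[2]
  bp <- function(cl, seeds) vapply(seeds, function(s) {
    tr <- generate_trial(cl, sig, cfg, seed = s)
    mean(bandpass_zero_phase(tr[4, ], cfg$fs)[idx]^2)
  }, numeric(1))
  a <- bp("LH", 1:40)
  b <- bp("RH", 41:80)
  expect_gt(t.test(a, b)$p.value, 0.01)
})

test_that("planted truth reports exactly the planted structure", {
  expect_equal(nrow(planted_truth(list())$coupling), 0)
  expect_equal(nrow(planted_truth(list())$erd), 0)
  sig <- list(
    LH = class_signature(erd_depth = 0, coupling_pairs = list(
      coupling_pair("C3", "C4", lag = pi / 4, strength = 0.8))),
    RH = class_signature(erd_depth = 0))
  tr <- planted_truth(sig)
  expect_equal(nrow(tr$coupling), 1)
  expect_equal(tr$coupling$class, "LH")
  expect_equal(tr$coupling$ch_i, "C3")
  expect_equal(tr$coupling$ch_j, "C4")
  # strength-0 pairs are not class structure
  sig0 <- list(LH = class_signature(erd_depth = 0, coupling_pairs = list(
    coupling_pair("C3", "C4", strength = 0))))
  expect_equal(nrow(planted_truth(sig0)$coupling), 0)
  # identical signatures are flagged non-separable
  same <- null_signatures()
  ns <- planted_truth(same)$nonseparable
  expect_equal(nrow(ns), 6)  # all pairs of 4 identical classes
  dif <- planted_truth(coupling_only_signatures())$nonseparable
  expect_equal(nrow(dif), 0)
})
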