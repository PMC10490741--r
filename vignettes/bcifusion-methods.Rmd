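---
title: "Methods: scattering features, functional connectivity and session transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scattering features, functional connectivity and session transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in
`bcifusion`, the assumptions behind them, the defaults and why they were
chosen, and the decisions taken where the underlying methodology is
genuinely open. It states no empirical result beyond what the package's
test suite computes.

## 1. Preprocessing

Trials (channels × samples, in µV) pass through, in order:

1. **Artifact exclusion.** Trials flagged as artifacts are dropped;
   nothing is repaired.
2. **Zero-phase band-pass, 8–30 Hz.** An order-4 Butterworth band-pass is
   applied forward and backward (`filtfilt`), so the phase response is
   identically zero and the magnitude response is the squared one-pass
   response. This band covers the µ (8–12 Hz) and β (13–30 Hz) rhythms in
   which motor-imagery ERD/ERS lives. Edges are handled by odd-symmetric
   reflection padding of length 3 × (filter state length), the standard
   way to keep startup transients off the retained samples. The filter
   order is not dictated by the methodology; order 4 per pass is the
   common EEG default (sharp band edges without ringing) and is exposed
   as a parameter.
3. **Baseline correction.** Per channel, the mean over the baseline
   window is subtracted from the whole trial. The default window,
   0–2 s, is the fixation period of the cue-based paradigm; it is a
   package choice (exposed as a parameter) since only the presence of a
   baseline step, not its window, is methodologically fixed.
4. **Common average reference (CAR).** The instantaneous cross-channel
   mean is subtracted from every channel. CAR and the band-pass are both
   linear, so their order is immaterial up to numerical noise (a
   property the suite verifies); the implemented order follows the
   conventional narrative: filter, baseline, re-reference.
5. **Epoching.** The motor-imagery analysis window, 2.5–5 s after trial
   onset, is cut with the half-open convention `[start, end)` on 0-based
   sample indices, making sample counts exact: at 250 Hz the epoch is
   exactly 625 samples. No 50 Hz notch is applied by default: recordings
   of the target paradigm ship notch-filtered.

## 2. Brain-connectivity features (BCFs)

Per epoch and channel, the discrete analytic signal
`z(t) = x(t) + i·xH(t)` is built by the frequency-domain construction
(zero the negative frequencies, double the positive ones). The
instantaneous amplitude is `A(t) = |z(t)|` and the instantaneous phase
`φ(t) = atan2(xH, x)`, wrapped to (−π, π]. Two notes:

- The phase uses the **four-quadrant** arctangent. A two-quadrant
  arctan of `xH/x` loses the component signs and breaks phase
  continuity; the four-quadrant form is the deliberate, documented
  choice.
- The epoch is transformed without padding. Hilbert edge effects decay
  well inside a 625-sample epoch; tests therefore assess amplitude and
  phase on the central 80% of samples.

Three pairwise metrics produce symmetric `nc × nc` adjacency matrices
(each unordered pair computed once):

- **PLI** `= |mean(sign(Δφ(t)))|` with Δφ wrapped to (−π, π] before the
  sign and `sign(0) = 0` — the standard convention, which makes exactly
  zero-lag coupling score 0, so common-reference and volume-conduction
  artifacts are invisible to it. Diagonal 0.
- **PC** — Pearson correlation between the two wrapped phase series.
  Wrapping is kept by default (`unwrap = TRUE` is available) because the
  statistic is defined on φ directly and unwrapping changes it. The
  cov/√(var·var) ratio is identical under population or sample variance
  normalization as long as the choice is consistent; the suite checks
  consistency against a population-variance loop oracle. Diagonal 1.
- **Pearson** — correlation of the band-passed signal series themselves
  (not the amplitude envelopes; an amplitude mode can be had by passing
  `A(t)` explicitly). Diagonal 1.

Each matrix is vectorized into its strict upper triangle, row-major —
`nc(nc−1)/2` values, 231 for 22 channels — with an explicit pair map so
every feature remains attributable to a channel pair. Degenerate inputs
(zero-variance channel, all-zero signal) raise errors naming the channel
rather than returning NaN.

For visualization, `zscore_grand_average()` standardizes each epoch's
off-diagonal values (mean 0, sd 1 within the epoch's matrix) before
averaging across epochs of a class; class differences are elementwise.
The within-epoch Z-score removes epoch-level global connectivity
offsets, which otherwise dominate class averages.

## 3. Translation-invariant features (TIFs)

A two-order, one-dimensional scattering cascade with Morlet-type filters:

- order 0: low-pass average of the epoch;
- order 1: low-passed modulus of each wavelet convolution,
  `|x ∗ ψ_λ1| ∗ φ`;
- order 2: `||x ∗ ψ_λ1| ∗ ψ_λ2| ∗ φ`, kept only for frequency-decreasing
  paths (ξ2 < ξ1), where the modulus of the first stage has its energy.

Defaults: invariance scale **T = 2 s** (the scale reported to work best
for this paradigm in prior work), **Q1 = 8** and **Q2 = 1** wavelets per
octave, orders ≤ 2 — the standard configuration for audio-length
biosignals. Filters are Gaussian band-passes with a zero-mean (Morlet)
correction, tiling 0.4·fs down to `fs/2^J`, `J = round(log2(T·fs))`; the
low-pass is a Gaussian of standard deviation T/4 s (support ≈ T). All
band-pass responses share one rescaling factor chosen so the
Littlewood–Paley sum `|φ̂|² + Σ|ψ̂|²` never exceeds 1, which makes every
stage — and hence the cascade — non-expansive; the suite fuzz-tests both
the frame bound (≤ 1.05 numerically) and `‖S(x) − S(y)‖ ≤ ‖x − y‖`.

**Reduction.** Each path's low-passed output is reduced to one time
average per invariance window: `floor(epoch/T)` frames, at least one.
With the default T = 2 s on the 2.5 s epoch this is exactly **one scalar
per path** — the epoch barely exceeds the scale, and a 1–2 sample "time
axis" of unstable length would be noise. Smaller scales genuinely retain
more temporal resolution, which is what makes shift sensitivity decrease
as T grows (a tested property). Convolutions use reflection padding;
with 2.5 s epochs, circular wrap-around would be material.

Coefficients are kept raw (no logarithm) by default so the
non-expansiveness property remains testable; this is a package decision
where the methodology is silent.

**Channel subset.** TIFs are extracted from a sensorimotor subset rather
than all 22 channels. The conventional description of that subset — "the
central, fronto-central and centro-parietal rows, half of the channels" —
is internally inconsistent on the 22-channel montage (those full rows
hold 17 electrodes). The package fixes the default to the 11
midline-centered electrodes FC1, FCz, FC2, C3, C1, Cz, C2, C4, CP1, CPz,
CP2 (`mi_channel_subset()`), and any other subset can be passed
explicitly.

## 4. Fusion, selection, classification

Fusion is serial concatenation with provenance tags (`tif:…`, `bcf:…`),
so fused matrices can always be sliced back into their sources. The
multiclass Fisher score uses population (divide-by-n_k) per-class
variances, matching the n_k-weighted form of the score; the degenerate
denominator rule is: numerator 0 → score 0, otherwise +∞ (a
zero-variance feature that separates classes is maximally
discriminative). Selection takes the S highest scores, ties broken by
ascending feature index for determinism.

The number of selected features S is not methodologically fixed; it is
treated as a hyperparameter searched on the training folds over a
documented grid (default {50, 100, 200, 400}, truncated to the feature
count). Likewise the SVM grid: C ∈ 2^(−3…9), γ ∈ 2^(−11…1), log-2
steps. The search protocol — one reading of an ambiguous convention — is:
for every (C, γ, S), stratified 10-fold CV on the training set with
Fisher scores, selection and standardization refit inside each fold's
training part (no leakage into held-out folds); the best mean-CV-accuracy
triple is refit on the full training set, and that best CV mean is
reported as validation accuracy. Fold assignment is stratified (the
design is class-balanced) and derives from a fixed, documented seed, so
training is deterministic given data and grid. Features are z-scored
with training statistics by default (RBF kernels are scale-sensitive);
constant features are centered, not scaled.

The one-versus-rest ensemble fits one binary RBF-SVM per class and
decides by argmax of decision values, with the decision-value sign
normalized to the positive class regardless of internal label order.

## 5. Transfer protocols and statistics

- **SST**: session 1 trains, session 2 tests.
- **CST** (fraction 0.40 by default): per class, the chronologically
  first `floor(0.4 · n_class)` session-2 epochs join the training set —
  "first" is read as recording order, and flooring keeps the calibration
  set no larger than the stated fraction; the remaining session-2 epochs
  are the test set. Train and test are disjoint by construction and the
  test set is drawn from session 2 only (fuzz-tested).

Accuracy is `100·trace/total` of the confusion matrix; Cohen's kappa
`(p_o − p_e)/(1 − p_e)` with marginal-product expected agreement;
precision and recall are macro-averaged one-vs-rest (micro-averaging
would equal accuracy under the balanced design and add nothing), with
never-predicted classes contributing 0. The Wilcoxon signed-rank
comparison is exact: zero differences dropped, midranks for ties, and
the two-sided p from the full distribution of the signed-rank sum over
all 2^n sign assignments (computed by the shift algorithm over doubled
midranks; verified against a brute-force enumeration oracle for all
n ≤ 12). With nine paired subjects this exact small-n regime is the
appropriate test.

## 6. The synthetic generator: what it does and does not emulate

`generate_session()` reproduces the *paradigm*: 7.5 s trials at 250 Hz,
four balanced classes × 72 trials in randomized order, two sessions,
artifact flags drawn at a configurable rate (flagged, not corrupted —
the pipeline only ever excludes them), and the 2.5–5 s MI window. Class
structure is planted through `class_signature()`:

- **ERD**: every channel carries 1/f-like background noise (white plus
  AR(1), a = 0.95), a µ-band carrier (unit amplitude, per-trial frequency
  jitter inside the band, phase diffusion, slow amplitude modulation) and
  a weaker β oscillation (amplitude 0.4). On the signature's ERD channels
  the carrier amplitude is scaled by (1 − depth) during the MI window,
  with 0.2 s raised-cosine ramps.
- **Coupling**: each coupled pair receives a shared band-limited phase
  process (default 20 Hz) injected into both channels with a fixed lag,
  scaled by `3 × strength` inside the MI window. The factor 3 makes the
  shared process dominate the pair's in-band phase at full strength, so
  the construction delivers its defining observable: a near-constant
  measured lag (PLI → 1). Per-channel frequency jitter elsewhere is
  essential — independent oscillators at one shared fixed frequency
  would hold an almost constant phase difference across a 2.5 s epoch
  and show spurious synchrony.

No generative model is dictated by the methodology; all signature
defaults are package choices, documented here, chosen once to resemble
textbook sensorimotor ERD topography (RH→C3, LH→C4, feet→Cz,
tongue→fronto-central) at effect sizes a clean laboratory dataset might
show. The generator does **not** emulate: volume conduction through a
head model (CAR leakage is the only cross-channel mixing), EOG/ocular
artifacts, inter-session covariate shift, inter-subject variability, or
non-stationarities beyond slow amplitude modulation. Consequently,
passing recovery tests demonstrates that the pipeline detects the kinds
of structure it claims to detect — channel-local band power and
inter-channel phase lag — not that it attains any particular accuracy on
real recordings, where session-to-session drift is typically the
dominant difficulty.

One emergent caution the tests surfaced: CAR spreads a strongly coupled
pair's oscillation into every channel as a common, zero-lag component.
Phase correlation and Pearson correlation see that leakage; the PLI, by
construction, does not. Recovery tests that need to localize a planted
pair therefore use the PLI, and this is exactly the volume-conduction
robustness argument made for the PLI in the connectivity literature.

## 7. Problem sizes and numerical conventions

The test suite runs everything at reduced scale, a deliberate package
choice so the full property suite (including 20-seed end-to-end recovery)
stays fast: a 10-channel sensorimotor montage, 8–16 trials per class,
4-fold CV, and compact SVM grids. The classifier, protocols and feature
extractors are identical at full scale; nothing in the implementation
depends on the reduced sizes. Oracle-equivalence tolerances are 1e−12
(identical arithmetic, different code paths); closed-form signal checks
use 2–5% tolerances reflecting Hilbert/filter edge effects.

Degenerate-input conventions, collected: all-zero signal → error (phase
undefined); zero-variance channel → error naming the channel; zero
within-matrix variance → error in Z-scoring; all-zero paired differences
→ p = 1 with a warning; constant features → Fisher score 0, centered but
unscaled; empty test set → error.

## 8. Known limitations

- The scattering implementation is a reference cascade written for
  clarity and testability; it is not the fastest possible (FFT-per-path)
  but processes a 625-sample epoch-channel in ~25 ms.
- The GDF adapter for real competition recordings is out of scope; real
  data enter through `trial_set()`.
- Exact Wilcoxon enumeration is limited to n ≤ 25 pairs; beyond that a
  normal approximation (not implemented) is the standard tool.
- The CST protocol assumes session-2 epochs are in recording order;
  shuffled inputs would silently change "first 40%".
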