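# bcifusion

Feature fusion of wavelet-scattering and functional-connectivity features
for multiclass motor-imagery EEG classification.

## The problem

A motor-imagery brain–computer interface (MI-BCI) decodes which movement a
user is *imagining* (left hand, right hand, feet, tongue) from multichannel
EEG. Classical pipelines extract features channel by channel and ignore the
interactions between channels, which limits multiclass performance: the
four imagery tasks engage adjacent sensorimotor areas whose channel-local
signatures (μ/β-band event-related desynchronization, ERD) overlap heavily.

`bcifusion` implements a pipeline that combines two complementary feature
families and classifies their fusion:

- **TIFs (translation-invariant features).** A scattering convolution
  network — iterated Morlet wavelet convolution, complex modulus and
  low-pass averaging — applied per epoch to a sensorimotor channel subset.
  Coefficients are invariant to temporal shifts up to the invariance scale
  *T* (default 2 s) and stable to deformation, with no learned weights.
- **BCFs (brain-connectivity features).** Per epoch, a symmetric
  functional-connectivity matrix over all channel pairs, vectorized into
  its nc(nc−1)/2 upper-triangle values. Metrics: phase correlation (PC,
  Pearson correlation of Hilbert instantaneous phases), plain Pearson
  correlation of the band-passed signals, and the phase lag index
  PLI = |⟨sign Δφ(t)⟩|, which is blind to zero-lag (volume-conduction)
  coupling.

Fusion is serial concatenation (an *n*-dimensional TIF vector and an
*m*-dimensional BCF vector give an (*n*+*m*)-dimensional feature vector).
Features are ranked by the multiclass Fisher score

F(X_j) = Σ_k n_k (μ_k(j) − μ(j))² / Σ_k n_k σ_k(j)²,

the top-*S* set is selected inside each training fold, and a one-versus-rest
RBF-kernel SVM (grid-searched C, γ with stratified 10-fold cross-validation)
does the classification. Two transfer protocols are built in:

- **SST** (session-to-session): train on session 1, test on session 2;
- **CST** (calibration-session): the chronologically first 40% of session 2,
  class-balanced, joins the training set; the remaining 60% is the test set.

Performance is reported as accuracy, Cohen's kappa, macro precision/recall,
and paired configurations are compared with an **exact** two-sided Wilcoxon
signed-rank test (zero differences dropped, midranks for ties, full
enumeration of sign assignments).

Because the package is developed against simulated data, it ships a
first-class synthetic session generator (`generate_session()`) that
emulates the cue-based 4-class paradigm — 7.5 s trials at 250 Hz, 72 trials
per class per session, MI window 2.5–5 s — with plantable, class-dependent
ERD (spectral) and phase-lag coupling (connectivity) structure, so every
claim the pipeline makes can be tested against known ground truth
(`planted_truth()`). An adapter for real recordings is a matter of filling
a `trial_set()` from your reader of choice.

## Worked example

Simulate two sessions with the default class signatures (contralateral
hand-area ERD plus one class-specific phase-coupled pair per class), then
compare channel features alone against the fusion under session-to-session
transfer:

```r
library(bcifusion)

cfg <- paradigm_config(trials_per_class = 12)     # 48 trials/session demo
s1  <- generate_session(cfg, default_signatures(), seed = 1, session_id = "S1")
s2  <- generate_session(cfg, default_signatures(), seed = 2, session_id = "S2")
s1
#> <trial_set> session S1: 22 channels x 1875 samples x 48 trials @ 250 Hz
#>   classes: F=12, LH=12, RH=12, T=12
#>   artifact-flagged trials: 0

grid <- classifier_grid(cost = c(1, 32), gamma = c(0.001, 0.01),
                        n_features = c(60, 120))
mi_transfer_eval(s1, s2, "tif",    "sst", grid = grid, n_folds = 4)
#> <mi_transfer_result> SST / tif
#>   validation accuracy 66.67% | test accuracy 72.92%, kappa 0.64, precision 0.72, recall 0.73
mi_transfer_eval(s1, s2, "tif+pc", "sst", grid = grid, n_folds = 4)
#> <mi_transfer_result> SST / tif+pc
#>   validation accuracy 83.33% | test accuracy 91.67%, kappa 0.89, precision 0.92, recall 0.92
```

Fusing connectivity features with the scattering features lifts test
accuracy from 72.9% to 91.7% here, because part of the planted class
structure lives only in inter-channel phase lags that channel-local
features cannot see. Validation accuracy is the best cross-validated mean
on the training session; test accuracy is measured on the held-out session.

The package also bundles the published per-subject benchmark accuracies for
this paradigm on BCI Competition IV dataset IIa
(`reference_session_transfer()`), so the paired statistics can be
reproduced directly:

```r
ref <- reference_session_transfer()
w <- wilcoxon_signed_rank_exact(ref$sst_tif_test, ref$sst_fused_test)
sprintf("exact signed-rank p = %.4f (n = %d)", w$p.value, w$n)
#> "exact signed-rank p = 0.0039 (n = 9)"
```

A thin command-line interface (`inst/cli/bcifusion`) wraps simulation,
preprocessing, evaluation and paired comparison; see `?mi_cli`.

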