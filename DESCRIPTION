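Package: bcifusion
Title: Feature Fusion of Wavelet-Scattering and Functional-Connectivity
    Features for Multiclass Motor-Imagery EEG Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A signal-processing and classification pipeline for multiclass
    motor-imagery brain-computer interfaces (MI-BCI). Provides a synthetic
    MI-EEG session generator with plantable event-related desynchronization
    and phase-coupling class structure, standard EEG preprocessing (zero-phase
    Butterworth band-pass, baseline correction, common average reference,
    epoching, artifact-trial exclusion), Hilbert-phase functional-connectivity
    features (phase lag index, phase correlation, Pearson correlation), a
    one-dimensional Morlet wavelet-scattering cascade producing
    translation-invariant features, multiclass Fisher-score feature selection
    with serial feature fusion, and one-versus-rest RBF-SVM classification
    under session-to-session and calibration-session transfer protocols with
    exact Wilcoxon signed-rank comparison of paired results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
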