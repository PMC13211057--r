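Package: eegdecoder
Title: Hybrid CNN-Transformer Decoding of Clinical EEG with
    Leave-One-Subject-Out Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for subject-independent classification of multichannel
    clinical EEG into Alzheimer's disease, Creutzfeldt-Jakob disease and
    healthy-control groups. Provides EDF input/output with artifact-interval
    sidecar annotations, a clinical preprocessing pipeline (segment excision,
    band-pass and notch filtering, ICA-based ocular artifact removal,
    5-second epoching, leakage-safe normalization), a compact hybrid
    one-dimensional CNN plus Transformer-encoder classifier with an
    EEGNet-8,2 baseline, nested leave-one-subject-out cross-validation with
    majority-vote subject aggregation and dual-level metrics, a synthetic
    EEG cohort generator with class-dependent spectral signatures for fully
    reproducible end-to-end testing, and edge-deployment tooling (parameter
    and FLOP accounting, portable model export with an independent NumPy
    reference runtime, per-trial latency profiling).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    MASS,
    signal,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    caret,
    yaml
SystemRequirements: Python (>= 3.8) with NumPy, for the portable-model
    reference runtime and export equivalence checks.
Config/testthat/edition: 3
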