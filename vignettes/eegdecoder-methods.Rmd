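---
title: "Methods: hybrid CNN-Transformer decoding of clinical EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid CNN-Transformer decoding of clinical EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model, the
preprocessing pipeline, the evaluation protocol, the synthetic cohort that
stands in for clinical data, and the numerical and design choices behind
each. Nothing stated here as an empirical result goes beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## The problem

Scalp EEG is a cheap, non-invasive window on cortical dynamics, and both
Alzheimer's disease (AD) and Creutzfeldt-Jakob disease (CJD) leave
signatures in it: diffuse slowing with attenuated posterior alpha in AD,
and quasi-periodic sharp-wave complexes (PSWCs, roughly 1 Hz) in CJD.
The package classifies 5-second, 19-channel EEG trials into
AD / CJD / healthy control (CNTRL) — and, crucially, evaluates the
classifier *subject-independently*: trials from one person must never
inform the model that is tested on that same person, because trial-level
random splits are contaminated by subject identity and produce wildly
optimistic accuracy estimates.

## The classifier

`build_eegdecoder()` constructs a compact hybrid network (654,723
trainable parameters; about 201 MFLOPs per inference under the convention
below):

1. **Temporal feature extractor.** Two 1-D convolutions over the
   19-channel signal — 19→64 channels with kernel 25, then 64→64 with
   kernel 15 — each followed by batch normalization, an ELU, and
   max-pooling by 4. All convolutions are *valid* (unpadded): the
   documented intermediate lengths 1280 → 1256 → 314 → 300 → 75 only hold
   without padding, so valid convolutions are a derived fact of the
   architecture, not a free choice.
2. **Transformer encoder.** The 64×75 feature map is transposed into a
   sequence of 75 time steps with 64-dimensional embeddings and passed
   through 2 post-norm encoder layers (2 attention heads with
   `d_k = 32`, feed-forward width 2048 with ReLU, dropout 0.1, residual
   connection then layer normalization). Scaled dot-product attention is
   `softmax(QK'/sqrt(d_k))V`; each row of the attention matrix is a
   probability distribution over time steps.
3. **Head.** Mean pooling over the 75 time steps gives a 64-vector; a
   single linear layer produces 3 raw class scores. Training minimizes
   multi-class cross-entropy (the standard loss for a linear score head).

Three encoder details deserve flagging because they are *inferred*:

* **Feed-forward width 2048, dropout 0.1, ReLU, post-normalization** are
  the conventional Transformer-encoder defaults. The exact parameter
  count confirms the width: no other feed-forward dimension reproduces
  654,723.
* **No positional encoding.** The parameter count leaves no room for
  learned positional parameters, and none is part of the design. The
  sequence order still matters through the convolutional front end, but
  the encoder itself is permutation-equivariant; `count_parameters()`
  would expose any deviation.
* **Convolution biases are present** even though batch normalization
  immediately follows (they are redundant in function but part of the
  count).

`build_eegnet()` provides the EEGNet-8,2 baseline (temporal filter bank
F1 = 8, depthwise spatial filters with depth multiplier D = 2 under a
max-norm-1 constraint, separable convolution with F2 = 16 maps, average
pooling 4 and 8, dropout 0.25). Details the configuration leaves open
(separable kernel 16, pooling sizes, max-norm constant) follow the
original compact-EEGNet design.

### Two implementations, one architecture

Training needs roughly 600 MFLOPs per trial per pass, which R-level code
cannot sustain on one CPU. The package therefore carries the forward and
backward passes twice: a plain-R double-precision reference
implementation (every layer an explicit function, validated against
central finite differences), and a single-precision compiled path
(RcppArmadillo) used by `train_model(backend = "fast")`. The test suite
asserts gradient agreement between the two on every tensor; tensors whose
true gradient is identically zero (key-projection biases under softmax
shift invariance, convolution biases absorbed by batch-norm centering)
agree only to round-off, which is the expected behaviour, not a defect.
Both backends are deterministic given the training seed, but they draw
shuffling and dropout from different generators, so their histories are
statistically, not bitwise, equivalent.

### Footprint accounting

`count_flops()` uses one fixed convention: a multiply-accumulate in a
convolution, attention projection/product, feed-forward or classifier
layer counts as 2 FLOPs; elementwise work (bias additions, normalization
scale/shift, activations, residual additions, softmax terms, pooling
comparisons) counts once per scalar. Under this convention the default
decoder needs about 201 MFLOPs per trial, of which the MAC backbone is
about 99.8 M MACs. Published FLOP figures for the same architecture vary
by roughly ±10% depending on whether elementwise terms are included;
the accounting here makes every term explicit (`count_flops(m,
breakdown = TRUE)`).

## Preprocessing pipeline

`preprocess_recording()` fixes the stage order: **excise → filter →
resample → ICA → epoch**.

* **Excision.** Clinical recordings carry annotated corrupted intervals
  (electrode pops, movement, acquisition gaps). Intervals are merged by
  union, converted to samples with half-open `[onset, offset)` semantics
  (no boundary sample is double-counted), and cut out; everything
  downstream operates within the resulting clean runs, so no trial ever
  spans a splice point. Excised plus retained duration equals the
  recording duration to one sample (asserted in the tests).
* **Filtering** is a zero-phase 4th-order Butterworth band-pass
  (1.6-40 Hz) followed by a Q = 30 biquad notch at 50 Hz, applied per
  clean run — filtering across stitched discontinuities would smear
  filter transients over clean data. Whether the original analysis
  filtered before or after excision is not documented; per-run filtering
  is this package's documented choice, and on artifact-free input the
  order is immaterial (tested).
* **Resampling** to 256 Hz uses Fourier-domain truncation (delay-free
  ideal low-pass); only downsampling is supported, since that is the
  only direction the protocol requires. An off-the-shelf polyphase
  resampler was rejected because its uncompensated group delay shifted
  the signal by several samples.
* **Ocular ICA.** Symmetric FastICA (logcosh contrast, seeded random
  orthogonal start) on a PCA whitening that retains ≥ 95% of variance.
  Components are scored by |correlation| with a surrogate EOG — the
  Fp1/Fp2 mean, since a 19-channel 10-20 montage has no dedicated EOG
  lead — and flagged by a z > 3 outlier rule. With the ~6-15 components a
  19-channel decomposition yields, a z-score computed *including* the
  candidate can mathematically never exceed 3, so the score is
  standardized against the other components (leave-one-out). Flagging is
  single-pass: iterating the rule re-standardizes after removing the
  ocular component and then promotes borderline brain components, which
  measurably damaged posterior rhythm power in development runs. Runs
  shorter than 30 s skip ICA (decomposition instability), and a failed
  decomposition falls back to the identity with a warning — never to a
  hard error mid-pipeline.
* **Epoching** cuts non-overlapping 5-s windows inside each run, in
  temporal order, capped at 40 per subject (earliest-first: the cap's
  selection order is not documented anywhere, and temporal order is the
  deterministic choice). 200 s of clean signal yields exactly 40 trials;
  87 s yields 17.
* **Normalization** is per-channel z-scoring whose mean and standard
  deviation are fitted on training trials only; the same parameters are
  applied to validation and test data. The test suite demonstrates the
  leakage-safety consequence: a mean-shifted test set stays off-center
  after normalization with train-fitted parameters.

## Evaluation protocol

`run_loso()` implements nested leave-one-subject-out cross-validation:

* **Outer loop**: each subject is held out once.
* **Inner loop**: remaining subjects are partitioned into
  class-stratified, subject-level folds (default 5). Stratification is
  this package's choice where the protocol is silent; it prevents
  validation folds without some class. Per fold: normalizer fitted on
  the fold's training subjects, model trained by Adam (learning rate
  1e-3, weight decay 1e-4, batch 64, at most 30 epochs) with early
  stopping on validation accuracy at patience 10.
* **Selection**: the single model with the best inner validation
  accuracy — whichever fold produced it — is carried, together with its
  own normalizer, to the held-out subject ("best validation performance
  across folds", read literally).
* **Aggregation**: subject prediction by majority vote over trial
  predictions; ties break toward the candidate with the larger summed
  class score (deterministic, and it uses the available evidence; the
  aggregation rule itself does not specify tie handling).
* **Leakage assertions**: the held-out subject must be absent from every
  inner fold (hard `stopifnot` at run time), and normalizers never see
  non-training trials by construction.

`compute_metrics()` reports both levels because they answer different
questions: trial-level accuracy weights subjects by their trial counts;
subject-level accuracy (after majority voting) weights each person
equally, which is the clinically relevant rate. Precision, recall and F1
use one-vs-rest counts with class-support weighting (equal to macro
averaging in a balanced cohort — both are emitted); Cohen's kappa
`(p_o - p_e) / (1 - p_e)` is computed from both confusion matrices.

## The synthetic cohort

`generate_cohort()` produces EDF recordings plus artifact sidecars with
the statistical structure the protocol assumes, so the entire pipeline is
testable without clinical data. Per subject the signal is a sum of
latent sources mixed to the scalp, in microvolts:

* **Background**: 8 latent 1/f^β Gaussian sources with random unit-norm
  topographies (volume conduction makes real scalp channels strongly
  correlated; an early per-channel-independent background made the ICA
  problem ill-posed — 19 independent sources cannot be separated from a
  ≤15-component decomposition) plus 15% sensor noise. β is 1.0-1.2 by
  class; background RMS 10 µV.
* **Class rhythm**: amplitude-modulated sinusoid at the class center
  frequency (CNTRL 10 Hz at 18 µV; AD 9 Hz attenuated to 7 µV; CJD
  9.5 Hz at 10 µV) with posterior topography.
* **Slowing**: diffuse 1-7 Hz band-limited noise (AD 16 µV, CJD 9 µV,
  CNTRL 4 µV).
* **PSWCs** (CJD only): a triphasic ~0.4 s template repeated at 1 Hz with
  ±10% period jitter, 55 µV, central topography.
* **Blinks**: Poisson arrivals (8-14 per minute) of smooth positive
  frontal deflections inside 0.5-2 s windows, 120 µV at Fp1/Fp2. The
  waveform is deliberately sharp-peaked: the 1.6 Hz high-pass removes
  most of a broad blink, and the preprocessing contract (ocular
  correlation drop ≥ 50% after ICA) is only meaningful if blink energy
  survives the filter.
* **Artifacts**: Poisson-distributed segments alternating electrode-pop
  steps (one channel, 400-900 µV, exponential decay) and movement bursts
  (all channels, 150-300 µV), with exact extents returned as the
  annotation ground truth.

Inter-subject variability follows the stated hierarchical model:
peak-frequency jitter Normal(0, 0.5 Hz), gain multiplier
LogNormal(0, 0.2), topography perturbation Normal(0, 0.05), and
subject-specific background topographies. Per-subject seeds are derived
by counter from the master seed, so generating more subjects never
changes existing ones, and the whole cohort is a pure function of
(spec, seed) — regeneration is byte-identical.

The default class gains were chosen once, before any classifier run, to
produce unambiguous canonical phenotypes (a "strong-effect" cohort):
posterior theta/alpha ratio separates AD from CNTRL at Mann-Whitney
p < 0.01 with 6 subjects per class, and the PSWC train is visible by eye.
What passing tests on this cohort show is that the *pipeline and
protocol* work end to end — excision, ICA, leakage-free training,
voting — and that the classifier recovers class structure it is entitled
to recover. They do not show clinical-grade performance: real EEG has
richer artifact taxonomy, non-stationarity, drugs, age confounds, and
far subtler class differences.

## Desk-scale evaluation sizes

The full-scale study design (36 subjects × 40 trials × 5 inner folds,
up to 30 epochs, five seeds) amount to thousands of full training runs of
a 654k-parameter network on ~1,100 trials each — a multi-day computation
on a single CPU in any implementation. The package's own recovery
experiment therefore runs the *identical nested protocol* at desk scale:
4 subjects per class (12 subjects), 10 trials per subject (80-s
recordings), 3 inner folds, 5 epochs, batch 8, two seeds (42 and 2025),
with the default strong-effect class signatures, plus a label-shuffled
chance-level control trained for one epoch. The sizes were frozen from
throughput-and-recovery pilots run under separate seeds before the test
seeds were ever evaluated; they are stated here once and used by the
acceptance test. The CLI runs the full-size protocol unchanged
(`eegdecoder.R train-loso --seeds 42,99,123,2025,2026 ...`) for anyone
with the budget. At desk scale each inner model sees only 7-8 training
subjects, so subject-level transfer is harder, not easier, than in the
full design — the dominant failure mode is a single atypical subject
(an outlying gain or topography draw) being misvoted wholesale — and the
recovery thresholds (mean subject accuracy ≥ 80%, kappa ≥ 0.7) were
kept as stated rather than recalibrated.

## Numerical choices and degenerate inputs

* EDF quantization uses the fixed clinical range ±3276.7 µV at 16 bits
  (0.1 µV steps, round-trip error ≤ 0.05 µV); samples outside the range
  are clipped by the generator and rejected by the writer. Labels never
  enter EDF headers (anonymization); they live in the manifest.
* The trial container stores float32 (little-endian, C order) — EEG at
  0.1 µV resolution gains nothing from float64 — and the loader verifies
  byte counts against the manifest shape before reading.
* Batch normalization uses momentum 0.1 and ε = 1e-5; running variance
  stores the unbiased estimate. Layer normalization uses ε = 1e-5. Adam
  uses the standard bias correction with ε = 1e-8 and *coupled* weight
  decay (L2 added to the gradient), matching the optimizer the training
  configuration names.
* Early stopping keeps the weights and batch-norm statistics of the best
  validation epoch; improvement requires exceeding the incumbent by more
  than 1e-12 (ties do not reset patience).
* A constant channel normalizes to zeros through the ε-guard rather than
  NaN. An empty trial set warns and is excluded downstream rather than
  erroring, matching how a heavily artifacted subject should degrade.
* `cohen_kappa()` defines the degenerate single-cell table (chance
  agreement exactly 1) as 1 for perfect agreement and an error
  otherwise.
* The portable model format stores float64 tensors; quantizing to
  float32 at export would cost nothing in deployment but would weaken the
  equivalence check (the NumPy runtime reproduces native scores to
  ~1e-15, so any disagreement above tolerance is a real defect, not
  serialization noise).

## Known limitations

* The synthetic cohort is a statistical stand-in, not a biophysical
  simulation: no head model, no EMG/ECG taxonomy, no non-stationary
  disease progression. Claims transfer to clinical data only at the
  level of protocol correctness.
* FastICA on 19 channels with short runs occasionally fails to isolate
  the ocular source (roughly 1 in 12 development seeds); the pipeline
  then leaves the run unchanged rather than guessing.
* The compiled training path supports the decoder only; EEGNet trains
  through the reference path, which is adequate for its role as a
  baseline at reduced scale but slow at full scale.
* Latency profiling measures this host; the numbers are reported, never
  asserted, because they are hardware facts, not software facts.
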