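---
title: "Methods: emotion classification from prefrontal fNIRS hemodynamics"
author: "fnirsEmotion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: emotion classification from prefrontal fNIRS hemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnirsEmotion)
```

## The problem and the data model

Functional near-infrared spectroscopy (fNIRS) measures cortical hemodynamics
by recording the attenuation of near-infrared light at two wavelengths.
`fnirsEmotion` implements an end-to-end pipeline for a ternary
emotion-recognition task (0 joy, 1 neutral, 2 sad) from an 8-channel
prefrontal montage sampled at 10 Hz during a block-design session: 60 s of
pre-task rest, then three 4-min movie clips (one per emotion), each followed
by 60 s of rest — 960 s and 9600 samples per trial.

The pipeline's data containers are S4 classes:

* `OpticalDensitySeries` — per-channel optical-density changes
  $\Delta A(\lambda, t)$ at 735 and 850 nm;
* `HemoglobinSeries` — per-channel $\Delta c_{HbO_2}(t)$ and
  $\Delta c_{Hb}(t)$;
* `TrialRecord` / `TrialMatrix` — a full recording with its protocol
  annotation, laid out as a 9600 × 16 matrix (columns 1–8: $\Delta HbO_2$
  of channels 1–8; columns 9–16: $\Delta Hb$);
* `WindowDataset` — labeled fixed-length windows with provenance.

## Modified Beer–Lambert conversion

At each wavelength the optical-density change relates linearly to the two
chromophore concentration changes:

$$\frac{\Delta A(\lambda)}{d \cdot DPF(\lambda)} =
  \epsilon_{HbO_2}(\lambda)\,\Delta c_{HbO_2} +
  \epsilon_{Hb}(\lambda)\,\Delta c_{Hb},$$

with $d$ the source–detector distance (3 cm), $DPF$ the differential path
factor and $\epsilon$ the extinction coefficients. With two wavelengths this
is a 2 × 2 linear system per sample; `odToHb()` solves it exactly (one LU
factorization of the extinction matrix per channel, applied to all time
points) rather than hard-coding the closed-form solution — the closed forms
are kept as an independent oracle in the test-suite. Default parameters:

| wavelength | DPF | $\epsilon_{HbO_2}$ (cm$^{-1}$) | $\epsilon_{Hb}$ (cm$^{-1}$) |
|---|---|---|---|
| 735 nm | 6.058 | 0.4646 | 1.2959 |
| 850 nm | 5.5 | 1.1596 | 0.7861 |

`hbToOd()` is the exact forward model, so the simulator can emit optical
input for the whole pipeline and the round trip is an identity to numerical
precision. The conversion assumes baseline-referenced $\Delta A$; absolute
concentrations, scattering corrections and partial-volume factors are out of
scope.

## Physiological-noise filtering

fNIRS signals carry cardiac (1–1.5 Hz), respiratory (≈ 0.4 Hz) and
Mayer-wave (0.1 Hz) oscillations on top of the slow task-driven trend.
`lowpassFilter()` applies a low-pass with default cutoff 0.09 Hz. The filter
family and order are design choices (unconstrained by the task definition):
a 4th-order Butterworth run forward and backward. Zero-phase filtering was
chosen so the hemodynamic peak is not delayed — a causal filter at this
cutoff would lag the response by seconds.

The forward–backward pass is implemented in-package (rather than with
`signal::filtfilt`) because edge handling matters at a 0.018 × Nyquist
cutoff: the state is initialized at its step-response steady state and the
series is extended by even (mirror) reflection over about three filter time
constants (`3 / cutoff` seconds), so a constant series passes through
unchanged (unit DC gain to < 1e-6) and start-up transients decay inside the
discarded padding. The resulting contract, verified in the tests from the
analytic response (`filterGain()`) and by direct RMS measurement: ≥ 40 dB
attenuation at 1.2 Hz, ≤ 2 % amplitude change at 0.01 Hz. Filtering is
applied after the Beer–Lambert conversion and before windowing; motion
artifacts and short-separation regression are out of scope.

## Windowing

`segmentWindows()` divides each 4-min emotion segment into `splitNum` equal,
contiguous, non-overlapping windows that inherit the segment label; rest
periods are discarded. `splitNum` ∈ {1, 2, 4, 8} reproduces the standard
segmentations; `splitNum = 8` gives 30-s windows of 300 samples and
24 windows per trial. `splitTrainTest()` splits stratified by label with
largest-remainder rounding, so 1600 windows at `testFraction = 0.2` give
exactly 1280/320. Stratification is a design choice — with small n it keeps
the class balance of every split. No automatic window-quality criterion is
imposed; `excludeWindows()` lets the analyst drop flagged windows
explicitly.

## The synthetic-data generator

Recordings of this kind are rarely shareable, so `simulateTrial()` /
`simulateDataset()` generate surrogate data with the same structure:

* **Trend**: per channel, a box-car drive (amplitude per emotion class and
  channel, zero in rest) convolved with a saturating exponential
  (`tauS = 15` s). A first-order kernel was chosen over a double-gamma HRF
  because the paradigm produces sustained multi-minute trends, not
  event-related responses.
* **Class structure**: joy drives positive $\Delta HbO_2$ (strongest on the
  right-frontopolar-like channels 7–8), sadness negative, neutral near zero;
  $\Delta Hb = -\tfrac{1}{3}\Delta HbO_2$. The absolute amplitudes
  (0.03–0.075 per channel for joy under the defaults) are free parameters of
  the generator, documented as such — they are plausibility choices, not
  estimates of any study's effect sizes.
* **Noise**: sinusoids with random per-channel phases at 1.2 Hz (cardiac),
  0.4 Hz (respiratory), 0.1 Hz (Mayer) and 0.005 Hz (slow drift), plus white
  noise (sd 0.02). Hb noise is scaled by 1/3.
* **Between-trial variability**: a log-normal amplitude multiplier
  (sdlog 0.2) per trial, which preserves the sign of every effect, mirroring
  group-level consistency of the response direction.

Per-trial seeds derive deterministically from the master seed, so datasets
are bit-reproducible. The generator does **not** emulate motion artifacts,
superficial-layer contamination, heteroscedastic sensor noise or
participant-specific channel topographies; a classifier that separates the
simulated classes demonstrates that the pipeline is correct and trainable,
not that comparable accuracy would be reached on real recordings.

Two reference conditions are fixed for validation: a *strongly separable*
condition (`effectScale = 4`, `noiseScale = 0.25`) under which the default
classifier must reach ≥ 0.90 test accuracy, and a *null* condition
(`effectScale = 0`) under which classifiers must stay within the binomial
95 % band around chance (1/3).

The null condition is evaluated on **held-out trials** (`splitByTrial()`),
not with the window-level split. Windows of one trial share phase-coherent
slow noise, and the simulated noise sinusoids are commensurate with the 30-s
window offset, so same-phase windows in other segments of the same trial are
near-duplicates; a window-level split therefore lets within-trial context
cross the train/test boundary even when no class effect exists (empirically
this context is label-*anti*-correlated here and drags accuracy far below
chance). Trial-disjoint evaluation — the standard subject/recording-wise
protocol against leakage in physiological ML — tests the intended property:
a classifier trained on null data is at chance on data it has genuinely
never seen. The window-level `splitTrainTest()` remains the default pipeline
split for the classification task itself.

## The CNN-Transformer classifier

`buildCnnTransformer()` implements the hybrid network. For a 300 × 16
window:

| stage | output |
|---|---|
| conv1 (32 filters, kernel 8, valid, stride 1) + BN + ReLU + maxpool 3 | (97, 32) |
| conv2 (32 filters, kernel 10) + BN + ReLU + maxpool 3 | (29, 32) |
| position-wise dense embedding (32) | (29, 32) |
| Transformer block (2 heads, $d_k$ = 16, FFN 32; residual + layer norm around both sublayers) | (29, 32) |
| flatten | 928 |
| dropout (0.3) → dense 500 (ReLU) → dense 3 (softmax) | 3 |

Attention is standard scaled dot-product,
$\mathrm{softmax}(QK^\top/\sqrt{d_k})V$, with $Q,K,V$ linear projections of
the input sequence; heads are contiguous column slices, concatenated and
mixed by $W_o$. The feed-forward sublayer is
$\mathrm{ReLU}(ZW_1 + b_1)W_2 + b_2$. No positional encoding is added: the
convolutional front-end already encodes locality, and adding one would
change the documented architecture. Conv kernel sizes (8, 10), pool width 3
and valid padding are the unique small-kernel choice that produces the
(300, 16) → (29, 32) trace above (300 → 293 → 97 → 88 → 29).

Training (`trainModel()`) is plain SGD on categorical cross-entropy,
learning rate 0.005, batch size 32, default 500 epochs (configurable; the
validation suite uses 100 on the strongly separable condition, where
convergence takes only a few epochs). Weights are Glorot-uniform; batch-norm
uses biased batch variance, $\epsilon$ = 1e-3 and running-statistic momentum
0.9 (inference uses the running statistics); dropout is inverted (scaled at
train time); the dense-500 layer uses ReLU. Training is bit-reproducible
given a seed.

No deep-learning framework is involved: the package carries a small
reverse-mode automatic-differentiation engine (`R/autodiff.R`) operating on
matrices, with conv/pool/batch-norm/layer-norm/attention primitives whose
analytic gradients are verified against central finite differences in the
test-suite. Batched sequences are stored sample-major as
`(batch · length) × features` matrices so the heavy operations are single
BLAS calls; the gradient of the first convolution with respect to its input
is skipped (it is never needed).

## Reference classifiers and model comparison

`fitBaseline()` exposes eight reference classifiers behind one interface:
decision tree (`rpart`), random forest (`randomForest`, 500 trees), SVM
(`e1071`, RBF defaults), k-NN (`class`, k = 5), XGBoost (`xgboost`,
`multi:softprob`, 50 rounds), and three neural models (plain CNN, LSTM with
32 hidden units, Transformer-only) built on the same autodiff engine.
Classical models see flattened window vectors; neural models keep the
sequence. Hyperparameters not pinned by the task use the backing library's
defaults and are recorded in the fitted objects; every fit is seeded.

`compareAll()` repeats (fresh stratified split → fit → test) `nRuns` times
and feeds the run × classifier accuracy table to `friedmanTest()`: mid-ranks
within each run, the tie-corrected Friedman $\chi^2$ (matching
`stats::friedman.test`, which serves as the cross-check in the tests, not as
the implementation), $p$ from the $\chi^2_{k-1}$ distribution, Kendall's
$W = \chi^2/(n(k-1))$ and Cohen's $f = \sqrt{W/(1-W)}$. Defining a "run" as
an independent seed/resplit repetition is an interpretation — repeated
accuracy measurements could equally come from folds or participants — and
$f$ from $W$ is one of several conventions; both are documented choices
tested against their own definitions. Under an i.i.d. null the test holds
its nominal 5 % type-I rate (verified over 2000 replicates at n = 18,
k = 9 in the acceptance tests).

## Numerical and scale choices

* Degenerate inputs: an all-tied Friedman row is mid-ranked, identical
  columns give statistic 0 (the 0/0 guard returns 0); a singular extinction
  matrix, a non-divisor `splitNum`, an empty class stratum, and
  windows/architecture shape mismatches raise informative errors.
* Ties in predicted probabilities resolve to the first class
  (deterministic).
* Module tests run on a shortened block design (6 s pre-rest,
  12 s clips, 6 s rests) and small windows so the whole suite is fast; the
  acceptance tests use the full 69-trial, 960-s, `splitNum = 8`
  configuration with 100 training epochs. These problem sizes are the
  package's chosen validation scales.
* `pipelineConfig()` + `runPipeline()` chain the stages reproducibly; the
  master seed fans out deterministically, every run writes a manifest with
  the config hash, and a CLI wrapper lives in `inst/scripts/fnirs-pipeline.R`.

## Known limitations

* The simulator's stationary sinusoidal noise is friendlier than real
  physiological noise (no frequency drift, no motion spikes); accuracy on
  simulated data says nothing quantitative about accuracy on recordings.
* The LSTM and Transformer-only baselines process full-length sequences in
  R and are therefore slow at the 300-step scale; they are practical at the
  reduced test scales and included for interface completeness.
* SNIRF ingestion and cortical activation mapping are not implemented; the
  per-channel group mean (`channelAverageWaveforms()`) is the only
  topographic summary.
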