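---
title: "Models and methods in affectkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in affectkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affectkit)
```

affectkit implements a dual framework for affect recognition from wearable
physiological signals: a 1D convolutional classifier for stress recognition
that transfers, by fine-tuning, to activity recognition; and a Temporal
Conformer — a convolution-plus-self-attention regressor — that predicts
continuous valence, arousal and dominance (VAD) from single-lead ECG. This
vignette documents the models, the tunable parameters, the synthetic data the
package trains on, and the numerical conventions precisely enough that every
number the test suite checks can be traced to a definition here.

## The stress-classification path

A feature row (by default 62 heart-rate-variability-style features) is treated
as a length-62, one-channel sequence. The classifier is:

Conv1D(64 filters, kernel 3, ReLU, L2) → BatchNorm → MaxPool(2) →
Dropout(0.4) → Conv1D(128, kernel 3, ReLU, L2) → BatchNorm → MaxPool(2) →
Dropout(0.4) → GlobalAveragePooling → Dense(64, ReLU) → Dropout(0.4) →
Dense(k, softmax).

Defaults that the architecture description leaves open and that we fixed:
same-padding convolutions, pool size 2, L2 coefficient 1e-4 (penalty
`l2 * sum(W^2)` on conv/dense kernels). Training uses Adam (learning rate
1e-3 for pretraining, 1e-4 for fine-tuning), batch size 128, at most 50
epochs, sparse cross-entropy or focal loss (`gamma = 2`), balanced class
weights `w_c = n / (k n_c)` multiplying each sample's loss, early stopping
(patience 8, best-validation weights restored) and reduce-on-plateau
(factor 0.5, patience 4, floor 1e-6). Patience values are our choices; the
training description only states that both callbacks exist. Validation loss
is computed unweighted.

The engine behind these models is written in R (im2col convolutions, batch
normalization, hand-derived backpropagation, Adam); there is no external
deep-learning runtime. Every layer's gradient is checked against central
finite differences in the test suite, and training is exactly reproducible
under a fixed seed: the only random sources are R's RNG (initialization,
shuffling, dropout).

### Transfer learning

Pretrained weights are saved in a single-file checkpoint (JSON architecture
descriptor + little-endian float64 arrays; bitwise round-trip). Fine-tuning
builds a fresh network for the new class count, loads every backbone weight
by name, reinitializes only the output head, and trains at learning rate
1e-4 with balanced class weights. All backbone layers stay trainable by
default (`freeze_conv = TRUE` freezes the two conv blocks). Because the
first convolution's kernel depends on the channel count, multichannel
activity windows are flattened to a single channel (channel blocks
concatenated along time) so the backbone applies unchanged; this convention
is ours and is what `flatten_windows()` implements.

## The VAD regression path

ECG trials are z-scored per signal (each trace by its own mean and
population SD), segmented into 5-s windows (640 samples at 128 Hz) with 50%
overlap (step 320), and each window inherits its parent trial's labels,
normalized from the 1–5 self-assessment scale to [0, 1] by `(x - 1) / 4`.

### The 33-feature extractor

Each 640-sample segment is reduced to 33 features, in fixed order:

* 11 statistical: mean, median, SD, IQR, skewness, excess kurtosis, min,
  max, range, RMS, Shannon entropy. Conventions: population moments
  (skewness `m3 / m2^1.5`, kurtosis `m4 / m2^2 - 3`), linear-interpolation
  percentiles for the IQR, and skewness = kurtosis = 0 for a constant
  segment. The source list names ten features but asserts eleven; we define
  the eleventh as range = max − min, the natural completion of its
  "range-based metrics" phrasing — a reconstruction, not an authorial value.
  Entropy uses a 16-bin equal-width histogram over the segment's own
  [min, max] (one occupied bin for a constant segment), `H = -sum p log2 p`
  with `0 log 0 = 0`, hence `H ≤ 4` bits.
* 12 wavelet: Daubechies-4 decomposition to level 3, sub-bands A3, D3, D2,
  D1 in that order, each contributing mean, SD and RMS energy of its
  coefficients. Convention (fixed here because the source does not state
  one): symmetric repeat-edge extension by L−1 samples, full convolution
  with the standard db4 analysis pair, downsampling that keeps every second
  sample starting at index L+1 (1-based), giving `floor((n + 7) / 2)`
  coefficients per level — the common filter-bank convention.
* 10 STFT: 64-sample frames, periodic Hann window, 50% overlap, incomplete
  tail dropped, one-sided spectrum; feature k is the mean over frames of the
  squared magnitude in frequency bin k, k = 0..9 ("mean power"; a flag
  switches to plain magnitude).

### The Temporal Conformer

The 33-vector enters as a length-33 one-channel sequence:
Conv1D(32, ReLU) → Dropout → Conv1D(64, ReLU) → Dropout → position-wise
linear projection to d = 64 → two post-norm transformer encoder blocks
(4 heads, feed-forward width 128, residual connections, layer norm, dropout
0.1, attention probabilities retained for inspection) → final layer norm →
dropout → flatten → Dense(3). Depth, heads and widths are configurable; the
defaults are ours (the source says only "multiple layers"). Training
minimizes Smooth-L1 (Huber) loss with `beta = 1` (`e^2/2` below 1, `|e| - 0.5`
above) under the same Adam/plateau/early-stopping regime, up to 100 epochs.

## Synthetic data: what it emulates and what it does not

The package never requires the original recordings; three seeded generators
stand in for them.

**Stress table** (`gen_stress_table`): class-conditional Gaussian features.
Class c shifts its mean by `effect_size` SD units on a class-specific random
half of the features. Defaults emulate the published shapes: 62 features,
proportions 0.5281 / 0.1700 / 0.3019 (135,650 rows reproduce the printed
94,955 / 20,347 / 20,348 split and the 10,746 / 3,460 / 6,142 test
supports). Counts use half-away-from-zero rounding with the remainder to the
largest class.

**ECG** (`gen_ecg`): Gaussian R-pulses (half-width 0.02 s) at RR intervals
drawn from Normal(60/heart rate, rr_sd) truncated positive, the first peak
fixed at 0.5 s, plus a 0.2 Hz baseline-wander sinusoid (amplitude 0.1) and
white noise. This is a stylized pulse train, not a PQRST morphology model:
passing tests show the pipeline recovers controllable rate/noise structure,
not that it handles real ECG artifacts.

**DREAMER-like trials** (`gen_dreamer_like`): 23 subjects × 18 trials by
default; per trial the latents are drawn uniformly — heart rate 45–130 bpm,
RR SD 0.005–0.30 s, noise SD 0.02–0.30 — and labels come from an affine,
clipped latent→VAD map: arousal rises with heart rate; valence falls with
noise; dominance falls with both heart rate (weight 0.65) and RR variability
(weight 0.35). We first tried a fully diagonal map (dominance ← RR
variability alone) and discarded it after an out-of-package oracle (a random
forest regressing the latents on the 33 features) showed beat-timing
variability is nearly invisible to aggregate segment features (R² ≈ 0.26
even with the other latents held fixed): every feature is a moment, band
energy, or frame-averaged band power whose 0.5-s frames contain about one
beat, so beat-timing irregularity largely cancels out. Tying dominance
partly to heart rate — interpretable as loss of perceived control at high
activation — keeps the named RR dependence while making all three label
dimensions genuinely learnable, which is what the parameter-recovery tests
require of the generator. With `label_jitter_sd = 0` labels are an exact
function of the latents.

**Activity windows** (`gen_activity_windows`): k = 4 classes with distinct
dominant oscillation frequencies (4/8/16/32 cycles per window) and
amplitudes, scaled by `effect_size`, over unit white noise; default
proportions 12137 : 969 : 699 : 131 (≈ 93:1 extremes).

## Explainability

* **Grad-CAM (1D)**: gradients of the target-class logit at the final conv
  layer; per-filter weights are time-averaged gradients; the map is
  `ReLU(sum_k w_k A_k)`, linearly upsampled to the input length and min-max
  normalized. An all-zero (flat) map is returned as zeros by design, not an
  error — a flat response is a legitimate finding about a model.
* **Multichannel Grad-CAM**: the time profile above, distributed over input
  channels in proportion to each channel's mean absolute input gradient,
  normalized jointly so the global max is 1 (per-channel normalization via
  flag). The cross-channel aggregation is ambiguous in the source; this
  definition reduces exactly to the single-channel map when C = 1.
* **Integrated Gradients**: midpoint-rule path integral from a zero baseline
  in the model's normalized input space; `IG = (x - b) * mean grad` over the
  grid; the completeness gap `sum(IG) - (F(x) - F(b))` is reported and
  shrinks as the grid refines; for a linear model IG is exactly `w_i x_i`.
* **Attention**: the conformer's per-layer, per-head attention
  probabilities, rows summing to 1.
* **t-SNE**: exact (non-tree) t-SNE with per-point bisection calibration of
  the Gaussian bandwidths to perplexity 30, early exaggeration 4 for the
  first quarter of 400 iterations, momentum 0.5→0.8, deterministic under the
  seed. Intended for the pooled (GAP) embeddings via
  `nn_activation(model, x, "gap")`.

## Diagnostics

Normalized VAD triples map to six states by rules evaluated in precedence
order Happy/Excited → Stressed → Relaxed → Fatigued → Passive → Neutral
(first match wins); min/max thresholds are inclusive, the Passive rule's
"below" comparisons strict, and dominance is consulted only by the Passive
rule. The numeric thresholds (0.6/0.7 happy, 0.6/0.4 stressed, 0.3/0.7
relaxed, 0.3/0.3 fatigued, 0.4/0.5 passive) are a reconstruction fitted to
reproduce the ten published worked rows — the source gives the rule
structure but no numbers — and are fully configurable. Fatigue Index is
`1 - arousal`; Motion Quality is `valence * dominance`; display rounding is
half away from zero to two decimals. Recomputing the published table from
its own printed two-decimal inputs reproduces all ten states and all ten
fatigue values exactly and eight of ten motion values; the other two differ
by one unit in the last place because that table's products were evidently
computed from unrounded predictions. Profiling uses k-means (k = 4,
k-means++ seeding, ten restarts, Lloyd iterations, fixed seed). The
published cluster ids are not reproducible — they depend on the authors'
full predicted dataset — and are out of scope.

## Evaluation conventions

Classification: precision/recall/F1/support per class from the confusion
matrix, macro and support-weighted averages, accuracy = trace/n (the
weighted recall equals accuracy identically). An empty predicted class
yields precision 0 with a warning. Regression: MAE and RMSE pooled over all
entries; R² per dimension then averaged (the pooled variant is exposed too —
the headline R² in the source is not labelled either way, and we chose the
per-dimension average); rounded accuracy maps both arrays back to the 1–5
scale (`x*4 + 1`), rounds half away from zero and scores per-dimension and
all-dimensions matches, the latter never exceeding any of the former. The
rounding scale is a parameter in spirit: the source does not state one, and
the 1–5 interpretation is the documented default.

## Problem sizes used by the tests and the acceptance script

Chosen as the smallest sizes at which each property is comfortably
demonstrated: CNN recovery trains on a 3,000-row, effect-size-3 table
(held-out accuracy ≥ 0.90, 12 epochs); transfer recovery pretrains on
1,200 rows and fine-tunes for 25 epochs on 1,394 activity windows of 64
samples × 3 channels at effect size 3 (macro recall ≥ 0.75 under focal
loss with balanced class weights — the package's default imbalance
treatment for fine-tuning — like its real-data counterpart, the weighted model trades
majority-class precision for minority-class recall); conformer recovery
uses 16 subjects × 12 trials of 15.25 s (960 five-second segments; batch
64, up to 140 epochs; mean per-dimension held-out R² ≥ 0.70 under zero
label jitter). The split-size identity is checked at the full 135,650-row
scale.

## Known limitations

* The generators are statistical stand-ins; none of the reported recoveries
  implies performance on real wearable recordings, and the published
  headline accuracies on the original datasets are explicitly not
  reproduced here.
* Dominance is the weakest label dimension by construction (see above);
  its recovery rests mostly on the heart-rate component of the map.
* The EDF writer/reader covers plain EDF (one data record, 16-bit samples,
  per-channel rates); EDF+ annotations and BDF are unsupported, and the
  start-offset field is not persisted.
* The MAT reader covers the uncompressed little-endian v5 subset the
  package writes (double arrays, cells, structs); compressed MAT files are
  rejected with a clear error.
* Exact t-SNE is quadratic in n; it is meant for embedding a few hundred
  pooled vectors, not full datasets.
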