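---
title: "The convolutional sparse transformer: model, design choices, and what the synthetic benchmark shows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The convolutional sparse transformer: model, design choices, and what the synthetic benchmark shows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csteeg)
```

## The model and its assumptions

`csteeg` classifies fixed-length EEG epochs `X ∈ R^{T×C}` (time frames ×
channels, microvolts) end to end. The architecture assumes that (i) the
discriminative signal is carried jointly by *which electrodes* are active
and *how their waveforms evolve*, and (ii) the raw waveform — only
filtered and segmented — is a sufficient input, with no hand-crafted
spectral features.

**Spatial channel attention.** Global average and max pooling over time
produce two `C`-vectors of channel statistics; a shared two-layer linear
MLP (`W0 : hidden×C`, `W1 : C×hidden`) maps both, and their sum passes
through a sigmoid:

$$M_c(X) = \sigma(W_1 W_0 X^c_{avg} + W_1 W_0 X^c_{max}) \in (0,1)^C.$$

The gate multiplies `X` channel-wise before any temporal mixing. Note the
MLP is *linear* inside the sigmoid (no hidden ReLU, unlike the CBAM
ancestor of this module); we implement the formula exactly as written.
Because the statistics are raw-amplitude sums, extreme inputs can
saturate the sigmoid in floating point; the gate is therefore clamped to
`[1e-12, 1 - 1e-12]` so it remains an open-interval multiplier with a
live gradient.

**Sparse self-attention.** Dense attention
`softmax(QK^T/√d)V` is the baseline (`dense_attention()`). The sparse
variant selects `u = max(1, ⌈c·ln L⌉)` *active* query positions at
equidistant intervals, `idx_k = ⌊kL/u⌋` (exposed 1-based in R as
`select_active_queries()`), attends them over the full key set, and
assigns every lazy position the column mean of `V`. Two properties
matter:

* the selection is content-free (a function of `L` and `c` only) and
  shared across heads;
* the lazy fill is an exact assignment — tests require bit-equality with
  `colMeans(V)`, not a tolerance.

The query–key pair count per layer is `u·L_K`, verified by an
instrumented counter rather than asymptotics; at `L = 1024`, `u = 7` and
the sparse/dense ratio is `7/1024`. The sampling factor `c`
(`query_factor`, default 1) generalizes the `ln L` budget.

**Distilling layers.** `X' = MaxPool(ELU(Conv1d(X)))` with conv kernel 3
(same padding) and pool kernel 3 / stride 2 / padding 1, so
`L' = ⌊(L−1)/2⌋+1` — a halving for even `L`. With the reference
`T = 2048`, five layers give 1024 → 512 → 256 → 128 → 64.

**Assembly.** Channel attention is applied once to the raw `[T×C]` input
(the gate multiplies the *EEG signal*, not embeddings). A kernel-3
convolution embeds `C` channels to `d_model` features per frame, plus
non-learned sinusoidal position codes (both toggleable). Encoder layers
follow the vanilla-transformer skeleton wherever the design is not
overridden: post-norm residual sublayers, a position-wise feed-forward
with width `d_ff`, dropout after each sublayer output. Sparse layers come
first, then full layers; a distilling layer follows attention layer `i`
for `i ≤ n_conv_layers`, so the reference 6-attention/5-conv
configuration distills after each of the first five layers and not after
the last. The predictor mean-pools the remaining positions and applies
one affine map; softmax is applied only in the loss and metrics.

## Parameters that matter

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `n_sparse_layers`, `n_full_layers` | 3, 3 | reference layer counts |
| `n_heads` | 8 | must divide `d_model` |
| `d_model`, `d_ff` | 128, 512 | stream and feed-forward widths |
| `n_conv_layers` = `n_pool_layers` | 5 | distilling stack depth |
| `query_factor` `c` | 1 | active-query budget `⌈c·ln L⌉` |
| `channel_reduction` `r` | `max(1, ⌊C/2⌋)` | gate MLP hidden width `⌊C/r⌋`; the classic `r = 16` is impossible at `C = 4` (pharmaco montages), so the default scales with `C` |
| `dropout` | 0.1 | after attention and feed-forward outputs |
| pool kernel/stride/pad | 3/2/1 | halves length; `T = 2048` survives 5 layers |
| training presets | 50 ep/64 bs/1e-3 (binary tasks); 300/32/1e-4 (11-class pharmaco) | more epochs, smaller batches, lower rate for the harder multi-class task |

Epoch lengths must satisfy `min_input_length(cfg)`: the temporal length
must stay ≥ 2 entering every distilling layer. Too-short inputs raise an
error naming the minimum rather than producing degenerate pools.

Weight initialization is uniform with fan-in scaling under
`ModelConfig$seed`; together with seeded shuffling and dropout this makes
`train_model()` bitwise reproducible on one device. The optimizer is Adam
on categorical cross-entropy — the field default, stated explicitly in
`train_config()` because nothing in the architecture prescribes it.

## Preprocessing

Filtering is zero-phase order-4 Butterworth. The wideband setting
(0.1–70 Hz) keeps delta through gamma while removing drift and
high-frequency noise; the neonatal preset uses a 0.5 Hz high-pass. Two
numerical choices:

* The band-pass is realized as an order-4 high-pass *cascaded* with an
  order-4 low-pass. A direct transfer-function band-pass with a 0.1 Hz
  edge at EEG rates is numerically fragile (poles crowd `z = 1`); the
  cascade is stable and has the clean closed form
  `|H|² = HP₄(f)·LP₄(f)` exposed by `filter_response()`.
* Each pass is endpoint-handled: odd-reflection padding plus a
  DC-matched start (the constant component is removed before filtering
  and restored through the filter's DC gain — equivalent to steady-state
  initial conditions for the constant part). Without this, a 0.1 Hz
  high-pass leaves seconds-long transients and a constant input does not
  map to zero. The realized response is validated against the analytic
  form via impulse-response FFT in the tests.

Segmentation cuts non-overlapping consecutive windows of
`window_s · fs` samples and drops a trailing partial window — matching
the "t·f·ch data points" accounting with no overlap. Seizure-type labels
come from an annotation-overlap rule: a window is positive when annotated
events cover at least 50% of it (threshold configurable); the rule had to
be made explicit because epoch labeling from interval annotations is
otherwise underdetermined.

Holdout splits are stratified by class with largest-remainder rounding
(so 5+5 epochs at 0.7 give per-class train counts 4 and 3, ties to the
earlier class), and k-fold CV deals shuffled classes round-robin. Both
epoch-level and grouped (subject-level) modes exist: epoch-level mirrors
the common baseline protocol, while the grouped mode is the leakage-safe
option when multiple epochs share a recording.

## The synthetic generator: what it emulates, and what it does not

`make_dataset()` draws per-channel `1/f^β` Gaussian backgrounds
(synthesized in the frequency domain — shaped amplitude spectrum, random
phases, inverse transform — for exact spectral control, standardized to
unit variance) and adds class signatures: a sinusoid with random
frequency inside a class band and random phase, confined to target
channels, optionally with Hann-windowed rhythmic bursts (Poisson onsets)
as a crude stand-in for ictal activity. This reproduces the two features
the architecture is built to exploit — band-limited oscillatory content
and channel topography — and nothing else.

It does **not** model volume conduction, inter-channel correlation of the
background, artifacts (EMG, eye blinks, electrode pops), non-stationary
drift, or realistic seizure morphology. Passing the desk-scale benchmark
therefore shows that the implementation *can learn spectral-spatial
signatures end to end*; it says nothing quantitative about clinical
datasets, whose headline numbers require the corresponding recordings.

The standard benchmark (`desk_task_spec()`) is: 4 channels at 128 Hz,
4 s windows (`T = 512`), 200 epochs per class, amplitude gain 3, seed 7;
class A carries 9–11 Hz on channels 1–2, class B 4–6 Hz on channels 3–4.
The reduced model for this task (`preset_config("desk")`) uses 2 sparse +
1 full attention layers, 3 distilling layers, `d_model = 64`; we chose
4 heads and `d_ff = 128` to keep proportions, and dropout 0 since the
task is strongly separable and the model small. The desk training preset
is 3 epochs, batch 32, rate 1e-3 — the loss reaches ~0.1 within three
passes and held-out accuracy saturates within one, so longer schedules
only add CPU time. Five-fold CV on this task is the package's learnability
check (mean accuracy ≥ 0.9 asserted in the test suite), and the four-row
ablation grid on the same task checks the *direction* of the ablation
effects (the full model is not beaten by any single ablation by more than
0.05) — magnitudes on clinical data are out of desk scope.

## Numerical choices and degenerate inputs

* Softmax rows are max-shifted before exponentiation; attention rows sum
  to 1 within 1e-6 by construction.
* Max-pool ties break to the earliest tap; pool padding is `-Inf` so
  padded positions never win.
* ELU uses `α = 1`; its forward is computed branch-free as
  `pmax(x,0) + expm1(pmin(x,0))`.
* Precision/recall with an empty prediction class are defined as 0
  (logged convention, keeps macro averages finite); single-class truth
  makes ROC-AUC `NA` with a warning rather than a crash.
* ROC-AUC is the trapezoid over one operating point per distinct
  threshold, which equals the Mann–Whitney rank statistic with midranks —
  asserted as an oracle identity in the tests.
* Fold aggregates are mean ± sd with the `n−1` denominator.
* The EDF writer scales each channel to the full 16-bit range with
  integer physical bounds, so round-trips are exact to one quantization
  step; the reader rejects mixed per-signal rates and truncated files.

## Open design points, resolved

* "`ln L` terms at equidistant intervals" fixes neither the rounding nor
  the offset: we use `u = max(1, ⌈c·ln L⌉)` and `idx_k = ⌊kL/u⌋`,
  deterministic, covering the sequence start, and consistent with the
  `O(L_K ln L_Q)` cost.
* The lazy-fill mean is the full column mean of `V` (a running mean is
  the other reading); the choice is exact and testable.
* Whether sparse layers precede full layers is not forced by anything:
  sparse-first is the default and the plan is a pure function of the
  configuration (`layer_plan()`).
* Position encoding is on by default but toggleable; nothing in the
  architecture requires it and its effect on the benchmark is not
  measured here.
* Multiclass precision/recall/F1 are macro one-vs-rest with per-class
  values retained; binary tasks report the positive class. Macro is the
  conservative unweighted choice where the averaging convention is not
  specified.
* The pharmaco-style sampling rate is a configuration value everywhere;
  no constant in the package assumes it.

## Problem sizes used by the test suite

Structural and gradient tests run on a miniature stack (`T = 16`,
`d_model = 8`); analytic gradients are checked against central finite
differences across every parameter tensor. The learnability and ablation
checks use the full desk benchmark (400 epochs of `T = 512`); oracle
equivalence uses 200 random instances with `L ≤ 32`, `d ≤ 8`. These sizes
were chosen so the whole suite, including the trained benchmarks,
completes in about ten minutes on a single CPU.

## Known limitations

* Pure-R training: throughput is BLAS-bound and fine at desk scale, but
  full-size clinical runs (e.g. `T = 2048`, `d_model = 128`, tens of
  thousands of epochs) call for hours of CPU, not minutes.
* No GPU, mixed precision, early stopping or schedulers; no decoder-side
  generative components.
* The CLI covers simulate/prepare/train/eval/ablate/sweep; it does not
  attempt montage handling, re-referencing, resampling or artifact
  rejection — inputs are assumed filtered-and-segmented raw EEG by
  design.
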