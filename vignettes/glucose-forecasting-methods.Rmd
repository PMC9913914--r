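---
title: "Methods: physiological features and multi-step CGM forecasting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: physiological features and multi-step CGM forecasting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucast)
```

## The forecasting problem

A continuous glucose monitor (CGM) reports interstitial glucose in
mg/dL every 5 minutes. For a person with type 1 diabetes, knowing where
glucose will be 30 or 60 minutes from now is what makes timely insulin
dosing or carbohydrate intake possible. glucast frames this as
multi-step sequence-to-sequence regression: the last 6 CGM samples
(half an hour) predict the next 6 (30-min horizon) or 12 (60-min
horizon) samples.

Two of the strongest known drivers of near-future glucose — meals and
bolus insulin — arrive as *events*: a timestamp with grams of
carbohydrate or insulin units. Fed to a sequence model as raw spikes
(zero everywhere, a single value at the event), they carry almost no
usable signal. The core idea implemented here is to transform each
event log into a *continuous* physiological feature sampled on the CGM
grid, so the model can see carbohydrate absorption building up and
insulin action tailing off.

## Operative carbohydrates

A meal of $C_{meal}$ grams is mapped onto a piecewise absorption curve
indexed by 5-min samples $k$ since the meal:

* samples $0 \le k < 3$: zero (a meal takes roughly 15 min to start
  moving glucose);
* $3 \le k < 12$: linear rise of $\alpha_{inc} \cdot C_{meal}$ per
  sample with $\alpha_{inc} = 0.111$ (11.1 %/sample), so the curve
  saturates at the full meal size by the 12th sample (60 min);
* $12 \le k < 48$: linear decay of $\alpha_{dec} \cdot C_{meal}$ per
  sample with $\alpha_{dec} = 0.028$ (2.8 %/sample), reaching zero
  3 h after the peak;
* the value is clamped to $[0, C_{meal}]$, which absorbs the
  sub-percent round-off in the printed rates ($9 \times 0.111$ and
  $36 \times 0.028$ are not exactly 1).

The published description of the middle branch is typographically
ambiguous; the reconstruction above is the unique piecewise-linear
curve consistent with all four prose constraints (zero first three
samples, 11.1 %/sample rise, maximum at the 12th sample, 2.8 %/sample
decay to zero). Whether "reaches zero after 3 h" counts from the meal
or from the peak is equally ambiguous in prose; the branch bound (48
samples) settles it as *from the peak*, which is what
`carb_curve_single()` implements and what the acceptance checks assert.

Overlapping meals combine by superposition. Linearity in $C_{meal}$ is
the only combination rule consistent with the per-event description,
and it makes the transform testable against a brute-force sum oracle.
Events are snapped to their nearest grid slot so $k$ stays integral.

```{r carb-curve}
cc <- carb_curve_single(0:48, c_meal = 100)
plot(0:48 * 5, cc, type = "l", xlab = "minutes since meal",
     ylab = "operative carbs (g)")
```

## Active insulin (insulin on board)

Rapid-acting bolus insulin is modeled with the standard exponential
insulin-on-board (IOB) curve. Given the activity peak time $t_p$
(75 min for the adult preset, 65 min for the child preset) and the
duration of insulin action $t_d$ (default 360 min), the shape
constants are

$$\tau = t_p \frac{1 - t_p/t_d}{1 - 2 t_p/t_d}, \qquad
  a = \frac{2\tau}{t_d}, \qquad
  S = \frac{1}{1 - a + (1 + a) e^{-t_d/\tau}},$$

and the surviving fraction $t$ minutes after a bolus is

$$\mathrm{IOB}(t) = 1 - S (1-a) \left[
  \left(\frac{t^2}{\tau t_d (1-a)} - \frac{t}{\tau} - 1\right)
  e^{-t/\tau} + 1 \right].$$

The formulation guarantees $\mathrm{IOB}(0) = 1$ and
$\mathrm{IOB}(t_d) = 0$ exactly, monotone decay in between, and an
activity curve $-\,d\,\mathrm{IOB}/dt$ peaking at $t_p$. The constraint
$t_p < t_d/2$ keeps $\tau$ finite; `insulin_shape_params()` rejects
anything else. The active-insulin feature at a grid slot is
$\sum_i \mathrm{dose}_i \cdot \mathrm{IOB}(t - t_i)$ over boluses, so a
4 U bolus contributes 4.0 at injection time and nothing after 6 h.

## Preprocessing and provenance

Sensor changes break the 5-min cadence, so the raw glucose event list
is first regularized: a grid is anchored at the first observation,
observations map to their nearest slot (collisions are an error, not a
merge), and empty slots are flagged `inserted_missing`. Gaps of exactly
one sample are forward-filled from the previous value; longer gaps are
linearly interpolated between their brackets (among common
interpolants, the linear one tracks CGM behaviour best at this
cadence). A centered median filter (default window 5 samples = 25 min,
wide enough to remove 1–2-sample sensor spikes without flattening a
meal rise; the window length is not dictated by the source material and
is configurable) smooths the **training** series only.

Every sample carries a provenance flag (`observed`,
`inserted_missing`, `imputed`, `smoothed`). Test data are imputed too —
windows must be contiguous — but imputed test targets are excluded
from every error computation via the provenance-driven mask in
`rmse_masked()`. Published sample counts for specific patients are
never hard-coded; all counts are recomputed from whatever data are
loaded.

## Dataset geometry

* **Windows.** `make_windows()` tiles a series into input windows of 6
  samples with stride 6 (non-overlapping), each paired with the next
  `horizon_len` targets. This reproduces the reference arithmetic:
  9,288 training timestamps → 1,548 examples, 2,322 test timestamps →
  387 examples. The final windows of a segment have targets that run
  past the end; by default these targets are kept as masked `NA`s (the
  trainer drops them, the evaluator masks them), while
  `drop_partial = TRUE` discards incomplete windows entirely. The two
  conventions disagree only at the segment boundary (by one window),
  and both are exposed because the reference counts require the first
  while strict modeling hygiene prefers the second. Stride is
  configurable for overlapping-window experiments.
* **Splits.** `rolling_origin_splits()` makes $k$ time-ordered splits
  with constant validation size $\lfloor n/(k+1) \rfloor$; training set
  $i$ has $n - (k - i + 1)\lfloor n/(k+1) \rfloor$ samples, so each
  training set extends the previous one and validation immediately
  follows it. For $n = 11{,}611$ and $k = 5$: validation 1,935 and
  training 1,936 … 9,676. Windows are built per block, so no window
  bridges a training/validation boundary.
* **Standardization.** Per-channel mean/sd are fit on training rows
  only and applied everywhere; predictions are inverse-transformed to
  mg/dL. Constant channels are rejected rather than silently scaled.

## The forecaster

The reference model is a stacked recurrent network: LSTM(128,
sequence-emitting) → leaky ReLU (slope 0.01) → dropout (0.2) →
LSTM(64) → dropout → dense head of 6 or 12 linear units. A single-layer
"vanilla" variant and a true bidirectional option exist behind flags;
the bidirectional option is off by default because looking forward
inside the input window is nonstandard for forecasting. Dropout rate,
leaky-ReLU slope and the epoch budget are not pinned down by the source
material; the defaults (0.2 / 0.01 / 100 epochs with early-stopping
patience 10) are common practice and all configurable.

No deep-learning backend is assumed: the LSTM forward pass, backward
pass (backpropagation through time) and Adam optimizer are implemented
in vectorized base R inside the package. The backward pass is verified
against central finite differences to ~1e-6 relative error in the test
suite, for the stacked, vanilla and bidirectional variants — this
gradient check is the engine's primary correctness oracle. Training
minimizes MSE on standardized targets (squared error is what the RMSE
evaluation implies), records per-epoch losses, restores the best
validation weights, and is bit-reproducible for a fixed seed: the seed
drives weight initialization, batch shuffling and dropout masks, and
all arithmetic is deterministic single-threaded BLAS.

Evaluation is walk-forward: the trained weights are frozen and applied
to consecutive non-overlapping test windows; all horizon positions are
pooled into one masked RMSE (a per-step breakdown is reported as
supplementary output). Whether published scores average several
training runs is unstated in the source; `compare_configurations()`
reports the seed-median across an explicit seed list.

## The synthetic patient

`simulate_patient()` generates the study conditions the pipeline
assumes, so everything is testable without the access-restricted
clinical dataset. The CGM is

$$\text{baseline} + \text{circadian} + \sum_{\text{meals}} g_c C_m
  \kappa_{carb}(t - t_m) - \sum_{\text{boluses}} g_i d_b
  \kappa_{act}(t - t_b) + \text{AR(1)} + \text{spikes},$$

clipped to the 40–400 mg/dL sensor range, where $\kappa_{carb}$ and
$\kappa_{act}$ are the package's own unit-peak carb and
insulin-activity kernels. Defaults: baseline 120 mg/dL, circadian
amplitude 15 mg/dL, AR(1) coefficient 0.95 with innovation sd 3 mg/dL,
3.5 meals/day of 20–90 g in waking hours (07:00–22:00), a bolus 15 min
before each meal at 0.1 U/g, gains of 2.5 mg/dL/g and 35 mg/dL/U, 0.5
sensor gaps/day of 2–24 samples, and 0.5 % spike probability at
40 mg/dL — values chosen once as a realistic adult profile. Because the
generator reuses the physiological kernels, the multivariate feature
configurations are informative *by construction*: a model that sees the
operative-carb channel can anticipate a rise its CGM history cannot.

What the simulator does **not** emulate: insulin–glucose ODE dynamics
(no UVA/Padova-style physiology), exercise/stress effects, sensor
drift, or reporting lag in self-reported meals. Passing tests therefore
demonstrate pipeline correctness and the qualitative value of the
feature transforms under these assumptions — not clinical accuracy on
real patients.

Ground-truth components (circadian, meal effect, insulin effect, AR
noise, spikes) are stored with each simulated record and sum exactly to
the pre-clip CGM, which gives the tests a bookkeeping identity to hold
on to. Gap runs are kept clear of segment boundaries so every gap is
bracketed for imputation.

## Numerical choices and degenerate inputs

* Events are snapped to the nearest grid slot (tolerance half an
  interval); two observations on one slot are an error.
* The IOB fraction and carb curve are clamped to their physical ranges
  to absorb floating-point residue at the branch edges.
* `impute_series()` refuses unbracketed (leading/trailing) gaps rather
  than extrapolating; `align_features()` extends edge values for
  auxiliary channels, where extrapolation is benign.
* Median smoothing shrinks its window symmetrically at the edges.
* Training aborts with a diagnostic if the loss goes non-finite
  (learning-rate / scaling hints) instead of returning NaN weights.
* Zero-variance channels, even window lengths, non-monotone event
  times and overlapping train/test grids are all rejected with
  specific errors; `validate_record()` returns findings instead of
  throwing, for use on untrusted files.

## Problem sizes used in the shipped checks

The test suite and reproduction script run entirely on synthetic data
at sizes chosen to keep the full check fast on one CPU while leaving
every comparison meaningful: 14 simulated days, 5 training seeds and a
16/8-unit stack for the multivariate-vs-univariate comparison;
32/16 units and 150 epochs where a model must demonstrably beat the
persistence baseline; 60 simulated days for the stationary-variance
and gap-rate checks; tiny (≤ 5-unit) networks for the finite-difference
gradient checks. The analytic kinetics and split-arithmetic checks are
exact at any size.

## Known limitations

* The recurrent engine is plain R: fine at these problem sizes, not a
  GPU substitute for week-scale clinical datasets with large layers.
* Basal insulin, heart rate and the other auxiliary channels are
  parsed and alignable but carry no pipeline semantics, mirroring the
  selected feature set (they were found uninformative in the source
  study).
* Single carb-absorption profile: no glycemic-index-specific curves.
* Self-reported meal timestamps are taken at face value.
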