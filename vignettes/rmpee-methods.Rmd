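---
title: "Estimating energy expenditure from respiratory kinematics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating energy expenditure from respiratory kinematics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmpee)
```

## The problem

Indirect calorimetry (IC) measures energy expenditure (EE) breath by breath
from gas exchange, but requires a face mask and a metabolic cart. Respiratory
magnetometer plethysmography (RMP) instead records four thoracoabdominal
distances — anteroposterior rib cage (RC) and abdomen (AB), axial chest wall
(CW) and spine (SP) — at 15 Hz with a wearable device. Because ventilation
drives both the distances and (through oxygen uptake) energy expenditure,
the distance traces carry enough information to estimate EE across rest and
exercise intensities. `rmpee` implements that estimation pipeline end to
end: a temporal convolutional network (TCN) maps 5 s windows of the four raw
distance signals to the window's mean EE (kcal/min), with the IC record as
training target, and the agreement between estimated and reference EE is
quantified exactly as a method-comparison study would (R², RMSE,
Bland–Altman limits of agreement, per-intensity paired tests).

Because the underlying human recordings are not publicly distributable, the
package ships a synthetic cohort generator that reproduces the statistical
structure the analysis depends on. Everything downstream of the generator is
agnostic about where the CSVs came from.

## The synthetic graded-exercise cohort

`simulate_subject()` draws adult (A), post-pubertal (PP) and pubertal (P)
profiles from group-level normal distributions (truncated at ±2.5 SD and at
the group age bounds, so means are preserved); BMI derives from the drawn
mass and height. `simulate_protocol()` builds the session: six minutes
sitting or standing, two minutes of rest, then a continuous ramp at
20 W/min (age ≤ 12) or 30 W/min (age ≥ 13) until the linear VO₂ response
reaches VO₂max, plus a terminal plateau of about 90 s during which VO₂
stays at VO₂max. The plateau is deliberately longer than one minute so that
the final-minute plateau criterion of `check_vo2max()` can be evaluated on
the simulated test itself.

`simulate_gas_exchange()` produces the breath-by-breath record with a
piecewise-linear intensity model:

* VO₂ is `vo2_rest` (default 3.5 mL/min/kg — one MET) during posture and
  rest, then rises at `vo2_per_watt` (default 10.3 mL/min/W, the standard
  cycle-ergometry oxygen cost) times the ramp rate, capped at VO₂max.
* Minute ventilation follows VO₂ through the ventilatory equivalent
  VE/VO₂: flat at 23 up to the first ventilatory threshold (placed at
  `th1_frac` = 0.55 of VO₂max), rising linearly to 30 at the second
  threshold (`th2_frac` = 0.80) and to 38 at VO₂max. VE/VCO₂ stays flat at
  27.5 until the second threshold (isocapnic buffering) and rises to 31 at
  VO₂max. These numbers are ordinary adult ramp-test values; their only
  structural role is that VE/VO₂ breaks upward at the first threshold while
  VE/VCO₂ stays flat, and both rise above the second — which is exactly the
  pattern the respiratory-equivalents threshold method reads. A by-product
  is a respiratory exchange ratio of ≈ 0.84 at rest reaching ≈ 1.09 at the
  second threshold and > 1.1 at exhaustion, so the RER attainment criterion
  behaves realistically.
* EE is derived *exactly* as `EE = VO₂ (L/min) × 4.825`; this identity is
  preserved under the multiplicative measurement noise because the noise is
  applied to VO₂ first and EE computed from the noisy value, mirroring how
  an IC cart derives EE from its own VO₂ measurement.
* Breath durations shrink linearly from 4 s to 2 s with intensity and are
  further shortened whenever tidal volume `VT = VE·duration/60` would
  exceed `vt_fraction_max` (0.55) of an estimated vital capacity
  (0.065 L/kg body mass). The cap is what turns the duration model into a
  realistic breathing-frequency response at high work rates.

`simulate_rmp()` renders the distance traces with a multi-compartment
chest-wall volume model: lung-volume change is a linear combination of the
channel displacements, `VT = Σ gain_c × excursion_c`, with configurable
gains (L/cm) and per-channel volume shares. Each breath is a raised-cosine
excursion around subject-specific baselines — smooth, band-limited and
period-controllable, which keeps the forward model invertible in tests —
sampled on the uniform 15 Hz grid and disturbed by additive gaussian noise
(0.02 cm default). Real breathing waveforms are not raised cosines, real
compartment contributions shift with posture and intensity, and real traces
contain motion artifacts; none of that is emulated, which is the main
reason synthetic recovery results should be read as validating the
*pipeline*, not the device.

Noise magnitudes (3% multiplicative on gas values and durations, 0.02 cm on
distances) are free parameters chosen once as plausible instrument-level
variability; no published distributional information exists for them.

## Windowing and targets

`segment_windows()` cuts the trace into 5 s windows (75 samples) with 80%
overlap (1 s step), anchored at the start of the recording; the count obeys
`floor((T − 5)/step) + 1`. A 5 s window covers at least one breathing cycle
(nominally 2–4 s). `align_targets()` assigns each window the time-weighted
mean of the breath values overlapping it — unbiased under variable breath
durations, unlike an unweighted mean of overlapping breaths. Windows
without breath support are dropped and counted. Channel signals are
z-scored per channel with statistics from the training split only
(`normalize_signals()`); training on raw centimeters is available by
skipping that step (`normalize = FALSE` in `study_config()`).

## Ventilatory thresholds

In the laboratory the two thresholds are placed visually by observers. That
procedure is not implementable, so `detect_thresholds()` substitutes a
reproducible surrogate: the second threshold is the breakpoint of the best
two-segment continuous piecewise-linear fit (exhaustive search over
interior breath times, least squares) to VE/VCO₂ over the ramp; the first
is the same fit applied to VE/VO₂ restricted to times before the second.
Admissibility requires a positive slope increase, a material SSE reduction
over a straight line (5% default), a flat pre-breakpoint VE/VCO₂ slope (at
most 10% of the post-threshold VE/VO₂ slope in magnitude) and the ordering
t₁ < t₂; otherwise the thresholds are reported indeterminate rather than
guessed. The surrogate is validated by recovery against the generator's
ground-truth breakpoints: within ±15 s on noiseless ramps and ±30 s at the
default noise level (the tolerance is a package choice; no inter-observer
agreement figure exists to calibrate against). Windows are then labeled
sitting/standing, rest→VT1, VT1→VT2 or VT2→VO₂max by their midpoints, with
left-closed ranges so a midpoint exactly at a threshold joins the higher
intensity.

## The TCN regressor

The model is a stack of residual blocks of dilated causal convolutions
(kernel 3; dilations 1, 2, 4, 8, 16; 64 filters), the five dilated layers
split 3 + 2 over two blocks, ReLU activations, an identity skip connection
(1×1 convolution in the first block where the channel count changes), and a
dense linear head reading the features of the last time step — one scalar
per window. The causal receptive field is `1 + (k − 1)(2ⁿ − 1)` = 63
samples (4.2 s at 15 Hz), long enough to span a full breathing cycle. The
implementation is pure R on BLAS matrix multiplies: windows are stacked
into a `(75·N) × C` matrix and each convolution tap becomes a time-shifted
GEMM, with the backward pass derived analytically (and checked against
numerical gradients in the test suite).

Training minimizes mean squared error on standardized targets with
minibatch Adam at learning rate 0.001; neither the loss nor the optimizer
of the original analysis is documented, so the field-standard pair is used.
Data are split 55/20/25 into train/validation/test. The default split is at
the window level, which shares near-duplicate overlapping windows between
the splits; that reproduces the original protocol (and its optimistic
bias), while `mode = "subject"` gives leakage-free generalization
estimates. The best-validation-epoch weights are retained.
`cross_validate()` performs k-fold cross-validation (default 5) by
retraining from scratch on each fold complement; it is a separate function
rather than a side effect of `train_tcn()` so that its considerable cost is
explicit. Predictions are denormalized and clipped at zero — EE is
non-negative.

EE (kcal/min) and mass-relative VO₂ (mL/min/kg) are separate single-output
models with identical architecture (`target = "ee"` / `"vo2"`).

## Evaluation

`r_squared()` is the coefficient of determination `1 − SS_res/SS_tot` (not
a squared correlation — the two differ when the fit is biased).
`bland_altman()` reports bias, SD of the differences and
`bias ± 1.96 SD` limits of agreement; a multiplier of 2 reproduces the
±2 SD plotting convention. `per_intensity_comparison()` tests each
intensity level with a paired t-test, after a Kolmogorov–Smirnov normality
check of the differences and a log-transform of both series when normality
fails and the values are positive (falling back, with a warning, to the
untransformed test otherwise); significance tiers are `*`, `**`, `***` at
p < 0.05, 0.01, 0.001. `required_windows()` is the sample-size formula
`⌈z²p(1−p)/m²⌉` (457 windows at z = 1.96, p = 0.05, m = 0.02) and
`bookkeep_windows()` the 120-windows-per-subject bookkeeping.

## Problem sizes and numerical choices

The packaged validation runs use sizes chosen to keep a complete
reproduction on a laptop-class single core comfortable: the synthetic
recovery study simulates 8 subjects (≈ 9,000 windows), trains the
reference architecture for 30 epochs with minibatches of 256, and reaches
its held-out R² target with a wide margin; the shuffled-target leakage
control trains under the identical protocol, because an undertrained
control can retain initialization-induced correlation between its output
and the signal amplitude envelope and thereby overstate leakage. Minibatches of 256 (rather than the
reference 1024) keep the number of Adam updates at this reduced sample
size (~600) commensurate with the original training regime (~1,250 updates
over 80 epochs at batch 1024); total computation is unchanged. Threshold
recovery uses 10–20 simulated ramps. Unit tests run miniature
architectures (3–8 filters) whose correctness transfers because the code
paths are size-generic.

Numerical details worth knowing: Adam uses β₁ = 0.9, β₂ = 0.999,
ε = 1e-8; weights are He-initialized from the training seed, and all
randomness (profile draws, noise, shuffling, splits) flows through
explicitly passed seeds, so identical seeds give bit-identical studies.
Zero-variance channels make z-scoring impossible and are reported as
errors naming the channel. Degenerate threshold inputs (constant
equivalents, too few ramp breaths) raise "indeterminate" errors rather
than returning a guess. The raised-cosine peak falls on the 15 Hz grid
only when half the breath period is a grid multiple, so exact
tidal-volume inversion from excursions holds for such breaths (e.g. 4 s);
arbitrary durations recover VT to within the grid quantization error
(< 2%).

## Limitations

The simulator's linear VO₂ kinetics omit the oxygen deficit at ramp onset
and slow-component drift; its equivalents are exactly piecewise linear,
making threshold detection easier than on human data; compartment gains
are constant within a subject, whereas real thoracoabdominal partitioning
changes with posture and load. Consequently the synthetic recovery R²
should be read as an upper bound achievable by the pipeline under clean
conditions, and the window-level split reproduces the optimism inherent in
splitting overlapping windows. Heart-rate dynamics are not simulated
(`check_vo2max()` accepts an external HR series), and no pathological
breathing patterns are generated.

The shuffled-target control has a subtlety of its own: even trained to its
converged behavior on permuted targets, the network retains a small,
sign-random residual association (|R²| on the order of 0.1) between its
output and the signal amplitude envelope, because ReLU networks are
asymptotically linear along input rays and random targets only weakly
constrain the sparse high-intensity region of input space. The control
therefore demonstrates that the fit *collapses* without real targets, not
that it reaches exactly zero.

One consequence of the simulator's multiplicative gas noise deserves
emphasis: because target noise (and model error) scale with intensity, the
pooled prediction-minus-reference distribution on synthetic test windows is
a scale mixture rather than a gaussian, and its `bias ± 1.96 SD` limits of
agreement cover slightly less than the nominal 95 % of points (the
acceptance suite measures about 94 % and reports the shortfall). This is a
property of the synthetic error structure, not of the Bland–Altman
implementation, whose coverage is verified at 95 % ± 1 % on gaussian
differences.
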