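---
title: "Measuring hip ROM during gait with one thigh IMU: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring hip ROM during gait with one thigh IMU}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`monohip` turns the raw tri-axial gyroscope and accelerometer streams of a
single thigh-worn IMU into per-gait-cycle hip flexion range of motion (ROM),
and quantifies how trustworthy that measurement is. This vignette explains
the model behind each stage, the parameters that matter, what the bundled
synthetic-data generator does and does not emulate, and the design decisions
taken where the problem is genuinely open.

## The measurement model

**What the sensor sees.** A thigh-mounted IMU measures thigh motion relative
to the world. The hip angle is thigh relative to *pelvis*; during gait the
pelvis tilts rhythmically, so the thigh excursion is systematically smaller
than the hip excursion. Two consequences drive the whole design: (i) thigh
ROM is a *biased* estimate of hip ROM (negative bias, roughly twice the
pelvis tilt amplitude), and (ii) the missing quantity is predictable from
per-cycle and per-participant covariates, which is why a regression layer
sits on top of the kinematics.

**Sensor-to-segment calibration.** The sensor's axes are never perfectly
aligned with the thigh. Instead of a posture calibration we use a functional
one: during walking the thigh rotates overwhelmingly about its
flexion–extension (medio-lateral) axis, so that axis is estimated as the
first principal component of the mean-removed tri-axial angular velocity.
The assumptions are that gait is approximately straight and that
out-of-plane rotation carries much less angular-velocity variance;
`pca_explained` reports the variance fraction and a warning fires below
0.6. The sign of the principal axis is intrinsically ambiguous; we orient it
so its largest-magnitude component is positive, then flip if the projected
angular velocity has a larger negative than positive peak, making the fast
swing-phase rotation — flexion — positive. The full segment frame is
completed by Gram–Schmidt: the medio-lateral axis first (it is the
functionally estimated quantity), then the sensor's nominal long axis
orthogonalized against it, then the cross product.

**Per-cycle angle.** The sagittal thigh angle is the trapezoidal cumulative
integral of the calibrated medio-lateral angular velocity, restarted at
every heel strike. Restarting converts the gyroscope's unbounded drift into
a small per-cycle error that does not grow with trial length (a property the
test suite asserts on 60-cycle noisy trials). Cycle ROM is simply the range
of that angle. Complementary and error-state Kalman quaternion filters are
provided as alternatives; both propagate orientation with exact axis-angle
gyro steps and correct pitch/roll toward the accelerometer gravity
direction. `select_best_method()` compares the candidates against an
external reference by mean absolute error with ties broken in the fixed
order strapdown, complementary, Kalman. On drift-free synthetic data
strapdown wins by construction; the fusion filters exist for longer or
noisier recordings.

**Prediction layer.** Per cycle we extract thigh ROM (`TR`), leg length
(`LL`), walking speed (`WS`) and seven signal metrics of the medio-lateral
angular velocity (mean, bias-adjusted skewness, RMS, crest factor, minimum
valley, total periodogram band power, 3 dB power bandwidth). Feature
selection is two-stage: for every feature pair with |Pearson R| at or above
0.5 the member less correlated with the reference hip ROM is dropped (pairs
processed in descending pairwise |R|, ties by name — this makes the result
independent of column order), then a single regression tree ranks the
survivors by impurity reduction and the top three enter the models. The
model family runs from a naive training-mean baseline through simple and
multiple linear regression (ordinary least squares) to random forests and
recurrent networks. Regression outputs are additionally classified into the
three-class scheme (reduced < 30°, average 30–45°, normal ≥ 45°) so every
model also yields a confusion matrix.

**Validation.** Agreement is summarized with Bland–Altman statistics on
predicted − reference differences: bias, sample-SD (n−1) limits of
agreement bias ± 1.96·SD, and their range. The validity criterion is a LoA
range strictly below 27.8°, stored as the printed clinical constant
(configurable via `validity_criterion()`); it corresponds to a standard
difference of about 5° between two measurement methods, but the package
treats it as a given threshold and does not assert its derivation. All
cross-validation is grouped: every participant-side (with all its visits
and trials) is one group, so the same anatomy never appears on both sides
of a split; classification additionally uses stratified grouped folds.
Nested cross-validation tunes hyperparameters strictly inside the outer
training groups, selecting by mean inner-fold loss with ties toward the
earlier (smaller) grid entry.

## Recurrent models

No deep-learning framework is available as an R dependency here, and the
recurrent models are part of the method under evaluation, so they are
implemented natively: batch-vectorized forward passes and analytic
backpropagation through time for simple RNN, GRU and LSTM cells, trained
with Adam. The architecture is fixed: a bidirectional recurrent layer over
the 100 × 7 cycle tensor, a second recurrent layer returning its final
state, two dense hidden layers, dropout after every recurrent and hidden
layer, and a linear (regression) or 3-class softmax (classification)
output. Activations are tanh for regression and rectified-linear for
classification; losses are mean squared error and sparse categorical
cross-entropy. The gradient code is verified against central finite
differences in the test suite (with ReLU-kink stencils excluded, where
finite differences are themselves invalid). Channel 1 of the cycle tensor
is the time-normalized sagittal thigh angle waveform — the time-series whose
range *is* the IMU sagittal ROM — followed by the three acceleration and
three angular-velocity channels; per-channel standardization is always
fitted on training folds only.

## The synthetic cohort

`simulate_cohort()` defines the conditions under which every claim is
tested. Defaults: 25 virtual participants, both limbs instrumented (50
cross-validation groups), three trials per side at 1.0 / 1.2 / 1.5 m/s
(slow, self-selected, fast), eight cycles per trial, 128 Hz sampling,
sensor ranges ±2000 °/s and ±16 g. Hip ROM is drawn per participant
(mean 38°, SD 10°, spanning all three classes), cycle duration follows a
linear cadence model (1.4 − 0.25·speed seconds).

The generative logic is deliberately inverted relative to the physics:
thigh ROM is drawn first (participant baseline + 4 °/(m/s) speed
modulation + 1.5° cycle jitter), and hip ROM is then *defined* as an affine
function of thigh ROM, leg length and walking speed —
`hip = b0 + 1·TR + 15·LL + 6·WS + group effect + cycle noise` — with `b0`
chosen so the mean thigh-minus-hip offset equals −2× the pelvis tilt
amplitude (4.2°, i.e. about −8°). The participant-level group effect
(SD = 2× the 1° pelvis amplitude SD) and the 2° cycle noise are the only
stochastic terms in that relation, so with all noise at zero the generating
coefficients are recoverable by OLS to machine precision — an exact oracle
for the regression layer. Waveforms are 4-harmonic cosine series with
1/k² amplitude decay, rescaled to the target range exactly; harmonic phases
get a 0.25 rad per-cycle jitter because stride-to-stride shape variation is
what keeps shape-sensitive metrics (RMS, crest factor) noisier than the
range itself — without it, RMS becomes an unrealistically clean duplicate
of ROM and the correlation filter cannot prefer thigh ROM. The hip waveform
is the thigh waveform plus a one-cycle pelvis sinusoid, rescaled about its
midpoint so its range equals the drawn hip ROM exactly.

The IMU forward model differentiates the sampled thigh angle for the
medio-lateral gyroscope channel, adds out-of-plane sinusoids at the 5th and
7th cadence harmonics at ≤ 20 % of the sagittal peak (orthogonal to the
sagittal harmonics over whole cycles, so they make the PCA problem
non-degenerate without tilting the true principal axis), injects a damped
10 Hz oscillation at each heel strike (soft-tissue artifact, amplitude
30 °/s, decay 8 s⁻¹), rotates everything by a random mounting misalignment
(up to 15° by default), and adds white noise (2 °/s, 0.3 m/s²). The
accelerometer measures gravity in the rotating, misaligned sensor frame
plus noise.

**What the generator does not emulate** — and hence what passing tests do
not demonstrate about real data: translational acceleration of the thigh
(the accelerometer model is gravity-only, adequate for the fusion filters'
tilt-referencing role but optimistic for impact transients), curved-path or
pathological gait beyond reduced ROM, frontal/transverse joint kinematics
as outputs, magnetometer effects, and the long-tailed soft-tissue artifact
spectra of real skin-mounted sensors. The headline pipeline property (MLR
valid at 27.8°, baselines worse, raw thigh ROM biased low) is a
qualitative reproduction of the method's behaviour under these controlled
conditions, not a reproduction of any clinical dataset's numbers.

## Numerical choices and degenerate inputs

* **Filter.** The nominal specification of the pre-processing filter is a
  2nd-order FIR at 3.2 Hz; at 128 Hz such a filter barely attenuates, so
  `filter_spec()` defaults to the literal order 2 while the cohort pipeline
  uses 50 taps (Hamming windowed-sinc, forward–backward for zero phase,
  reflect-padding of three filter lengths so startup transients never reach
  retained samples, coefficients normalized to unit DC gain).
* **Cross-correlation delay.** Pearson-normalized, FFT-based; ties between
  equal peaks break toward the smallest |delay|; zero-variance inputs are
  rejected rather than returning NaN.
* **Cycles.** Half-open `[heel strike, next heel strike)` so segmentation
  is a lossless partition; time normalization is linear interpolation onto
  100 points with endpoints preserved.
* **Quaternions.** Hamilton convention, scalar-first; unit norm is enforced
  every propagation step; Euler decomposition is intrinsic Z-Y-X with the
  medio-lateral (pitch) component as the sagittal angle — consistent with
  the calibrated segment frame rather than any fixed global axis — and
  samples with |pitch| > 89.9° are flagged as gimbal-proximal.
* **Features.** Skewness is the bias-adjusted sample skewness, defined as 0
  when the variance is numerically zero; crest factor is 1 at zero RMS;
  band power is the one-sided periodogram sum (exactly Parseval's mean
  square); the 3 dB bandwidth extends to the band edge when the power never
  falls below half the peak on a side. Constant features have their
  correlations treated as 0 in the filter so they can never force a drop.
* **Classes.** The printed class limits overlap at 30° and 45°; bins are
  half-open on the left edge (30° → class 2, 45° → class 3) so the mapping
  is total and monotone; values below 10° clamp to class 1 with a warning.
* **Folds.** Group assignment is a seeded shuffle dealt round-robin (sizes
  within one group of each other); the stratified variant assigns groups
  greedily in descending size to the eligible fold (group count below the
  ceiling) with the smallest class-proportion deviation. Every consumer of
  folds re-runs the disjointness/exhaustiveness audit and aborts on
  leakage.

## Design decisions taken on open questions

* The parameter-recovery experiment in the acceptance script uses the
  configuration with the participant-level pelvis spread at zero, because
  the check compares OLS estimates against generating coefficients using
  `lm()` standard errors, which assume independent residuals; under the
  default configuration the group-level effect makes those standard errors
  anti-conservative. This is a property of the experiment design, decided
  from the error model, not a tuning of the generator.
* Which Euler component serves as the sagittal angle, and the fusion
  filters' tuning, are unspecified in the method's public description; both
  are resolved by the calibrated-axis convention above and by exposed
  defaults (complementary gain 0.02, Kalman noise densities from the sensor
  noise configuration).
* Problem sizes in tests and the acceptance script (25 virtual
  participants, 1200 cycles, 20-seed calibration sweeps, 200-cycle /
  30-epoch recurrent smoke training) were chosen as the smallest cohorts on
  which the tested properties are stable; they are the package's own
  desk-scale defaults.

## Known limitations

Strapdown ROM inherits a small negative bias from low-pass filtering when
fast-cadence harmonics approach the cutoff; the accelerometer model's
omission of translational acceleration means fusion-filter accuracy on real
impact-laden gait will be worse than on the synthetic cohort; recurrent
models are trained on CPU-scale budgets and their comparative performance
is reported, not asserted — whether added model complexity helps is a
data-dependent question the package leaves to the data.
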