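---
title: "Calibrating planar gaze from raw tracker voltages: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating planar gaze from raw tracker voltages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(gazecal)
```

## The measurement problem

An eye tracker viewing an eye that works over a *horizontal* display
reports two voltages per sample — the eye's apparent position in the
camera image — while everything else in the rig (targets, hand
position) is expressed in planar screen centimetres.  The voltage-to-cm
relationship is warped by the viewing geometry: the eye sits above and
behind the display, so equal on-screen steps near the body subtend
larger eye rotations than equal steps far away, and the voltage image
of a regular target grid is a perspectively compressed, slightly
sheared mesh.  `gazecal` fits an explicit empirical inverse of that
warp and converts its output into degrees of visual angle.

The pipeline assumes: (i) a planar display below the eye, (ii) a
voltage response that is smooth and strictly monotone in each screen
axis over the work area, (iii) head-position changes that act on the
voltages as an approximately constant additive offset, and (iv)
fixation recordings in which non-fixation samples (blinks, saccades)
can be rejected by simple range and robust-outlier rules.

## Coordinate frames and angles

Screen frame: planar cm, origin at the work-area centre, x rightward,
y away from the body.  Eye frame: X′ right, Y′ ahead, Z′ up, origin at
the eyeball centre; the screen origin sits at
`screenOriginInEyeFrame`, with a negative third component since the
display is below the eye.  `screenToEyeFrame()` is a pure translation,
so an on-screen point doubles as the gaze *vector* from the eye.

Angles between gaze vectors are defined by the scalar product,
`cos α = u·v/(‖u‖‖v‖)`.  Numerically we evaluate
`α = atan2(‖u×v‖, u·v)`: the arccosine form loses half the working
precision near `cos α = ±1` and needs clamping against floating-point
overshoot, while the `atan2` form is exact for parallel vectors and
well-conditioned everywhere.  Tests cross-check it against the
spherical law of cosines on 10⁴ random pairs at 1e−9°.

Polar coordinates follow a fixed, recorded convention: θ is the
azimuth of the projection onto the horizontal X′Y′ plane measured from
Y′ (straight ahead), positive rightward; φ is the elevation from that
plane, negative downward — so straight-ahead is (0°, 0°) and every
point on the display has φ < 0.  Whether elevation should instead be
measured from the vertical axis is a genuine convention ambiguity, so
both are supported through `rigGeometry(elevationConvention = )` and
the choice travels with the geometry object.

`displayLatency()` models the raster refresh as a linear space–time
function, `latency = distance × frame_period / screen_extent`, and
accepts a measured two-point slope override mirroring a
two-photoresistor measurement; measured slopes slightly below the
nominal one are expected and accepted.

## The synthetic rig

`pinholeForwardModel()` is a mechanistic stand-in for a
servo-controlled artificial eye: the pupil centre sits on the eyeball
sphere (radius 1.25 cm) along the gaze direction and is imaged through
a pinhole camera placed 40 cm ahead of and 12 cm below the eye,
looking back at it; image coordinates are scaled to volts.  Eyeball
rotation plus the oblique camera reproduce the depth-dependent
compression that motivates the whole method.  The default geometry —
work-area centre 30 cm ahead of and 25 cm below the eye, 20 × 9 cm
work area — is a declared fixture chosen as plausible for a primate
rig, not a measured constant; gains and offsets are chosen so the grid
spans a few volts, well inside ±10 V saturation.

Noise enters through `noiseModel()`:

* `sampleNoiseDegRMS` — per-sample angular jitter; the stated value is
  the RMS of the deviation *magnitude*, split as SD = RMS/√2 per
  tangent axis.  Monkey-grade recordings correspond to 0.048°.
* `trialScatterDegSD` — per-trial fixational offset, SD per axis in
  degrees; 0.1° is a realistic fixation scatter.
* `voltageNoiseV` — additive white sensor noise per channel.
* `headShiftV` — a constant voltage offset emulating a head shift.
* `blinkProb` — probability of a contiguous saturated, invalid-flagged
  excursion within a trial (a sentinel; no blink waveform is modelled).

Angular perturbations (jitter and scatter) are applied along the two
orthogonal tangent-plane axes of the gaze direction — horizontal and
vertical visual angle — and the deviated ray is re-intersected with
the display plane before entering the forward model.  Applying them as
raw (θ, φ) increments instead would compress the θ contribution by
cos φ and break the identity that isotropic per-axis jitter of SD σ
yields a sample-to-sample RMS of 2σ.

A second forward model, `polynomialInverseModel()`, is defined by its
*inverse*: the voltage-to-cm map is an exact bivariate quartic and the
forward direction is obtained by damped Newton iteration.  Because a
quartic calibration must recover it to numerical precision, it turns
the end-to-end pipeline into an exactly checkable round trip.  Its
default coefficients form a triangular, strictly monotone map over the
default work area; the Newton solver halves steps whenever a residual
grows and refuses to silently return non-converged points.

What the simulator does **not** emulate: corneal-reflection optics and
illuminator-position artifacts (the deformation of the reflection spot
near proximal targets), eyelid occlusion, servo dynamics, camera frame
quantization, and time-varying drift.  Passing tests therefore
demonstrate correctness of the *method* under a clean, known rig — not
performance on any particular hardware, where those omitted effects
set the error floor.

## Calibration

`selectSamples()` drops invalid-flagged samples, samples outside the
admissible voltage range, and samples deviating from the trial median
by more than 5 robust SDs (MAD-based) per channel.  Online
saccade/blink detectors are deliberately out of scope, so the default
rejection is conservative and configurable; a trial whose samples are
all rejected is reported unusable, never silently dropped, and
`averageAnchors()` fails loudly naming any target with no usable
trial.

`regridBiharmonic()` interpolates the two inverse surfaces through all
anchors with the 2-D biharmonic Green's function `g(r) = r²(ln r − 1)`
plus an affine term, solving one dense symmetric system per surface
(28 × 28 at the default 25 anchors).  The affine term makes affine
anchor sets reproduce exactly, which is also the test oracle.
Duplicate anchors make the system singular and are reported by row.
The default lattice is 50 × 50 nodes over the anchors' voltage
bounding box — fine enough that the subsequent fit sees the surface,
coarse enough to stay instantaneous.

`fitPolynomial()` uses the full total-degree basis (6/10/15 terms for
orders 2/3/4) on voltages normalized per channel to [−1, 1]; the
normalization is stored in the model and re-applied at evaluation.
Without it the quartic design matrix on raw volts is poorly
conditioned.  The fit is ordinary least squares via QR with an
explicit rank check.  Both fit targets are supported: `fitOn = "mesh"`
(the default: fit the regridded surface, which smooths interpolation
into the fit) and `fitOn = "anchors"` (fit the 25 anchors directly,
which is exact when the true inverse is itself a polynomial of the
fitted order).  Model-order comparison (`compareOrders()`) reports
per-order accuracy and paired t-tests on per-trial angular errors;
order 4 is the package default.

## Reconstruction and drift correction

`voltagesToGaze()` evaluates the stored polynomials at O(basis size)
per sample, suitable for 1 kHz streams; per-sample and vectorized
evaluation agree bit-exactly.  Voltages outside the fitted voltage box
are evaluated but flagged as extrapolation; non-finite samples yield
flagged invalid rows rather than exceptions, honouring a streaming
contract.

Drift correction uses the sign convention
`corrected = raw + (calibration centre mean − current centre mean)`,
fixed so that correction restores calibration-epoch coordinates; with
a noise-free offset estimate, shifting a session and correcting it
reproduces the original reconstruction bit for bit (verified with a
dyadic shift so the float algebra is exact).  How often drift is
re-estimated between trials is an experimental choice and is left as a
parameter.

## Validation battery

* Accuracy: median absolute angular distance to target across trials.
* Precision (IQR): interquartile range of the angular error
  distribution.  The quantile rule is fixed to linear interpolation
  (R type 7) and recorded in the report metadata, since different
  conventions move small-sample IQRs.
* Precision (RMS): RMS of angular distances between successive samples
  within one fixation — the conventional tracker-noise figure,
  insensitive to slow drift.
* Distribution comparisons: two-sided Wilcoxon rank-sum tests.
* Discriminability: from a centre-fixation voltage distribution
  (mean, SD per channel), `shiftBoundaries()` places the two mean
  shifts bracketing the significance boundary of the *expected*
  two-sample t statistic, `δ* = t_crit·σ·√(2/n)`, one a twentieth of a
  SD below it and one above — a tenth of a SD apart, deterministic and
  reproducible.  `discriminabilityTable()` draws the distribution once
  and *translates the drawn sample* by those shifts, so the
  voltage-space verdict (significant / not) holds by construction, and
  the t- and F-tests on transformed θ and φ isolate exactly what the
  procedure is meant to check: whether the transformation preserves
  discriminability.  Drawing fresh samples at shifted means instead
  would flip verdicts near the boundary by sampling noise alone and
  test the t-test rather than the transformation.  The F-test is the
  two-sided variance-ratio test; t-tests are run on θ and φ (the
  axes the reported table is labelled with) rather than on raw cm.

## Problem sizes and determinism

Simulated sessions in the tests and in `scripts/acceptance.R` use the
study-scale conditions: a 5 × 5 grid on the 20 × 9 cm work area, three
repeats, 100-ms windows at 1 kHz (75 trials, 7 500 samples per
session); validation sets use 25 grid or 25 uniformly random targets;
discriminability uses n = 1000 draws per distribution, repeated over
20 seeds; the noisy-condition acceptance quantity is the median over
10 simulation seeds of the mean angular distance on 25 random targets.
Every stochastic step takes an explicit integer seed and restores the
caller's RNG state, so sessions are bit-reproducible; seeded sessions
round-trip losslessly through the CSV format.

## Known limitations

* A single constant offset is the entire drift model; rotational head
  movement, which changes the warp itself and not just its origin,
  requires recalibration.
* The calibration is monocular and ignores torsion; there is no
  corneal-reflection channel, matching pupil-only tracking.
* The polynomial surfaces extrapolate poorly outside the calibrated
  voltage box — evaluation there is flagged, and flagged values should
  be treated as unreliable rather than merely imprecise.
* The simulator's clean pinhole rig gives error levels that bound what
  the method itself contributes; real recordings add participant
  behaviour, optics artifacts and hardware noise on top.
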