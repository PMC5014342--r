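---
title: "Methods: soil differentiation, TUG risk scoring and cue scheduling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: soil differentiation, TUG risk scoring and cue scheduling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solegait)
```

# What the package computes

An instrumented insole carries a tri-axial accelerometer under the heel and
force-sensitive resistors (FSRs) under heel and forefoot.  Two analyses run
on its streams:

1. **Soil differentiation.**  Each heel strike excites the ground; the
   vibration transient measured at the heel approximates the soil's impulse
   response, so hard slabs ring high and briefly while granular soils
   respond low, broad and noisy.  A weighted combination of spectral and
   time-domain features of each strike is reduced to a single
   *differentiation level* on which soil classes separate.
2. **Fall-risk scoring.**  A Timed Up and Go (TUG) trial — rise from a
   chair, walk 3 m, turn, walk back, sit — is segmented from the insole
   streams alone; cadence and stride length are derived from step events,
   and their variability is condensed into a risk-of-falling index.  When
   the index exceeds the reference measured on the safest surface, a
   rhythmic vibrotactile cue is scheduled at 10% above the walker's
   baseline cadence.

No public dataset of insole recordings accompanies this problem, so a
synthetic generator with exact ground truth stands in for hardware; it is
first-class, tested code, and everything below states what it does and does
not emulate.

# Heel-strike preprocessing

Strikes are gated by the heel FSR with hysteresis: a window opens above
`onset_frac` (default 0.3) of the per-recording channel maximum and closes
below `release_frac` (default 0.1), so in-contact dips do not split a
strike.  The thresholds are fractions of the observed maximum because FSR
units are uncalibrated and vary between builds.  A `max_window_ms` cap
(250 ms) keeps the window on the impact transient rather than the whole
stance phase.

Each window then passes a four-stage chain:

1. mean removal,
2. zero-padding of the tail to the next power of two,
3. multiplication by a Hamming window of the padded length,
4. Savitzky–Golay smoothing (order 3, window 11 samples at 1 kHz).

Mean removal comes first so the zero pad does not introduce a step edge
whose spectrum would swamp the soil response.  Padding before windowing
(rather than windowing the raw length) was an open choice; the chosen
order tapers the padded record as a whole, which keeps the window's
spectral leakage properties independent of the raw strike length.  The
Savitzky–Golay defaults are a common smoothing choice that preserves the
impact transient; both are exposed in the configuration
(`strike.sg_order`, `strike.sg_window`).  All four stages are linear, so
preprocessing commutes with amplitude scaling — a property the tests
exercise directly.

# Spectral centroid and the feature set

The one-sided FFT magnitude spectrum (magnitudes divided by the padded
length, "mean absolute value" scaling) is summarized by its centroid
$(S_x, S_y)$.  Two conventions are implemented:

* **area** (default): the region under the magnitude curve is a uniform
  lamina, $S_x = \sum f_i m_i / \sum m_i$ and
  $S_y = \sum m_i^2/2 \,/\, \sum m_i$.  This varies with spectral shape,
  which is what makes it a soil signature.
* **point**: every occupied bin is a unit point mass and $S_x$, $S_y$ are
  plain means.  On a fixed bin grid this makes $S_x$ nearly constant, so
  it is kept only as the literal reading of the unit-mass centroid
  definition.

$S_x$ is reported in Hz (bin index is available by rescaling); the
exclusion bounds below are therefore in Hz and magnitude units.

Each strike's feature vector is $(S_x, S_y,$ mean, standard deviation,
variance, kurtosis$)$, the last four computed on the preprocessed
time-domain window with population ($1/n$) moments; kurtosis is the plain
standardized fourth moment (Gaussian $\to 3$).  A zero-variance window
gets kurtosis 0 and a flag rather than a division by zero.  Whether the
statistics should be taken on the window or the spectrum was open; the
time domain was chosen because decay speed and noisiness — the physical
distinctions between soils — live there, while the spectrum is already
represented by the centroid.

# The differentiation level and its fit

The level of strike $i$ is $L_i = \sum_k W_k \tilde F_{ik}$ over
standardized features $\tilde F$.  Standardization is essential: raw
features differ by orders of magnitude (Hz versus m/s²), and any
weight optimization on raw features degenerates onto the largest-scaled
one.  It also makes $L$ invariant to affine rescaling of the raw features.

The weights maximize the smallest pairwise class separation

$$J(W) = \min_{c_1 \ne c_2} \frac{|\bar L_{c_1} - \bar L_{c_2}|}
  {s_{c_1} + s_{c_2} + \varepsilon}, \qquad \varepsilon = 10^{-6},$$

a Fisher-like ratio that operationalizes "push every pair of class levels
apart".  $J$ is a minimum of ratios and therefore non-smooth; a
Nelder–Mead polish alone stalls in local basins, so the fit first screens
a large seeded batch of random unit directions (200 per restart) and
polishes the leaders.  The search is deterministic given the seed.
Weights below 5% of the unit norm are zeroed after the fit — a cheap
stand-in for feature-subset selection — and the surviving vector is
renormalized.  Classes are ordered by mean level; decision thresholds sit
at midpoints of adjacent class means, and a level exactly on a threshold
goes to the lower class.  A fit with $J < 1$ (adjacent classes closer
than their summed spreads) is flagged non-separable.

Outliers are handled in centroid space: a strike whose $(S_x, S_y)$ falls
outside the rectangle $[0, x_{\max}] \times [0, y_{\max}]$ is excluded
from the detection rate (its class is still reported).  By default the
rectangle is calibrated from the training centroids (1.25 times their
maxima), because the bounds only mean something relative to the data that
defined the clusters; fixed bounds (the configuration defaults are 50 Hz
and $8\times10^{-4}$) can be supplied for a device with a frozen
calibration.

# TUG segmentation and gait parameters

The summed FSR channel frames the trial.  The loaded level is the median
force over samples above half the channel maximum; the standing threshold
is half of that.  Unloaded gaps shorter than 0.7 s (swing phases) are
bridged, and the trial is the first-to-last sustained (≥ 0.5 s) loaded
run: its start is the sit-to-stand onset, its end the stand-to-sit
completion.  Step events are peaks of the mean-removed, 10 Hz low-passed
acceleration magnitude, at least 0.3 s apart and at least half a standard
deviation tall.  The walking portion runs from the first step to the last;
the turning phase is the contiguous run of step intervals longer than 1.3
times the median interval lying nearest the temporal midpoint of the walk
— on a 3 m out-and-back course the turn is mid-trial and turning slows
stepping.  The insole alone cannot observe trunk rotation, so this
interval heuristic is the design choice; its failure mode (a mid-walk
hesitation mistaken for the turn) is visible in `plot_tug_segmentation()`.

Step counts are validated against FSR contact bursts; a disagreement
beyond 20% of the burst count switches the step source to the FSRs with a
warning, which covers a saturated or detached accelerometer.

Instantaneous cadence is $60/\Delta t$ per step interval.  Intervals
inside the turn are excluded from the cadence and stride statistics: the
turn is a deliberate slow-down, and leaving it in would dominate the
variability estimates that the risk index interprets as gait instability.
Strides pair consecutive steps within each straight-walking run (with one
instrumented side this is the same-foot approximation).  Stride length
uses the cube-root relation

$$SL = 0.98 \left( \frac{1}{N} \sum_{i=1}^{N} |a_i| \right)^{1/3}$$

on the mean-removed vertical acceleration of the stride.  The rectification
is this package's reading: the signed mean of oscillatory gait
acceleration is near zero and would make every stride length collapse.
Walking speed is the accumulated stride length over the walking-portion
duration (turn included); the 3 m nominal distance is not used because the
accumulated estimate stays meaningful when a trial deviates from the
nominal course.

# The risk index and cue scheduling

Gait variability is summarized by the coefficient of variation
$CV = 100\,\sigma/M$ (sample standard deviation — trials contribute few
strides, so the $n-1$ denominator matters).  The risk index is

$$\mathrm{Risk} = \alpha \,(CV_{cad} + CV_{SL}), \qquad
  \alpha = c/\mathrm{speed},$$

with the speed entering as a dimensionless value and $c = 1$ by default
(`risk.alpha_c`): slow, irregular gait scores high.  Risk is strictly
increasing in each CV and strictly decreasing in speed; TUG times map to
mobility categories at the printed 10 s and 16 s boundaries (boundaries
inclusive to the intermediate band).

Cues are 50 ms pulses at $1.10 \times$ baseline cadence, the baseline
being the mean cadence of at least two reference trials on the safest
surface.  The schedule is a data-level pulse train (onset, duration); the
PWM carrier that drives the motor is hardware and out of scope.  The
actuator activates when the current risk strictly exceeds the reference
risk.

# What the synthetic generator emulates — and what it does not

**Strikes** are sums of exponentially damped sinusoids at per-soil
resonances plus white "grain" noise, gated by a half-sine impact envelope;
every strike is a pure function of (profile, rate, seed).  The shipped
six-class library encodes the qualitative physics: concrete rings at
420 Hz with 1% damping and almost no noise; parquet slightly lower;
broken stone is a two-resonance mixture; snow is low, damped and noisy.
Two granular classes — sand and stone dust — are deliberately given
neighbouring resonances (150 Hz) with different damping and duration, so
their spectral centroids crowd each other while their time-domain texture
stays distinct.  That is the regime the weighted level exists for: a
centroid-only model misassigns part of that pair while the full feature
set separates it, reproducing the structure of the centroid-versus-level
comparison the method was designed around.  Grain-noise levels are kept
low (0.5–2% of impact amplitude) so that within-class feature spread is
small relative to between-class distances — the separability regime the
weighted level achieved on the real soils.  The absolute centroid
coordinates of these profiles are *not* comparable to any published
cluster plot: the real per-soil spectra were never tabulated, so the
profiles are stand-ins with the right qualitative ordering, not
reconstructions.

**TUG trials** are built at 100 Hz from a load ramp (0.4 s), a standing
hold, alternating step bumps with FSR contact bursts, three slowed turn
intervals, a return walk and an unload ramp.  Step intervals are drawn at
the nominal cadence CV and each interval is rounded to the sample grid —
interval-wise, not cumulatively — so a zero-CV profile measures exactly
zero residual variability instead of discretization jitter.  Stride
lengths are drawn at the nominal stride CV and encoded by solving, per
stride, for the bump amplitude at which the package's own stride-length
estimator returns the drawn value exactly (root-finding against the
sampled signal).  Stride-interior steps carry wide bumps holding that
solved mass; stride-boundary and turn steps carry narrow-but-tall bumps,
which keeps their mass contribution small (so the per-stride solve always
has a positive root) while leaving them prominent to the peak detector.
The defaults describe a healthy adult: 6 strides of 1 m at 120 steps/min
with 2% variability, completing the TUG in under 10 s.

Not emulated: musculoskeletal dynamics, double-support timing, freezing
of gait, sensor drift or saturation, real soil spectra, and any
between-subject structure.  Passing tests on this generator therefore
show that the *pipeline arithmetic* is right — segmentation finds the
boundaries the generator placed, the estimators invert the encodings, the
classifier separates classes that are separable by construction — not
that the method generalizes to human recordings.

# Numerical choices and degenerate inputs

* Timestamps must be uniform to 1e-6 relative spacing; FSR values
  non-negative; every recording needs `accel_z` and at least one `fsr_*`
  channel.
* CSV files are written with 17 significant digits and parsed with base
  R's correctly rounded reader, so a write–read cycle is bit-identical.
* An all-zero spectrum has no centroid (error); an all-outlier evaluation
  set yields an `NA` detection rate with a warning rather than 0/0.
* A level exactly on a threshold classifies to the lower class; weights
  are sign-normalized (largest component positive) so fits are
  reproducible bit-for-bit under a fixed seed.
* The turn-interval floor in the generator is 1.5 step intervals, keeping
  the slow-down detectable at any cadence.

# Problem sizes

The shipped study conditions are 6 soils × 13 strikes at 1 kHz for the
classification experiment, and 50 seeded trials of 20 strides at 100 Hz
with 5% nominal CVs for the variability-recovery experiment; both run in
well under a minute on one core and are what the test suite and
`scripts/acceptance.R` execute.

# Known limitations

The turn heuristic assumes one mid-trial turn; multi-turn protocols need
an explicit course model.  The stride-length relation is a calibration
formula — its 0.98 prefactor was tuned for adults walking at natural
speed and inherits that scope.  The exclusion rectangle is axis-aligned
in centroid space; a rotated or per-class region would reject outliers
more sharply.  The fit optimizes a single projection; two classes that
coincide in every feature cannot be separated by any weighting, and the
`separable` flag reports exactly that.
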