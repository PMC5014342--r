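# solegait

Gait analysis for sensor-instrumented insoles: differentiate the type of
soil underfoot from heel-strike vibration, score the risk of falling from
a Timed Up and Go (TUG) trial, and schedule rhythmic vibrotactile cues.

An *enactive insole* carries a tri-axial accelerometer in the heel, FSR
force sensors under heel and forefoot, and a vibration actuator.  For
people with impaired gait — the elderly, people with Parkinson's disease —
the surface they walk on is itself a fall-risk factor: soft or granular
soils (sand, foam carpet, gravel) destabilize gait where concrete does
not.  `solegait` implements the computation stack such an insole needs:

* **Soil differentiation.**  Each heel strike approximates the soil's
  impulse response.  Strike windows are gated by the heel FSR, passed
  through a mean-removal / zero-pad-to-2^n / Hamming / Savitzky–Golay
  chain, and summarized by the spectral centroid (S_x, S_y) of their FFT
  magnitude plus time-domain statistics (mean, SD, variance, kurtosis).
  A weighted differentiation level

      L = Σ_k W_k · F_k   (features standardized)

  is fitted by maximizing the minimum pairwise class separation
  |ΔL̄| / (s₁ + s₂); classes are intervals on the L axis, with an
  exclusion rectangle in centroid space rejecting outliers.

* **TUG risk scoring.**  The trial is segmented from the FSR load and the
  acceleration step peaks into sit-to-stand, walk, turn, walk back and
  stand-to-sit.  Per stride, SL = 0.98·(Σ|a_i|/N)^(1/3); per step
  interval, cadence = 60/Δt.  Gait variability enters as coefficients of
  variation CV = 100·σ/M, and the risk index is

      Risk = α · (CV_cad + CV_SL),   α = 1 / speed.

  TUG times under 10 s are normal mobility; over 16 s flags increased
  fall risk.

* **Cueing.**  50 ms vibrotactile pulses at 110% of the baseline cadence
  (mean of ≥ 2 reference trials on concrete), activated when the current
  risk strictly exceeds the reference risk.

* **Synthetic sensing.**  No insole dataset is public, so a tested
  generator produces labelled heel strikes (damped-resonance mixtures per
  soil, 1 kHz) and full TUG trials (100 Hz) with exact ground truth —
  phase times, step times, stride lengths, nominal variability.

## Worked example

```r
library(solegait)

# --- soil differentiation on the shipped six-class synthetic set -------
ds     <- simulate_soil_dataset(seed = 42)   # 6 soils x 13 strikes, 1 kHz
report <- run_soil_pipeline(ds)
report
#> <soil_report> 78 strikes, 6 classes
#>   detection rate: 1
#> <soil_model> 6 classes: stone_dust < sand < snow < parquet < broken_stone < concrete
#>   objective (min pairwise separation): 3.372 (separable)
#>   weights: sy= 0.118, std= 0.978, variance=-0.169

# --- TUG trial scored against two baseline walks -----------------------
b1 <- simulate_tug(gait_profile(), seed = 11)$recording
b2 <- simulate_tug(gait_profile(), seed = 12)$recording
trial <- simulate_tug(
  gait_profile(n_strides = 8, cadence_mean = 85, cadence_cv = 12,
               stride_len_mean = 0.7, stride_cv = 12, turn = 3),
  seed = 13
)$recording

tug <- run_tug_pipeline(trial, list(b1, b2))
tug
#> <tug_report>
#>   TUG time 15.84 s (intermediate); 20 steps, cadence 85.2 steps/min, speed 0.40 m/s
#>   risk 56.4% (CV_cad 12.6%, CV_SL 10.2%, alpha 2.48); reference 4.9%
#>   cue: ACTIVE at 133.2 pulses/min
```

The soil report says the fitted weighted-level model assigns every one of
the 78 training strikes to its true class (detection rate 1), leaning on
the time-domain spread (`std`) with smaller centroid contributions.  The
TUG report describes a slow, irregular walker: 15.84 s puts the trial in
the intermediate mobility band, and the high cadence/stride variability
at 0.40 m/s yields a risk of 56% against a 4.9% reference from the two
healthy baseline walks — so the cue activates, pulsing at 133 per minute
(10% above the 121 steps/min baseline cadence).

Per-object helpers follow the usual conventions: `tidy()` / `glance()` on
a fitted soil model, `autoplot()` on recordings, models and cue
schedules, `plot_tug_segmentation()` for a segmented trial, and
`read_recording()` / `write_recording()` for self-describing CSV or
JSON-Lines sensor files.  A command-line wrapper ships in
`inst/cli/solegait.R` (`simulate`, `soil fit|rate`, `tug score`, `cue`).

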