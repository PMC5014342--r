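# Synthetic heel-strike profile library: damped-resonance mixtures per
# soil class.  Frequencies in Hz, impact amplitude in m/s^2, duration in
# milliseconds, grain noise as a relative amplitude.
- soil: concrete
  resonance_freqs: [420.0]
  damping_ratios: [0.010]
  grain_noise: 0.005
  impact_amp: 28.0
  duration_ms: 60.0
- soil: parquet
  resonance_freqs: [320.0]
  damping_ratios: [0.030]
  grain_noise: 0.008
  impact_amp: 20.0
  duration_ms: 80.0
- soil: broken_stone
  resonance_freqs: [90.0, 230.0]
  damping_ratios: [0.050, 0.060]
  grain_noise: 0.02
  impact_amp: 15.0
  duration_ms: 120.0
- soil: stone_dust
  resonance_freqs: [150.0]
  damping_ratios: [0.060]
  grain_noise: 0.01
  impact_amp: 4.0
  duration_ms: 90.0
- soil: sand
  resonance_freqs: [150.0]
  damping_ratios: [0.035]
  grain_noise: 0.01
  impact_amp: 8.0
  duration_ms: 150.0
- soil: snow
  resonance_freqs: [60.0]
  damping_ratios: [0.100]
  grain_noise: 0.02
  impact_amp: 5.0
  duration_ms: 180.0
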