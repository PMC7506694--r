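# Default per-class generator profiles for synthetic VAG data.
# Severity-ordered stand-ins: increasing burst activity and widening
# emphasis bands below ~500 Hz from healthy control through chondromalacia
# stages, with osteoarthritis dominated by a strong low-frequency band.
# Amplitudes are arbitrary accelerometer units.
ctrl:
  baseline_noise_sd: 1.0
  spectral_tilt: 1.0
  emphasis_bands: []
  bursts_per_cycle: 0.5
  burst_band: [100, 400]
  burst_amplitude: 2.0
cmp1:
  baseline_noise_sd: 1.0
  spectral_tilt: 1.0
  emphasis_bands:
    - {f_lo: 150, f_hi: 300, gain: 0.8}
  bursts_per_cycle: 2.0
  burst_band: [100, 450]
  burst_amplitude: 3.0
cmp2:
  baseline_noise_sd: 1.1
  spectral_tilt: 1.0
  emphasis_bands:
    - {f_lo: 120, f_hi: 380, gain: 1.4}
  bursts_per_cycle: 4.0
  burst_band: [100, 500]
  burst_amplitude: 4.0
cmp3:
  baseline_noise_sd: 1.2
  spectral_tilt: 1.0
  emphasis_bands:
    - {f_lo: 90, f_hi: 480, gain: 2.4}
  bursts_per_cycle: 6.0
  burst_band: [100, 550]
  burst_amplitude: 6.0
oa:
  baseline_noise_sd: 1.2
  spectral_tilt: 1.5
  emphasis_bands:
    - {f_lo: 20, f_hi: 200, gain: 3.0}
  bursts_per_cycle: 5.0
  burst_band: [50, 350]
  burst_amplitude: 5.0
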