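# Shared fixtures: everything is generated in code at test time; signal
# sizes are kept small (short durations, reduced sampling rates) so the
# whole suite stays fast while exercising the full pipeline.

sine_signal <- function(freq, fs = 10000, duration = 0.6, id = "sine",
                        label = NA_character_, amplitude = 1) {
  t <- (0:(round(duration * fs) - 1)) / fs
  signal_record(id, amplitude * sin(2 * pi * freq * t), fs, label)
}

# a flat-valued spectrum on the canonical 6 s / 10 kHz grid (df = 1/6 Hz)
flat_spectrum <- function(value = 2, n = 60000, fs = 10000) {
  sp <- magnitude_spectrum(signal_record("flat", rnorm(n), fs))
  sp$values <- rep(value, length(sp$values))
  sp
}

# quiet baseline profile; optionally with one emphasis band
quiet_profile <- function(label = "ctrl", band = NULL, gain = 0) {
  class_profile(
    label,
    baseline_noise_sd = 1, spectral_tilt = 1,
    emphasis_bands = if (!is.null(band)) {
      data.frame(f_lo = band[1], f_hi = band[2], gain = gain)
    },
    bursts_per_cycle = 0, burst_band = c(100, 400), burst_amplitude = 0
  )
}

# two-class set where the classes differ only in one planted band
planted_pair_set <- function(seed, n_per_class = 10, gain = 8,
                             band = c(800, 900), fs = 2000, duration = 1) {
  pa <- quiet_profile("ctrl")
  pb <- quiet_profile("oa", band = band, gain = gain)
  recs <- c(
    lapply(seq_len(n_per_class), function(k) {
      generate_signal(pa, duration, fs, 4, seed = seed * 1000 + k,
                      id = paste0("ctrl_", k))
    }),
    lapply(seq_len(n_per_class), function(k) {
      generate_signal(pb, duration, fs, 4, seed = seed * 1000 + 500 + k,
                      id = paste0("oa_", k))
    })
  )
  signal_set(recs)
}

# small five-class synthetic dataset with the default profiles
tiny_five_class_set <- function(seed = 3, n_per_class = 4, duration = 0.5,
                                fs = 2000) {
  cfg <- synth_config(group_sizes = rep(n_per_class, 5), duration = duration,
                      sample_rate = fs, seed = seed)
  generate_dataset(cfg)
}

coarse_schedule <- function() {
  search_schedule(c(200, 50, 10), c(Inf, 100, 20))
}

# mean periodogram power of a signal inside a band
band_power <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))[seq_len(n %/% 2 + 1)]^2
  f <- (0:(n %/% 2)) * fs / n
  mean(p[f >= f_lo & f <= f_hi])
}
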