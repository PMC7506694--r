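test_that("generation is bit-deterministic under a fixed seed", {
  p <- default_profiles()[["cmp2"]]
  s1 <- generate_signal(p, 0.2, 2000, 4, seed = 9)
  s2 <- generate_signal(p, 0.2, 2000, 4, seed = 9)
  expect_identical(s1$samples, s2$samples)

  cfg <- synth_config(group_sizes = rep(2, 5), duration = 0.05,
                      sample_rate = 2000, seed = 5)
  expect_identical(generate_dataset(cfg)$records, generate_dataset(cfg)$records)
})

test_that("dataset sizes follow the configuration", {
  cfg <- synth_config(duration = 0.005, sample_rate = 10000, seed = 1)
  expect_length(generate_dataset(cfg), 184L)

  cfg10 <- synth_config(group_sizes = rep(2, 5), duration = 0.02,
                        sample_rate = 2000, seed = 1)
  expect_length(generate_dataset(cfg10), 10L)

  cfg_b <- synth_config(group_sizes = rep(2, 5), duration = 0.02,
                        sample_rate = 2000, seed = 2)
  a <- generate_dataset(cfg10)
  b <- generate_dataset(cfg_b)
  expect_identical(a$counts, b$counts)
  expect_false(identical(a$records[[1]]$samples, b$records[[1]]$samples))
})

test_that("an emphasis band raises in-band periodogram power", {
  # oracle: direct periodogram band-power comparison over 20 seeded realizations
  fs <- 2000
  ratios <- vapply(1:20, function(seed) {
    with_band <- generate_signal(quiet_profile("oa", band = c(800, 900), gain = 10),
                                 0.5, fs, 4, seed = seed)
    without <- generate_signal(quiet_profile("ctrl"), 0.5, fs, 4, seed = seed)
    r_with <- band_power(with_band$samples, fs, 800, 900) /
      band_power(with_band$samples, fs, 100, 200)
    r_without <- band_power(without$samples, fs, 800, 900) /
      band_power(without$samples, fs, 100, 200)
    r_with / r_without
  }, numeric(1))
  expect_true(all(ratios > 1))
})

test_that("a zero-gain, zero-burst, zero-tilt profile is flat colored noise", {
  p <- class_profile("ctrl", baseline_noise_sd = 2, spectral_tilt = 0,
                     bursts_per_cycle = 0, burst_amplitude = 0)
  s <- generate_signal(p, 2, 2000, 4, seed = 1)
  expect_equal(sd(s$samples), 2, tolerance = 1e-6)
  # white: low-band and high-band mean power agree within sampling noise
  r <- band_power(s$samples, 2000, 50, 300) / band_power(s$samples, 2000, 600, 850)
  expect_gt(r, 0.7)
  expect_lt(r, 1.4)
})

test_that("band edges beyond Nyquist are rejected", {
  p <- quiet_profile("ctrl", band = c(800, 1200), gain = 1)
  expect_error(generate_signal(p, 0.1, 2000, 4, seed = 1), "Nyquist")
  pb <- class_profile("ctrl", burst_band = c(900, 1100))
  expect_error(generate_signal(pb, 0.1, 2000, 4, seed = 1), "Nyquist")
})

test_that("the separability knob works: disjoint loud bands separate, identical profiles overlap", {
  fs <- 2000
  bc_sep <- numeric(10)
  bc_same <- numeric(10)
  for (rep in 1:10) {
    sep_set <- planted_pair_set(seed = rep, n_per_class = 10, gain = 8)
    labs <- vapply(sep_set$records, function(r) r$label, character(1))
    feats <- vapply(sep_set$records, function(r) {
      band_feature(family_spectrum(r, 3), 800, 900)
    }, numeric(1))
    bc_sep[rep] <- bhattacharyya(feats[labs == "ctrl"], feats[labs == "oa"])

    same_recs <- c(
      lapply(1:10, function(k) generate_signal(quiet_profile("ctrl"), 1, fs, 4,
                                               seed = 5000 + rep * 100 + k,
                                               id = paste0("ctrl_", k))),
      lapply(1:10, function(k) generate_signal(quiet_profile("oa"), 1, fs, 4,
                                               seed = 7000 + rep * 100 + k,
                                               id = paste0("oa_", k)))
    )
    same_set <- signal_set(same_recs)
    labs2 <- vapply(same_set$records, function(r) r$label, character(1))
    feats2 <- vapply(same_set$records, function(r) {
      band_feature(family_spectrum(r, 3), 800, 900)
    }, numeric(1))
    bc_same[rep] <- bhattacharyya(feats2[labs2 == "ctrl"], feats2[labs2 == "oa"])
  }
  expect_true(all(bc_sep < 0.2))
  expect_true(mean(bc_same) > 0.8)
})
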