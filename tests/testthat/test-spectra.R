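test_that("magnitude spectrum localises pure tones and DC", {
  s <- sine_signal(100, fs = 10000, duration = 6)
  sp <- magnitude_spectrum(s)
  expect_equal(sp$frequencies[which.max(sp$values)], 100)
  expect_equal(sp$bin_width, 1 / 6)
  expect_length(sp$values, 30001L)

  const <- signal_record("dc", rep(3, 1000), 1000)
  spc <- magnitude_spectrum(const)
  expect_equal(which.max(spc$values), 1L)
  expect_lt(max(spc$values[-1]), 1e-9 * spc$values[1])
})

test_that("family transforms obey their algebraic identities", {
  s <- sine_signal(137, fs = 2000, duration = 0.7)
  f1 <- family_spectrum(s, 1)
  f2 <- family_spectrum(s, 2)
  f3 <- family_spectrum(s, 3)
  f4 <- family_spectrum(s, 4)
  expect_equal(f2$values, 2 * pi * f1$frequencies * f1$values)
  expect_equal(f3$values, f1$values^2)
  expect_equal(f4$values, f2$values^2)
  expect_identical(f2$values[1], 0)
  expect_identical(f4$values[1], 0)
  expect_error(family_spectrum(s, 5), "family")
})

test_that("amplitude scaling is linear in families 1-2 and quadratic in 3-4", {
  set.seed(8)
  base <- signal_record("b", rnorm(500), 1000)  # broadband: every bin is O(1)
  scaled <- signal_record("s", 3 * base$samples, 1000)
  for (fam in 1:4) {
    ratio <- family_spectrum(scaled, fam)$values / family_spectrum(base, fam)$values
    ratio <- ratio[is.finite(ratio)]
    expect_equal(ratio, rep(if (fam <= 2) 3 else 9, length(ratio)),
                 tolerance = 1e-9)
  }
})

test_that("Parseval's identity holds for the reconstructed two-sided energy", {
  set.seed(42)
  x <- rnorm(4096)
  s <- signal_record("p", x, 1000)
  f3 <- family_spectrum(s, 3)  # |X_k|^2 one-sided
  n <- length(x)
  # restore conjugate-symmetry weights: DC and (even n) Nyquist count once
  two_sided <- 2 * sum(f3$values) - f3$values[1] -
    if (n %% 2 == 0) f3$values[length(f3$values)] else 0
  expect_equal(two_sided, n * sum(x^2), tolerance = 1e-9)
})

test_that("range snapping reproduces the canonical 1/6 Hz grid examples", {
  expect_identical(snap_range_to_bins(235.51, 235.51, 1 / 6, 30001L),
                   c(1413L, 1413L))
  expect_identical(snap_range_to_bins(100, 100.01, 1 / 6, 30001L),
                   c(600L, 600L))
  expect_identical(snap_range_to_bins(0, 5000, 1 / 6, 30001L),
                   c(0L, 30000L))
})

test_that("band_feature matches the closed-form flat-spectrum value", {
  sp <- flat_spectrum(value = 2)
  # 601 inclusive bins from 600 to 1200, normalised by 100 Hz
  expect_equal(band_feature(sp, 100, 200), 2 * 601 / 100)
  # degenerate single-bin band returns the bin value itself
  expect_equal(band_feature(sp, 235.51, 235.51), 2)
  # linearity
  sp2 <- sp
  sp2$values <- 2 * sp2$values
  expect_equal(band_feature(sp2, 100, 200), 2 * band_feature(sp, 100, 200))
  expect_error(band_feature(sp, 4000, 6000), "outside")
})

test_that("band_feature depends only on bins inside the band", {
  s <- sine_signal(300, fs = 2000, duration = 0.5)
  sp <- family_spectrum(s, 3)
  v <- band_feature(sp, 200, 400)
  tampered <- sp
  outside <- sp$frequencies < 195 | sp$frequencies > 405
  tampered$values[outside] <- tampered$values[outside] + 100
  expect_identical(band_feature(tampered, 200, 400), v)
})

test_that("baseline features locate band power and handle degenerate signals", {
  s150 <- sine_signal(150, fs = 10000, duration = 0.6)
  s350 <- sine_signal(350, fs = 10000, duration = 0.6)
  b150 <- baseline_features(s150)
  b350 <- baseline_features(s350)
  expect_gt(b150["P1"] / b150["P2"], 10)
  expect_gt(b350["P2"] / b350["P1"], 10)

  zero <- signal_record("z", rep(0, 600), 10000)
  expect_equal(unname(baseline_features(zero)), c(0, 0, 0, 0))

  short <- signal_record("s", rnorm(100), 10000)
  expect_error(baseline_features(short), "segment")
})
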