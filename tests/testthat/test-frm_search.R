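# fabricate a map with known coefficients for tie-break tests
fake_frm <- function(coef, lo, hi) {
  structure(
    list(family = 1L, pair = c("ctrl", "oa"), f_lo_axis = lo, f_hi_axis = hi,
         coefficients = coef, bin_width = min(diff(lo)), n_bins = 1000L,
         iteration = 1L),
    class = "vag_frm"
  )
}

test_that("a map's defined-cell count follows the triangular formula", {
  set <- planted_pair_set(seed = 1, n_per_class = 3, duration = 0.25)
  axes <- seq(0, 1000, by = 100)  # 11 snapped axis points
  map <- compute_frm(set, c("ctrl", "oa"), 1, axes, allow_degenerate = TRUE)
  expect_length(map$f_lo_axis, 11L)
  expect_equal(sum(!is.na(map$coefficients)), 11L * 12L / 2L)
  strict <- compute_frm(set, c("ctrl", "oa"), 1, axes, allow_degenerate = FALSE)
  expect_equal(sum(!is.na(strict$coefficients)), 11L * 10L / 2L)
  defined <- map$coefficients[!is.na(map$coefficients)]
  expect_true(all(defined >= 0 & defined <= 1))
})

test_that("classes with identical generating distributions show no spurious separability", {
  mins <- vapply(1:10, function(seed) {
    recs <- c(
      lapply(1:30, function(k) generate_signal(quiet_profile("ctrl"), 0.5, 1000, 4,
                                               seed = seed * 10000 + k,
                                               id = paste0("ctrl_", k))),
      lapply(1:30, function(k) generate_signal(quiet_profile("oa"), 0.5, 1000, 4,
                                               seed = seed * 10000 + 5000 + k,
                                               id = paste0("oa_", k)))
    )
    set <- signal_set(recs)
    map <- compute_frm(set, c("ctrl", "oa"), 1, seq(0, 500, by = 100))
    min(map$coefficients, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(mins > 0.7))
})

test_that("best_cell takes the argmin and breaks ties by width then lower bound", {
  coef <- matrix(NA_real_, 3, 3)
  coef[1, 2] <- 0.5; coef[1, 3] <- 0.30; coef[2, 3] <- 0.30
  # widths: (1,3) = 100, (2,3) = 50 -> narrower wins
  m <- fake_frm(coef, lo = c(0, 50, 100), hi = c(0, 50, 100))
  b <- best_cell(m)
  expect_equal(b$coefficient, 0.30)
  expect_equal(c(b$f_lo, b$f_hi), c(50, 100))

  # equal widths -> smaller f_lo wins
  coef2 <- matrix(NA_real_, 3, 3)
  coef2[1, 2] <- 0.2; coef2[2, 3] <- 0.2
  b2 <- best_cell(fake_frm(coef2, c(0, 50, 100), c(0, 50, 100)))
  expect_equal(c(b2$f_lo, b2$f_hi), c(0, 50))

  expect_error(best_cell(fake_frm(matrix(NA_real_, 2, 2), c(0, 1), c(0, 1))),
               "no defined cells")
})

test_that("map cells agree with direct band-feature + Bhattacharyya evaluation", {
  set <- planted_pair_set(seed = 6, n_per_class = 4, duration = 0.25)
  axes <- seq(0, 1000, by = 250)
  map <- compute_frm(set, c("ctrl", "oa"), 3, axes)
  labs <- vapply(set$records, function(r) r$label, character(1))
  for (i in seq_along(map$f_lo_axis)) {
    for (j in seq_along(map$f_hi_axis)) {
      if (is.na(map$coefficients[i, j])) next
      feats <- vapply(set$records, function(r) {
        band_feature(family_spectrum(r, 3), map$f_lo_axis[i], map$f_hi_axis[j])
      }, numeric(1))
      direct <- bhattacharyya(feats[labs == "ctrl"], feats[labs == "oa"])
      expect_equal(map$coefficients[i, j], direct, tolerance = 1e-9)
    }
  }
})

test_that("iterative search refines monotonically, snaps to bins and is reproducible", {
  set <- planted_pair_set(seed = 2, n_per_class = 6, duration = 0.5)
  res <- iterative_search(set, c("ctrl", "oa"), 3, coarse_schedule())
  expect_length(res$maps, 3L)
  bests <- vapply(res$maps, function(m) best_cell(m)$coefficient, numeric(1))
  expect_true(all(diff(bests) <= 0))
  expect_equal(res$best$coefficient, bests[3])
  for (m in res$maps) {
    expect_equal(m$f_lo_axis / m$bin_width,
                 round(m$f_lo_axis / m$bin_width), tolerance = 1e-9)
  }
  res2 <- iterative_search(set, c("ctrl", "oa"), 3, coarse_schedule())
  expect_identical(res$best, res2$best)
  expect_identical(lapply(res$maps, `[[`, "coefficients"),
                   lapply(res2$maps, `[[`, "coefficients"))
})

test_that("the full forty-search build yields 120 maps and a ten-row spec", {
  set <- tiny_five_class_set(seed = 8, n_per_class = 3, duration = 0.25)
  sched <- search_schedule(c(250, 100, 25), c(Inf, 150, 50))
  res <- build_feature_spec(set, sched)
  expect_length(res$maps, 120L)
  expect_equal(sum(vapply(res$maps, `[[`, integer(1), "iteration") == 3L), 40L)
  defs <- res$spec$definitions
  expect_equal(nrow(defs), 10L)
  expect_identical(defs$letter, letters[1:10])
  # per-pair selection = min over that pair's four family results
  fr <- res$spec$family_results
  for (l in letters[1:10]) {
    expect_equal(defs$coefficient[defs$letter == l],
                 min(fr$coefficient[fr$letter == l]))
  }
})

test_that("a dataset missing a class is rejected by name", {
  set <- tiny_five_class_set(seed = 9, n_per_class = 3, duration = 0.1)
  four <- signal_set(set$records[vapply(set$records, function(r) r$label != "cmp2",
                                        logical(1))])
  expect_error(build_feature_spec(four, coarse_schedule()), "cmp2")
})

test_that("FRM TSV export round-trips and keeps the best cell", {
  set <- planted_pair_set(seed = 3, n_per_class = 3, duration = 0.25)
  map <- compute_frm(set, c("ctrl", "oa"), 2, seq(0, 1000, by = 200),
                     iteration = 2L)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_frm(map, path)
  back <- import_frm(path)
  expect_identical(back$f_lo_axis, map$f_lo_axis)
  expect_identical(back$f_hi_axis, map$f_hi_axis)
  expect_identical(back$coefficients, map$coefficients)
  expect_identical(back$pair, map$pair)
  expect_identical(back$iteration, map$iteration)
  expect_identical(best_cell(back), best_cell(map))
})

test_that("feature spec JSON serialisation round-trips the definitions", {
  set <- tiny_five_class_set(seed = 10, n_per_class = 3, duration = 0.1)
  sched <- search_schedule(c(400, 200, 100), c(Inf, 300, 150))
  res <- build_feature_spec(set, sched)
  path <- withr::local_tempfile(fileext = ".json")
  write_feature_spec(res$spec, path)
  back <- read_feature_spec(path)
  expect_equal(back$definitions, res$spec$definitions)
  expect_equal(back$schedule$steps_hz, res$spec$schedule$steps_hz)
  expect_equal(back$sample_rate, res$spec$sample_rate)
})
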