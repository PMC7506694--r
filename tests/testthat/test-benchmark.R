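# a hand-made ten-definition spec on simple bands, for feature extraction tests
toy_spec <- function(sample_rate = 2000, n_samples = 500) {
  p <- class_pairs()
  structure(
    list(
      definitions = data.frame(
        letter = p$letter, class_a = p$class_a, class_b = p$class_b,
        family = rep(1:4, length.out = 10),
        f_lo_hz = seq(50, 500, by = 50),
        f_hi_hz = seq(50, 500, by = 50) + 100,
        coefficient = NA_real_, stringsAsFactors = FALSE
      ),
      family_results = NULL,
      schedule = search_schedule(c(200, 100, 50), c(Inf, 100, 50)),
      sample_rate = sample_rate, n_samples = n_samples,
      provenance = list()
    ),
    class = "vag_feature_spec"
  )
}

test_that("extract_features builds an n x 10 matrix consistent with the spectra stack", {
  set <- tiny_five_class_set(seed = 12, n_per_class = 2, duration = 0.25)
  spec <- toy_spec()
  x <- extract_features(set, spec)
  expect_equal(dim(x), c(10L, 10L))
  expect_identical(colnames(x), letters[1:10])
  expect_false(anyNA(x))
  # spot-check three cells against direct evaluation
  for (j in c(1L, 4L, 10L)) {
    d <- spec$definitions[j, ]
    r <- set$records[[3]]
    expect_equal(x[3, j],
                 band_feature(family_spectrum(r, d$family), d$f_lo_hz, d$f_hi_hz),
                 tolerance = 1e-12)
  }
  # a constant-zero signal has an all-zero feature row
  zrec <- signal_record("zero", rep(0, 500), 2000, "ctrl")
  xz <- extract_features(list(zrec), spec)
  expect_equal(unname(xz[1, ]), rep(0, 10))
  # Nyquist mismatch is rejected
  expect_error(extract_features(set, toy_spec(sample_rate = 4000)), "sample rate")
})

test_that("improvement reproduces the published arithmetic and its sign convention", {
  expect_equal(round(improvement(0.48, 0.64), 1), 33.3)
  expect_equal(round(improvement(0.549, 0.316, lower_is_better = TRUE), 2), 42.44)
  expect_equal(improvement(0.5, 0.5), 0)
  expect_error(improvement(0, 0.3), "old = 0")
  # antisymmetry up to scaling: swapping roles flips the sign, rescaled by new/old
  old <- 0.6; new <- 0.45
  expect_equal(improvement(old, new, TRUE),
               -improvement(new, old, TRUE) * new / old, tolerance = 1e-12)
})

test_that("the benchmark is deterministic and validates its inputs", {
  set.seed(20)
  x <- matrix(rnorm(50 * 4), 50, 4)
  labs <- factor(rep(vag_labels(), each = 10), levels = vag_labels())
  suite <- default_classifier_suite()[c(1, 3, 6)]
  b1 <- run_benchmark(x, labs, suite, n_repeats = 6, seed = 5)
  b2 <- run_benchmark(x, labs, suite, n_repeats = 6, seed = 5)
  expect_identical(b1$accuracies, b2$accuracies)
  b3 <- run_benchmark(x, labs, suite, n_repeats = 6, seed = 6)
  expect_false(identical(b1$accuracies, b3$accuracies))
  expect_true(all(b1$accuracies >= 0 & b1$accuracies <= 1))

  thin <- factor(c(rep("ctrl", 46), rep("oa", 4)), levels = vag_labels())
  expect_error(run_benchmark(x, thin, suite, n_repeats = 2), ">= 5")
  expect_error(run_benchmark(x, factor(rep("ctrl", 50))), "2 classes")
})

test_that("training accuracy dominates test accuracy on average", {
  set.seed(30)
  x <- matrix(rnorm(60 * 4), 60, 4)
  labs <- factor(rep(vag_labels(), each = 12), levels = vag_labels())
  cfg <- default_classifier_suite()[[1]]  # depth-limited tree
  gap <- replicate(30, {
    sp <- vagfrm:::stratified_split(labs)
    xs <- vagfrm:::standardise_by(x, sp$teach)
    m <- vagfrm:::fit_classifier(cfg, xs[sp$teach, ], labs[sp$teach])
    mean(m(xs[sp$teach, ]) == as.character(labs[sp$teach])) -
      mean(m(xs[sp$test, ]) == as.character(labs[sp$test]))
  })
  expect_gt(mean(gap), 0)
})

test_that("the paired comparison shares splits, summarises correctly and reproduces", {
  set <- tiny_five_class_set(seed = 13, n_per_class = 6, duration = 0.1,
                             fs = 10000)
  spec <- toy_spec(sample_rate = 10000, n_samples = 1000)
  suite <- default_classifier_suite()[c(3, 6)]
  cmp1 <- compare_feature_sets(set, spec, suite, n_repeats = 4, seed = 3)
  cmp2 <- compare_feature_sets(set, spec, suite, n_repeats = 4, seed = 3)
  expect_identical(cmp1$table, cmp2$table)

  tab <- cmp1$table
  body <- tab[!tab$classifier %in% c("mean", "max"), ]
  mean_row <- tab[tab$classifier == "mean", ]
  max_row <- tab[tab$classifier == "max", ]
  expect_equal(mean_row$improvement_pct, mean(body$improvement_pct))
  expect_equal(mean_row$accuracy_new, mean(body$accuracy_new))
  expect_equal(max_row$accuracy_new, max(body$accuracy_new))
  expect_equal(body$improvement_pct,
               improvement(body$accuracy_old, body$accuracy_new))
})
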