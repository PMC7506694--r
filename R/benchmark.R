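#' Extract the ten-feature matrix for a dataset
#'
#' One row per signal, one column per feature definition (letters a-j):
#' column j is the band feature of definition j's family spectrum over its
#' frequency band.
#'
#' @param set A [signal_set()] (or plain list of [signal_record()]s for
#'   unlabeled prediction inputs).
#' @param spec A `vag_feature_spec` from [build_feature_spec()] /
#'   [read_feature_spec()].
#' @return Numeric matrix with signal ids as row names and letters as
#'   column names.
#' @export
extract_features <- function(set, spec) {
  stopifnot(inherits(spec, "vag_feature_spec"))
  records <- if (inherits(set, "vag_dataset")) set$records else set
  sr <- records[[1L]]$sample_rate
  if (!is.null(spec$sample_rate) && abs(sr - spec$sample_rate) > 1e-9) {
    vag_stop(sprintf(
      "dataset sample rate (%g Hz) disagrees with the feature spec (%g Hz)",
      sr, spec$sample_rate))
  }
  defs <- spec$definitions
  out <- matrix(NA_real_, nrow = length(records), ncol = nrow(defs),
                dimnames = list(vapply(records, function(r) r$id, character(1)),
                                defs$letter))
  for (fam in unique(defs$family)) {
    rows <- which(defs$family == fam)
    for (i in seq_along(records)) {
      sp <- family_spectrum(records[[i]], fam)
      for (j in rows) {
        out[i, j] <- band_feature(sp, defs$f_lo_hz[j], defs$f_hi_hz[j])
      }
    }
  }
  out
}

# stratified teaching/testing/validation split; returns index list
stratified_split <- function(labels, split = c(0.6, 0.2, 0.2)) {
  if (abs(sum(split) - 1) > 1e-9 || any(split < 0)) {
    vag_stop("split proportions must be nonnegative and sum to 1")
  }
  teach <- integer(0); test <- integer(0); valid <- integer(0)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (length(idx) == 0L) next
    if (length(idx) < 3L) {
      vag_stop(sprintf("class %s has %d member(s); need >= 3 for a 3-way split",
                       cl, length(idx)))
    }
    idx <- sample(idx)
    n_teach <- max(1L, round(split[1L] * length(idx)))
    n_test <- max(1L, round(split[2L] * length(idx)))
    n_teach <- min(n_teach, length(idx) - n_test - (split[3L] > 0))
    teach <- c(teach, idx[seq_len(n_teach)])
    test <- c(test, idx[n_teach + seq_len(n_test)])
    if (n_teach + n_test < length(idx)) {
      valid <- c(valid, idx[(n_teach + n_test + 1L):length(idx)])
    }
  }
  list(teach = teach, test = test, valid = valid)
}

# column standardisation fit on the teaching split only (leakage prevention)
standardise_by <- function(x, teach_idx) {
  mu <- colMeans(x[teach_idx, , drop = FALSE])
  sdev <- apply(x[teach_idx, , drop = FALSE], 2L, stats::sd)
  sdev[sdev == 0 | !is.finite(sdev)] <- 1
  scale(x, center = mu, scale = sdev)
}

#' Repeated-random-split classifier benchmark
#'
#' For each repeat, the data are split stratified-at-random into teaching,
#' testing and validation portions, columns are standardised on the teaching
#' split, every configured classifier is fitted on the teaching split and
#' its accuracy measured on the testing split. Reported accuracies are means
#' over repeats, which removes the split-to-split luck that a single
#' partition would bake in.
#'
#' @param features Numeric feature matrix, one row per signal.
#' @param labels Factor (or character) of class labels, one per row.
#' @param configs Classifier configs, default [default_classifier_suite()].
#' @param n_repeats Number of random splits (the study design uses 1024).
#' @param split Teaching/testing/validation proportions (validation is held
#'   out unused by the default classifiers).
#' @param seed Integer seed; the whole benchmark is deterministic given it.
#' @return Object of class `vag_benchmark`: data frame `results`
#'   (classifier, mean_accuracy, sd_accuracy) plus `n_repeats`, `split`,
#'   `seed`, and the per-repeat accuracy matrix `accuracies`.
#' @export
run_benchmark <- function(features, labels, configs = default_classifier_suite(),
                          n_repeats = 1024L, split = c(0.6, 0.2, 0.2),
                          seed = 1L) {
  features <- as.matrix(features)
  labels <- droplevels(factor(labels))
  if (nlevels(labels) < 2L) vag_stop("need at least 2 classes")
  if (nrow(features) != length(labels)) vag_stop("features/labels length mismatch")
  if (any(table(labels) < 5L)) {
    vag_stop("every class needs >= 5 members for stratified splitting")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  repeat_seeds <- sample.int(2147483646L, n_repeats)
  acc <- matrix(NA_real_, nrow = n_repeats, ncol = length(configs))
  for (r in seq_len(n_repeats)) {
    set.seed(repeat_seeds[r])
    sp <- stratified_split(labels, split)
    xs <- standardise_by(features, sp$teach)
    for (ci in seq_along(configs)) {
      set.seed(repeat_seeds[r] + ci)
      model <- fit_classifier(configs[[ci]], xs[sp$teach, , drop = FALSE],
                              labels[sp$teach])
      pred <- model(xs[sp$test, , drop = FALSE])
      acc[r, ci] <- mean(pred == as.character(labels[sp$test]))
    }
  }
  structure(
    list(
      results = data.frame(
        classifier = vapply(configs, function(cf) cf$label, character(1)),
        info = vapply(configs, function(cf) cf$info, character(1)),
        mean_accuracy = colMeans(acc),
        sd_accuracy = apply(acc, 2L, stats::sd),
        stringsAsFactors = FALSE
      ),
      accuracies = acc, n_repeats = n_repeats, split = split, seed = seed
    ),
    class = "vag_benchmark"
  )
}

#' @export
print.vag_benchmark <- function(x, ...) {
  cat(sprintf("<vag_benchmark> %d repeats, split %s, seed %d\n",
              x$n_repeats, paste(x$split, collapse = "/"), x$seed))
  print(x$results, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Relative improvement of a metric, in percent
#'
#' For a lower-is-better metric (such as the Bhattacharyya coefficient)
#' this is `(old - new) / old * 100`; for a higher-is-better metric (such
#' as classification accuracy) it is `(new - old) / old * 100`, so that a
#' positive value always means the new method did better.
#'
#' @param old,new Metric values; `old` must be nonzero.
#' @param lower_is_better Direction of the metric.
#' @return Improvement in percent (vectorised).
#' @export
#' @examples
#' improvement(0.549, 0.316, lower_is_better = TRUE)   # 42.44
#' improvement(0.48, 0.64, lower_is_better = FALSE)    # 33.3
improvement <- function(old, new, lower_is_better = FALSE) {
  if (any(old == 0)) vag_stop("improvement undefined for old = 0")
  if (lower_is_better) (old - new) / old * 100 else (new - old) / old * 100
}

#' Paired benchmark of the new ten-feature set against the baseline four
#'
#' Extracts the ten pairwise band features and the four classical
#' comparator features (P1, P2, F470, F780) for the same signals, then runs
#' the repeated-random-split benchmark with *identical* partitions per
#' repeat for both feature sets (a paired comparison, removing split noise
#' from the contrast), and tabulates per-classifier accuracies and
#' improvements plus mean and max summary rows.
#'
#' @param set A [signal_set()].
#' @param spec A `vag_feature_spec`.
#' @param configs,n_repeats,split,seed As in [run_benchmark()].
#' @return Object of class `vag_comparison` whose `table` element mirrors
#'   the published comparison layout: classifier, info, accuracy_new,
#'   accuracy_old, improvement_pct, with `mean` and `max` rows appended.
#' @export
compare_feature_sets <- function(set, spec, configs = default_classifier_suite(),
                                 n_repeats = 1024L, split = c(0.6, 0.2, 0.2),
                                 seed = 1L) {
  stopifnot(inherits(set, "vag_dataset"))
  x_new <- extract_features(set, spec)
  x_old <- baseline_feature_matrix(set)
  labels <- droplevels(dataset_labels(set))
  if (any(table(labels) < 5L)) {
    vag_stop("every class needs >= 5 members for stratified splitting")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  repeat_seeds <- sample.int(2147483646L, n_repeats)
  acc_new <- matrix(NA_real_, n_repeats, length(configs))
  acc_old <- matrix(NA_real_, n_repeats, length(configs))
  for (r in seq_len(n_repeats)) {
    set.seed(repeat_seeds[r])
    sp <- stratified_split(labels, split)
    xn <- standardise_by(x_new, sp$teach)
    xo <- standardise_by(x_old, sp$teach)
    truth <- as.character(labels[sp$test])
    for (ci in seq_along(configs)) {
      set.seed(repeat_seeds[r] + ci)
      m <- fit_classifier(configs[[ci]], xn[sp$teach, , drop = FALSE],
                          labels[sp$teach])
      acc_new[r, ci] <- mean(m(xn[sp$test, , drop = FALSE]) == truth)
      set.seed(repeat_seeds[r] + ci)
      m <- fit_classifier(configs[[ci]], xo[sp$teach, , drop = FALSE],
                          labels[sp$teach])
      acc_old[r, ci] <- mean(m(xo[sp$test, , drop = FALSE]) == truth)
    }
  }
  mean_new <- colMeans(acc_new)
  mean_old <- colMeans(acc_old)
  tab <- data.frame(
    classifier = vapply(configs, function(cf) cf$label, character(1)),
    info = vapply(configs, function(cf) cf$info, character(1)),
    accuracy_new = mean_new,
    accuracy_old = mean_old,
    improvement_pct = improvement(mean_old, mean_new, lower_is_better = FALSE),
    stringsAsFactors = FALSE
  )
  tab <- rbind(
    tab,
    data.frame(classifier = "mean", info = "",
               accuracy_new = mean(mean_new), accuracy_old = mean(mean_old),
               improvement_pct = mean(tab$improvement_pct),
               stringsAsFactors = FALSE),
    data.frame(classifier = "max", info = "",
               accuracy_new = max(mean_new), accuracy_old = max(mean_old),
               improvement_pct = max(tab$improvement_pct),
               stringsAsFactors = FALSE)
  )
  structure(
    list(table = tab, accuracies_new = acc_new, accuracies_old = acc_old,
         n_repeats = n_repeats, split = split, seed = seed),
    class = "vag_comparison"
  )
}

#' @export
print.vag_comparison <- function(x, ...) {
  cat(sprintf("<vag_comparison> %d repeats, seed %d\n", x$n_repeats, x$seed))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}
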