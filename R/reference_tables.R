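# Published reference values from the original clinical VAG study (184
# signals from five diagnosed groups). The raw recordings are not publicly
# deposited, so these tables are the fixed comparison points for the
# improvement arithmetic and for sanity checks; nothing in the package
# recomputes them from data.

#' Reference per-family Bhattacharyya coefficients
#'
#' The published best-band Bhattacharyya coefficient for every class pair
#' (letters a-j) and every feature family, obtained on the original
#' 184-signal clinical dataset.
#'
#' @return Data frame with columns `letter`, `class_a`, `class_b`,
#'   `family1`..`family4`.
#' @export
reference_family_coefficients <- function() {
  p <- class_pairs()
  cbind(p, data.frame(
    family1 = c(0.863, 0.634, 0.318, 0.308, 0.726, 0.446, 0.401, 0.637, 0.594, 0.900),
    family2 = c(0.844, 0.629, 0.316, 0.367, 0.717, 0.442, 0.486, 0.667, 0.696, 0.919),
    family3 = c(0.842, 0.659, 0.453, 0.458, 0.769, 0.560, 0.587, 0.694, 0.741, 0.897),
    family4 = c(0.872, 0.662, 0.464, 0.462, 0.768, 0.577, 0.603, 0.693, 0.744, 0.876)
  ))
}

#' Reference optimal frequency ranges
#'
#' The published best frequency band (Hz) per class pair and family on the
#' original clinical dataset. Several optima are single-frequency bands
#' (`f_lo == f_hi`), which is why degenerate bands are first-class in
#' [band_feature()].
#'
#' @return Data frame with columns `letter`, `class_a`, `class_b`, `family`,
#'   `f_lo_hz`, `f_hi_hz`.
#' @export
reference_frequency_ranges <- function() {
  p <- class_pairs()
  lo <- rbind(
    c(235.51, 279.95, 235.51, 226.56),
    c(240.23, 240.23, 331.22, 331.22),
    c(111.17, 103.19, 109.70, 26.20),
    c(15.79, 0.00, 47.69, 0.00),
    c(398.11, 405.76, 258.30, 239.10),
    c(78.78, 15.14, 78.61, 9.11),
    c(8.46, 0.81, 42.64, 0.81),
    c(94.40, 91.80, 88.05, 79.92),
    c(8.79, 0.00, 71.45, 233.40),
    c(0.00, 0.98, 16.28, 157.88)
  )
  hi <- rbind(
    c(235.51, 279.95, 235.51, 226.56),
    c(240.56, 240.56, 331.38, 331.38),
    c(452.96, 359.21, 428.39, 303.71),
    c(1110.68, 554.85, 5000.00, 649.25),
    c(398.93, 405.76, 258.63, 239.10),
    c(465.82, 417.97, 428.39, 290.36),
    c(849.61, 470.70, 5000.00, 690.92),
    c(394.86, 287.43, 392.42, 263.83),
    c(955.73, 513.02, 5000.00, 233.89),
    c(4384.44, 166.18, 193.20, 157.88)
  )
  out <- do.call(rbind, lapply(1:4, function(fam) {
    cbind(p, data.frame(family = fam, f_lo_hz = lo[, fam], f_hi_hz = hi[, fam]))
  }))
  out[order(out$letter, out$family), ]
}

#' Reference baseline-feature Bhattacharyya coefficients
#'
#' The published Bhattacharyya coefficients of the four classical
#' comparator features (P1 50-250 Hz, P2 250-450 Hz, F470, F780) per class
#' pair on the original clinical dataset, together with the published
#' per-pair improvement of the new band features over the best comparator.
#'
#' @return Data frame with columns `letter`, `class_a`, `class_b`, `P1`,
#'   `P2`, `F470`, `F780`, `improvement_pct`.
#' @export
reference_baseline_coefficients <- function() {
  p <- class_pairs()
  cbind(p, data.frame(
    P1 = c(0.964, 0.906, 0.549, 0.582, 0.942, 0.607, 0.670, 0.809, 0.809, 0.924),
    P2 = c(0.960, 0.795, 0.668, 0.516, 0.874, 0.782, 0.635, 0.881, 0.809, 0.962),
    F470 = c(0.951, 0.924, 0.837, 0.860, 0.936, 0.882, 0.901, 0.952, 0.950, 0.985),
    F780 = c(0.963, 0.943, 0.947, 0.943, 0.904, 0.955, 0.948, 0.965, 0.951, 0.980),
    improvement_pct = c(11.46, 17.11, 42.44, 40.31, 17.96, 43.48, 36.85,
                        21.26, 26.58, 5.19)
  ))
}

#' Reference classifier accuracies
#'
#' The published mean test accuracies (over 1024 random splits of the
#' original clinical dataset) of the ten benchmark classifiers on the new
#' ten-feature vectors and on the classical four-feature vectors, with the
#' published improvement percentages.
#'
#' @return Data frame with columns `classifier`, `info`, `accuracy_new`,
#'   `accuracy_old`, `improvement_pct`.
#' @export
reference_classifier_accuracies <- function() {
  data.frame(
    classifier = c("decision tree", "decision tree", "discriminant analysis",
                   "naive Bayes", "support vector machine",
                   "k nearest neighbors", "k nearest neighbors",
                   "decision forest", "decision forest", "neural network"),
    info = c("max. 10 splits", "max. 5 splits", "", "", "linear kernel",
             "k = 20, euclidean distance", "k = 5, euclidean distance",
             "bagging", "boosting, max 10 splits",
             "10 hidden neurons, tansig function"),
    accuracy_new = c(0.62, 0.60, 0.63, 0.64, 0.67, 0.64, 0.63, 0.62, 0.63, 0.63),
    accuracy_old = c(0.59, 0.59, 0.53, 0.48, 0.63, 0.61, 0.62, 0.57, 0.60, 0.60),
    improvement_pct = c(5.1, 1.7, 18.9, 33.3, 6.3, 4.9, 1.6, 8.8, 5.0, 5.0),
    stringsAsFactors = FALSE
  )
}
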