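#' Coarse-to-fine search schedule
#'
#' Each iteration is a (step, window) pair: the grid step in Hz and the
#' half-width of the refinement window around the previous best band's
#' bounds (the first window is ignored; iteration one always scans the full
#' 0-Nyquist triangle). The default three-iteration schedule scans the full
#' range at ~10 Hz, then +/-800 Hz at ~2.5 Hz, then +/-80 Hz at the
#' spectrum's native resolution (~0.167 Hz for a 6 s recording). Steps are
#' snapped to integer multiples of the spectrum bin width at search time.
#'
#' @param steps_hz Strictly decreasing positive grid steps, one per iteration.
#' @param windows_hz Refinement half-widths, same length; the first entry is
#'   conventionally `Inf`.
#' @return Object of class `vag_schedule`.
#' @export
search_schedule <- function(steps_hz = c(10, 2.5, 1 / 6),
                            windows_hz = c(Inf, 800, 80)) {
  steps_hz <- as.numeric(steps_hz)
  windows_hz <- as.numeric(windows_hz)
  if (length(steps_hz) != length(windows_hz) || length(steps_hz) < 1L) {
    vag_stop("steps_hz and windows_hz must have equal positive length")
  }
  if (any(steps_hz <= 0) || any(diff(steps_hz) >= 0)) {
    vag_stop("steps_hz must be positive and strictly decreasing")
  }
  if (any(windows_hz[-1L] <= 0)) vag_stop("refinement windows must be positive")
  structure(list(steps_hz = steps_hz, windows_hz = windows_hz),
            class = "vag_schedule")
}

# cumulative band sums for all signals of one class, one family:
# row per signal, column i = sum of spectrum values over bins 0..i-1
# (leading zero column), so bins a..b sum to cums[, b+2] - cums[, a+1].
family_cums <- function(records, family) {
  first <- family_spectrum(records[[1L]], family)
  n_bins <- length(first$values)
  out <- matrix(0, nrow = length(records), ncol = n_bins + 1L)
  out[1L, -1L] <- cumsum(first$values)
  if (length(records) > 1L) {
    for (i in 2L:length(records)) {
      out[i, -1L] <- cumsum(family_spectrum(records[[i]], family)$values)
    }
  }
  list(cums = out, bin_width = first$bin_width, n_bins = n_bins)
}

# band features for every signal at one snapped bin range
band_features_from_cums <- function(cums, i_lo, i_hi, bin_width) {
  s <- cums[, i_hi + 2L] - cums[, i_lo + 1L]
  if (i_lo == i_hi) {
    s  # single bin: the bin value itself (normalisation factor 1)
  } else {
    s / ((i_hi - i_lo) * bin_width)
  }
}

frm_core <- function(cums_a, cums_b, lo_bins, hi_bins, bin_width,
                     allow_degenerate = TRUE, grid_points = 2048L, padding = 4) {
  coef <- matrix(NA_real_, nrow = length(lo_bins), ncol = length(hi_bins))
  for (i in seq_along(lo_bins)) {
    for (j in seq_along(hi_bins)) {
      il <- lo_bins[i]
      ih <- hi_bins[j]
      if (il > ih || (!allow_degenerate && il == ih)) next
      fa <- band_features_from_cums(cums_a, il, ih, bin_width)
      fb <- band_features_from_cums(cums_b, il, ih, bin_width)
      coef[i, j] <- bhattacharyya(fa, fb, grid_points = grid_points,
                                  padding = padding)
    }
  }
  coef
}

#' Compute one Frequency Range Map
#'
#' A Frequency Range Map (FRM) tabulates, for a class pair and feature
#' family, the Bhattacharyya coefficient of the band feature over every
#' (lower bound, upper bound) combination of the supplied frequency axes.
#' Cells with `f_lo > f_hi` (and, unless `allow_degenerate`, `f_lo == f_hi`)
#' are undefined (`NA`); defined entries lie in \[0, 1\], small values
#' marking bands that separate the pair well. Axis frequencies are snapped
#' to the spectrum bin grid.
#'
#' @param set A [signal_set()] containing both classes.
#' @param pair Character vector of two class labels.
#' @param family Feature family 1-4 (see [family_spectrum()]).
#' @param f_lo_axis,f_hi_axis Numeric axes in Hz; `f_hi_axis` defaults to
#'   `f_lo_axis`.
#' @param allow_degenerate Admit single-frequency bands (`f_lo == f_hi`).
#' @param grid_points,padding Passed to [bhattacharyya()].
#' @param iteration Iteration tag stored on the map.
#' @return Object of class `vag_frm`.
#' @export
compute_frm <- function(set, pair, family, f_lo_axis, f_hi_axis = f_lo_axis,
                        allow_degenerate = TRUE, grid_points = 2048L,
                        padding = 4, iteration = 1L) {
  stopifnot(inherits(set, "vag_dataset"))
  pair <- as.character(as_vag_label(pair))
  if (length(pair) != 2L || pair[1L] == pair[2L]) {
    vag_stop("pair must be two distinct class labels")
  }
  labs <- dataset_labels(set)
  rec_a <- set$records[labs == pair[1L]]
  rec_b <- set$records[labs == pair[2L]]
  if (length(rec_a) < 2L || length(rec_b) < 2L) {
    vag_stop(sprintf("both classes need >= 2 signals (got %s=%d, %s=%d)",
                     pair[1L], length(rec_a), pair[2L], length(rec_b)))
  }
  ca <- family_cums(rec_a, family)
  cb <- family_cums(rec_b, family)
  nyq <- (ca$n_bins - 1L) * ca$bin_width
  if (any(f_lo_axis < 0) || any(f_hi_axis > nyq + ca$bin_width / 2)) {
    vag_stop(sprintf("axes must lie within [0, %g] Hz", nyq))
  }
  lo_bins <- sort(unique(pmin(ca$n_bins - 1L, pmax(0L, as.integer(round(f_lo_axis / ca$bin_width))))))
  hi_bins <- sort(unique(pmin(ca$n_bins - 1L, pmax(0L, as.integer(round(f_hi_axis / ca$bin_width))))))
  coef <- frm_core(ca$cums, cb$cums, lo_bins, hi_bins, ca$bin_width,
                   allow_degenerate, grid_points, padding)
  new_frm(family, pair, lo_bins, hi_bins, coef, ca$bin_width, ca$n_bins, iteration)
}

new_frm <- function(family, pair, lo_bins, hi_bins, coef, bin_width, n_bins,
                    iteration) {
  structure(
    list(family = as.integer(family), pair = pair,
         f_lo_axis = lo_bins * bin_width, f_hi_axis = hi_bins * bin_width,
         coefficients = coef, bin_width = bin_width, n_bins = n_bins,
         iteration = as.integer(iteration)),
    class = "vag_frm"
  )
}

#' @export
print.vag_frm <- function(x, ...) {
  nd <- sum(!is.na(x$coefficients))
  cat(sprintf(
    "<vag_frm> %s-%s family %d iter %d: %d x %d axes, %d defined cells\n",
    x$pair[1L], x$pair[2L], x$family, x$iteration,
    length(x$f_lo_axis), length(x$f_hi_axis), nd))
  if (nd > 0) {
    b <- best_cell(x)
    cat(sprintf("  best: %.4g-%.4g Hz, coefficient %.4f\n",
                b$f_lo, b$f_hi, b$coefficient))
  }
  invisible(x)
}

#' Best cell of a Frequency Range Map
#'
#' The defined cell with the minimal Bhattacharyya coefficient; exact ties
#' are broken in favour of the narrower band, then the smaller lower bound,
#' for determinism and parsimony.
#'
#' @param map A `vag_frm`.
#' @return List with `f_lo`, `f_hi` (Hz) and `coefficient`.
#' @export
best_cell <- function(map) {
  stopifnot(inherits(map, "vag_frm"))
  if (all(is.na(map$coefficients))) vag_stop("map has no defined cells")
  m <- min(map$coefficients, na.rm = TRUE)
  hits <- which(map$coefficients == m, arr.ind = TRUE)
  lo <- map$f_lo_axis[hits[, 1L]]
  hi <- map$f_hi_axis[hits[, 2L]]
  ord <- order(hi - lo, lo)
  k <- ord[1L]
  list(f_lo = lo[k], f_hi = hi[k], coefficient = m)
}

# shared engine behind iterative_search / build_feature_spec
iterative_core <- function(cums_a, cums_b, bin_width, n_bins, schedule,
                           pair, family, grid_points = 2048L, padding = 4,
                           verbose = FALSE) {
  n_iter <- length(schedule$steps_hz)
  maps <- vector("list", n_iter)
  best <- NULL
  for (it in seq_len(n_iter)) {
    step_bins <- max(1L, as.integer(round(schedule$steps_hz[it] / bin_width)))
    if (it == 1L) {
      lo_bins <- unique(c(seq(0L, n_bins - 1L, by = step_bins), n_bins - 1L))
      hi_bins <- lo_bins
      allow_deg <- FALSE
    } else {
      w_bins <- max(step_bins, as.integer(round(schedule$windows_hz[it] / bin_width)))
      bl <- as.integer(round(best$f_lo / bin_width))
      bh <- as.integer(round(best$f_hi / bin_width))
      lo_bins <- sort(unique(pmin(n_bins - 1L, pmax(0L,
                c(seq(bl - w_bins, bl + w_bins, by = step_bins), bl)))))
      hi_bins <- sort(unique(pmin(n_bins - 1L, pmax(0L,
                c(seq(bh - w_bins, bh + w_bins, by = step_bins), bh)))))
      allow_deg <- TRUE
    }
    coef <- frm_core(cums_a, cums_b, lo_bins, hi_bins, bin_width,
                     allow_degenerate = allow_deg,
                     grid_points = grid_points, padding = padding)
    maps[[it]] <- new_frm(family, pair, lo_bins, hi_bins, coef, bin_width,
                          n_bins, it)
    best <- best_cell(maps[[it]])
    if (verbose) {
      message(sprintf("  %s-%s family %d iter %d: best %.4g-%.4g Hz (Bcoef %.4f)",
                      pair[1L], pair[2L], family, it,
                      best$f_lo, best$f_hi, best$coefficient))
    }
  }
  list(best = best, maps = maps)
}

#' Three-iteration band search for one class pair and family
#'
#' Iteration one scans the full 0-Nyquist triangle of (lower, upper) band
#' bounds (strictly `f_lo < f_hi`); each later iteration re-grids a window
#' around the previous best band's bounds at a finer step, admitting
#' degenerate single-frequency bands, and always re-evaluates the previous
#' best cell so the best coefficient can never regress.
#'
#' @param set A [signal_set()].
#' @param pair Two class labels.
#' @param family Feature family 1-4.
#' @param schedule A [search_schedule()].
#' @param grid_points,padding Passed to [bhattacharyya()].
#' @param verbose Log each iteration's best band.
#' @return List with `best` (see [best_cell()]) and `maps` (one `vag_frm`
#'   per iteration).
#' @export
iterative_search <- function(set, pair, family, schedule = search_schedule(),
                             grid_points = 2048L, padding = 4,
                             verbose = FALSE) {
  stopifnot(inherits(set, "vag_dataset"), inherits(schedule, "vag_schedule"))
  pair <- as.character(as_vag_label(pair))
  labs <- dataset_labels(set)
  rec_a <- set$records[labs == pair[1L]]
  rec_b <- set$records[labs == pair[2L]]
  if (length(rec_a) < 2L || length(rec_b) < 2L) {
    vag_stop(sprintf("both classes need >= 2 signals for pair (%s, %s)",
                     pair[1L], pair[2L]))
  }
  ca <- family_cums(rec_a, family)
  cb <- family_cums(rec_b, family)
  iterative_core(ca$cums, cb$cums, ca$bin_width, ca$n_bins, schedule,
                 pair, family, grid_points, padding, verbose)
}

#' Build the ten-feature specification
#'
#' Runs [iterative_search()] for every one of the ten class pairs and every
#' one of the four feature families (forty searches; with the default
#' three-iteration schedule, 120 maps, forty of them final-iteration), then
#' selects per pair the family with the minimal final coefficient (ties go
#' to the lower family index). The result is the ten-element feature
#' specification: one (pair, family, frequency band) definition per pair,
#' lettered a-j.
#'
#' @param set A [signal_set()] containing all five classes.
#' @param schedule A [search_schedule()].
#' @param grid_points,padding Passed to [bhattacharyya()].
#' @param verbose Log per-iteration best bands.
#' @return List with `spec` (a `vag_feature_spec`) and `maps` (list of all
#'   `vag_frm` maps, named `<letter>_f<family>_i<iteration>`).
#' @export
build_feature_spec <- function(set, schedule = search_schedule(),
                               grid_points = 2048L, padding = 4,
                               verbose = FALSE) {
  stopifnot(inherits(set, "vag_dataset"))
  missing_cls <- names(set$counts)[set$counts == 0L]
  if (length(missing_cls) > 0) {
    vag_stop(sprintf("missing class(es): %s", paste(missing_cls, collapse = ", ")))
  }
  pairs <- class_pairs()
  labs <- dataset_labels(set)
  results <- vector("list", nrow(pairs) * 4L)
  maps <- list()
  ri <- 0L
  for (family in 1:4) {
    cums_by_class <- lapply(vag_labels(), function(cl) {
      family_cums(set$records[labs == cl], family)
    })
    names(cums_by_class) <- vag_labels()
    for (p in seq_len(nrow(pairs))) {
      ca <- cums_by_class[[pairs$class_a[p]]]
      cb <- cums_by_class[[pairs$class_b[p]]]
      res <- iterative_core(ca$cums, cb$cums, ca$bin_width, ca$n_bins,
                            schedule, c(pairs$class_a[p], pairs$class_b[p]),
                            family, grid_points, padding, verbose)
      ri <- ri + 1L
      results[[ri]] <- data.frame(
        letter = pairs$letter[p], class_a = pairs$class_a[p],
        class_b = pairs$class_b[p], family = family,
        f_lo_hz = res$best$f_lo, f_hi_hz = res$best$f_hi,
        coefficient = res$best$coefficient, stringsAsFactors = FALSE
      )
      for (it in seq_along(res$maps)) {
        maps[[sprintf("%s_f%d_i%d", pairs$letter[p], family, it)]] <- res$maps[[it]]
      }
    }
  }
  all_res <- do.call(rbind, results)
  defs <- do.call(rbind, lapply(split(all_res, all_res$letter), function(d) {
    d <- d[order(d$coefficient, d$family), ]
    d[1L, ]
  }))
  defs <- defs[order(defs$letter), ]
  rownames(defs) <- NULL
  sr <- set$sample_rate
  spec <- structure(
    list(
      definitions = defs,
      family_results = all_res[order(all_res$letter, all_res$family), ],
      schedule = schedule,
      sample_rate = sr,
      n_samples = length(set$records[[1L]]$samples),
      provenance = list(
        n_signals = length(set$records),
        class_counts = as.list(as.integer(set$counts)),
        created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
      )
    ),
    class = "vag_feature_spec"
  )
  names(spec$provenance$class_counts) <- names(set$counts)
  list(spec = spec, maps = maps)
}

#' @export
print.vag_feature_spec <- function(x, ...) {
  cat(sprintf("<vag_feature_spec> 10 pairwise band features (fs=%g Hz, N=%d)\n",
              x$sample_rate, x$n_samples))
  print(x$definitions, row.names = FALSE)
  invisible(x)
}

#' Serialise / deserialise a feature specification
#'
#' The specification is written as JSON: the ten definitions plus the
#' schedule and provenance block.
#'
#' @param spec A `vag_feature_spec`.
#' @param path JSON file path.
#' @return `path` (write) or the restored `vag_feature_spec` (read).
#' @export
write_feature_spec <- function(spec, path) {
  stopifnot(inherits(spec, "vag_feature_spec"))
  payload <- list(
    definitions = spec$definitions,
    schedule = list(steps_hz = spec$schedule$steps_hz,
                    windows_hz = spec$schedule$windows_hz),
    sample_rate = spec$sample_rate,
    n_samples = spec$n_samples,
    provenance = spec$provenance
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_feature_spec
#' @export
read_feature_spec <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  windows <- as.numeric(payload$schedule$windows_hz)
  windows[1L] <- Inf
  structure(
    list(
      definitions = as.data.frame(payload$definitions),
      family_results = NULL,
      schedule = search_schedule(as.numeric(payload$schedule$steps_hz), windows),
      sample_rate = payload$sample_rate,
      n_samples = payload$n_samples,
      provenance = payload$provenance
    ),
    class = "vag_feature_spec"
  )
}

#' Export / import a Frequency Range Map as TSV
#'
#' Rows are lower-bound frequencies, columns upper-bound frequencies;
#' undefined cells are blank. Header comment lines carry the pair, family
#' and iteration so the file round-trips. `export_frm()` can additionally
#' render a PNG heatmap with the best cell marked.
#'
#' @param map A `vag_frm`.
#' @param path Output TSV path.
#' @param heatmap Optional PNG path for a rendered map.
#' @return `path` (export) or the restored `vag_frm` (import).
#' @export
export_frm <- function(map, path, heatmap = NULL) {
  stopifnot(inherits(map, "vag_frm"))
  con <- file(path, "w")
  writeLines(c(
    sprintf("# pair: %s %s", map$pair[1L], map$pair[2L]),
    sprintf("# family: %d", map$family),
    sprintf("# iteration: %d", map$iteration),
    sprintf("# bin_width_hz: %.17g", map$bin_width),
    sprintf("# n_bins: %d", map$n_bins),
    paste(c("f_lo_hz", sprintf("%.17g", map$f_hi_axis)), collapse = "\t")
  ), con)
  for (i in seq_along(map$f_lo_axis)) {
    row <- ifelse(is.na(map$coefficients[i, ]), "",
                  sprintf("%.17g", map$coefficients[i, ]))
    writeLines(paste(c(sprintf("%.17g", map$f_lo_axis[i]), row),
                     collapse = "\t"), con)
  }
  close(con)
  if (!is.null(heatmap)) {
    b <- best_cell(map)
    grDevices::png(heatmap, width = 800, height = 700)
    graphics::image(
      map$f_lo_axis, map$f_hi_axis, map$coefficients,
      xlab = "lower frequency bound (Hz)", ylab = "upper frequency bound (Hz)",
      main = sprintf("FRM %s-%s, family %d, iteration %d",
                     map$pair[1L], map$pair[2L], map$family, map$iteration),
      col = grDevices::hcl.colors(64, "viridis", rev = TRUE)
    )
    graphics::points(b$f_lo, b$f_hi, pch = 1, cex = 3, lwd = 3, col = "red")
    grDevices::dev.off()
  }
  invisible(path)
}

#' @rdname export_frm
#' @export
import_frm <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  meta <- function(key) sub(sprintf("^# %s: ", key), "", hdr[grepl(paste0("^# ", key, ":"), hdr)])
  body <- lines[!startsWith(lines, "# ")]
  head_fields <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  f_hi_axis <- as.numeric(head_fields[-1L])
  rows <- strsplit(body[-1L], "\t", fixed = TRUE)
  f_lo_axis <- vapply(rows, function(r) as.numeric(r[1L]), numeric(1))
  coef <- matrix(NA_real_, length(f_lo_axis), length(f_hi_axis))
  for (i in seq_along(rows)) {
    vals <- rows[[i]][-1L]
    vals <- c(vals, rep("", length(f_hi_axis) - length(vals)))
    coef[i, ] <- suppressWarnings(as.numeric(ifelse(vals == "", NA, vals)))
  }
  bw <- as.numeric(meta("bin_width_hz"))
  structure(
    list(family = as.integer(meta("family")),
         pair = strsplit(meta("pair"), " ")[[1L]],
         f_lo_axis = f_lo_axis, f_hi_axis = f_hi_axis, coefficients = coef,
         bin_width = bw, n_bins = as.integer(meta("n_bins")),
         iteration = as.integer(meta("iteration"))),
    class = "vag_frm"
  )
}
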