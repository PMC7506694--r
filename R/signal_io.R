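#' Construct a single VAG signal record
#'
#' A signal record holds one accelerometer time series in arbitrary amplitude
#' units, its sampling rate and (optionally) its condition label.
#'
#' @param id Character identifier, unique within a dataset.
#' @param samples Numeric vector of accelerometer samples; finite, length >= 2.
#' @param sample_rate Sampling rate in Hz, > 0.
#' @param label Condition label (see [vag_labels()]) or `NA` for unlabeled
#'   prediction inputs.
#' @return An object of class `vag_signal`.
#' @export
#' @examples
#' s <- signal_record("demo", sin(2 * pi * 100 * (0:999) / 1e4), 1e4, "ctrl")
#' s
signal_record <- function(id, samples, sample_rate, label = NA_character_) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) {
    vag_stop(sprintf("signal '%s': length >= 2 required (got %d)", id, length(samples)))
  }
  if (!all(is.finite(samples))) {
    vag_stop(sprintf("signal '%s': samples must be finite (no NaN/Inf)", id))
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || !is.finite(sample_rate) ||
      sample_rate <= 0) {
    vag_stop(sprintf("signal '%s': sample_rate must be a single positive number", id))
  }
  if (!is.na(label)) label <- as.character(as_vag_label(label))
  structure(
    list(id = as.character(id), samples = samples,
         sample_rate = as.numeric(sample_rate), label = label),
    class = "vag_signal"
  )
}

#' @export
print.vag_signal <- function(x, ...) {
  cat(sprintf(
    "<vag_signal> id=%s  n=%d  fs=%g Hz  dur=%.3g s  label=%s\n",
    x$id, length(x$samples), x$sample_rate,
    length(x$samples) / x$sample_rate,
    if (is.na(x$label)) "<none>" else x$label
  ))
  invisible(x)
}

#' Construct a labeled signal set
#'
#' Bundles signal records into a dataset: all records must share one sampling
#' rate, every record must be labeled, and every represented class must have
#' at least two records (the kernel density estimates downstream need two or
#' more points per class).
#'
#' @param records List of [signal_record()] objects.
#' @return An object of class `vag_dataset` with elements `records` (named by
#'   id) and `counts` (per-class tally over the canonical labels).
#' @export
signal_set <- function(records) {
  if (length(records) == 0L) vag_stop("no records")
  ids <- vapply(records, function(r) r$id, character(1))
  if (anyDuplicated(ids)) {
    vag_stop(sprintf("duplicate signal id(s): %s",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  rates <- vapply(records, function(r) r$sample_rate, numeric(1))
  if (length(unique(rates)) != 1L) {
    vag_stop(sprintf("mixed sample rates in dataset: %s Hz",
                     paste(sort(unique(rates)), collapse = ", ")))
  }
  labs <- vapply(records, function(r) r$label, character(1))
  if (anyNA(labs)) {
    vag_stop("all records in a labeled set must carry a label")
  }
  labs <- as_vag_label(labs)
  counts <- table(labs)
  thin <- names(counts)[counts == 1L]
  if (length(thin) > 0) {
    vag_stop(sprintf("class(es) with a single record: %s (need >= 2 per class)",
                     paste(thin, collapse = ", ")))
  }
  names(records) <- ids
  structure(
    list(records = records, counts = counts, sample_rate = rates[[1L]]),
    class = "vag_dataset"
  )
}

#' @export
print.vag_dataset <- function(x, ...) {
  cat(sprintf("<vag_dataset> %d signals @ %g Hz\n", length(x$records), x$sample_rate))
  cnt <- x$counts[x$counts > 0]
  cat("  ", paste(sprintf("%s=%d", names(cnt), cnt), collapse = "  "), "\n", sep = "")
  invisible(x)
}

#' @export
length.vag_dataset <- function(x) length(x$records)

# labels of a dataset as a factor in canonical level order
dataset_labels <- function(set) {
  as_vag_label(vapply(set$records, function(r) r$label, character(1)))
}

#' Read one signal file
#'
#' CSV signals are one sample per line with no header (the sampling rate
#' comes from the manifest); WAV signals must be mono 16-bit PCM, the
#' sampling rate is taken from the header and samples are rescaled to
#' \[-1, 1\] (integer PCM ranges are container artifacts, not physics).
#'
#' @param path Path to the signal file.
#' @param format `"csv"` or `"wav"`; default guessed from the file extension.
#' @param sample_rate Sampling rate in Hz; required for CSV, ignored for WAV.
#' @param id Record identifier; defaults to the file stem.
#' @param label Optional condition label.
#' @return A [signal_record()].
#' @export
read_signal <- function(path, format = c("auto", "csv", "wav"),
                        sample_rate = NULL, id = NULL, label = NA_character_) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("csv", "wav")) {
      vag_stop(sprintf("cannot infer format of '%s'; pass format=", path))
    }
    format <- ext
  }
  if (!file.exists(path)) {
    vag_stop(sprintf("signal file not found: '%s'", path), class = "vag_io_error")
  }
  id <- id %||% tools::file_path_sans_ext(basename(path))
  if (format == "csv") {
    if (is.null(sample_rate)) {
      vag_stop(sprintf("CSV signal '%s' needs an explicit sample_rate", path))
    }
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    x <- suppressWarnings(as.numeric(lines))
    if (anyNA(x)) {
      bad <- which(is.na(x))[1L]
      vag_stop(sprintf("'%s': non-numeric value at line %d: '%s'",
                       path, bad, lines[bad]))
    }
    signal_record(id, x, sample_rate, label)
  } else {
    w <- read_wav_pcm16(path)
    signal_record(id, w$samples, w$sample_rate, label)
  }
}

#' Read a dataset manifest
#'
#' The manifest is a CSV with header `id,path,label,sample_rate_hz`, one row
#' per signal; relative signal paths are resolved against the manifest's own
#' directory.
#'
#' @param path Path to the manifest CSV.
#' @param require_labels If `FALSE`, rows with an empty label are admitted as
#'   unlabeled prediction inputs and a plain list of records is returned
#'   instead of a `vag_dataset`.
#' @return A [signal_set()] (or a list of records when
#'   `require_labels = FALSE` and some labels are missing).
#' @export
read_manifest <- function(path, require_labels = TRUE) {
  if (!file.exists(path)) {
    vag_stop(sprintf("manifest not found: '%s'", path), class = "vag_io_error")
  }
  man <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("id", "path", "label", "sample_rate_hz")
  missing_cols <- setdiff(need, names(man))
  if (length(missing_cols) > 0) {
    vag_stop(sprintf("manifest '%s' lacks column(s): %s",
                     path, paste(missing_cols, collapse = ", ")))
  }
  if (nrow(man) == 0L) vag_stop("no records")
  base_dir <- dirname(normalizePath(path))
  rates <- suppressWarnings(as.numeric(man$sample_rate_hz))
  if (anyNA(rates)) {
    vag_stop(sprintf("manifest row %d: non-numeric sample_rate_hz",
                     which(is.na(rates))[1L]))
  }
  records <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    lab <- man$label[i]
    if (is.na(lab) || !nzchar(lab)) {
      if (require_labels) vag_stop(sprintf("manifest row %d (id '%s'): missing label",
                                           i, man$id[i]))
      lab <- NA_character_
    } else if (!lab %in% vag_labels()) {
      vag_stop(sprintf("manifest row %d (id '%s'): unknown label '%s'",
                       i, man$id[i], lab))
    }
    p <- man$path[i]
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base_dir, p)
    rec <- read_signal(p, sample_rate = rates[i], id = man$id[i], label = lab)
    if (rec$sample_rate != rates[i]) {
      vag_stop(sprintf(
        "manifest row %d (id '%s'): sample_rate_hz %g disagrees with signal file (%g Hz)",
        i, man$id[i], rates[i], rec$sample_rate))
    }
    records[[i]] <- rec
  }
  if (anyNA(vapply(records, function(r) r$label, character(1)))) {
    return(records)
  }
  signal_set(records)
}

#' Write a dataset to disk
#'
#' Each record is written as a one-column CSV (`<id>.csv`, full decimal
#' precision so that a read/write round trip is lossless) next to a manifest
#' `manifest.csv`. Returns the manifest path.
#'
#' @param set A [signal_set()].
#' @param directory Output directory (created if absent).
#' @param overwrite Overwrite existing signal files / manifest.
#' @return Path to the written manifest, invisibly usable by [read_manifest()].
#' @export
write_dataset <- function(set, directory, overwrite = FALSE) {
  stopifnot(inherits(set, "vag_dataset"))
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  manifest_path <- file.path(directory, "manifest.csv")
  files <- file.path(directory, paste0(names(set$records), ".csv"))
  clash <- c(files[file.exists(files)], manifest_path[file.exists(manifest_path)])
  if (length(clash) > 0 && !overwrite) {
    vag_stop(sprintf("refusing to overwrite existing file(s): %s (set overwrite = TRUE)",
                     paste(basename(clash), collapse = ", ")))
  }
  for (i in seq_along(set$records)) {
    rec <- set$records[[i]]
    # %.17g round-trips IEEE doubles exactly through decimal text
    writeLines(sprintf("%.17g", rec$samples), files[i])
  }
  man <- data.frame(
    id = names(set$records),
    path = basename(files),
    label = vapply(set$records, function(r) r$label, character(1)),
    sample_rate_hz = vapply(set$records, function(r) r$sample_rate, numeric(1)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(man, manifest_path, row.names = FALSE, quote = FALSE)
  invisible(manifest_path)
}
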