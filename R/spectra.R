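#' One-sided magnitude spectrum of a VAG signal
#'
#' The discrete Fourier transform of the whole, un-windowed, un-segmented
#' signal, reduced to the one-sided bins 0..floor(N/2). No conjugate-symmetry
#' factor of two is applied: it is a constant that cancels both in
#' Bhattacharyya comparisons and in argmin band selection.
#'
#' @param signal A [signal_record()].
#' @return An object of class `vag_spectrum` with fields `frequencies`
#'   (0, df, ..., Nyquist), `values` (nonnegative magnitudes), `bin_width`
#'   (= sample_rate / N), `family`, `source_id`, `sample_rate`, `n_samples`.
#' @export
#' @examples
#' fs <- 1000
#' s <- signal_record("sine", sin(2 * pi * 100 * (0:999) / fs), fs)
#' sp <- magnitude_spectrum(s)
#' sp$frequencies[which.max(sp$values)]  # 100 Hz
magnitude_spectrum <- function(signal) {
  stopifnot(inherits(signal, "vag_signal"))
  x <- signal$samples
  if (!all(is.finite(x))) vag_stop("signal contains non-finite samples")
  n <- length(x)
  k <- n %/% 2L
  mag <- Mod(stats::fft(x))[seq_len(k + 1L)]
  bin_width <- signal$sample_rate / n
  structure(
    list(
      frequencies = (0:k) * bin_width,
      values = mag,
      bin_width = bin_width,
      family = 1L,
      source_id = signal$id,
      sample_rate = signal$sample_rate,
      n_samples = n
    ),
    class = "vag_spectrum"
  )
}

#' @export
print.vag_spectrum <- function(x, ...) {
  cat(sprintf("<vag_spectrum> family %d  %d bins  df=%.5g Hz  source=%s\n",
              x$family, length(x$values), x$bin_width, x$source_id))
  invisible(x)
}

#' Family-transformed spectrum
#'
#' The four spectral feature families applied bin-wise to the one-sided
#' magnitude spectrum |X(f)|:
#' family 1 = |X(f)| (the spectrum itself), family 2 = 2 pi f |X(f)| (the
#' spectrum of the signal's derivative, obtained by frequency-domain
#' multiplication, never finite differencing), family 3 = |X(f)|^2 (energy),
#' family 4 = (2 pi f)^2 |X(f)|^2 (energy of the derivative).
#'
#' @param signal A [signal_record()].
#' @param family Integer 1-4.
#' @return A `vag_spectrum` with family-transformed `values`.
#' @export
family_spectrum <- function(signal, family) {
  family <- as.integer(family)
  if (length(family) != 1L || is.na(family) || !family %in% 1:4) {
    vag_stop("family must be one of 1, 2, 3, 4")
  }
  sp <- magnitude_spectrum(signal)
  w <- 2 * pi * sp$frequencies
  sp$values <- switch(family,
    sp$values,
    w * sp$values,
    sp$values^2,
    (w * sp$values)^2
  )
  sp$family <- family
  sp
}

#' Snap a frequency range to spectrum bins
#'
#' Each bound is rounded to its nearest DFT bin and clamped to the valid
#' index range. Indices are zero-based (bin 0 is DC), matching the
#' frequency grid `i * bin_width`.
#'
#' @param f_lo,f_hi Band bounds in Hz, `0 <= f_lo <= f_hi <= Nyquist`.
#' @param bin_width Bin width in Hz.
#' @param n_bins Number of one-sided bins.
#' @return Integer vector `c(i_lo, i_hi)`, zero-based, `i_lo <= i_hi`.
#' @export
snap_range_to_bins <- function(f_lo, f_hi, bin_width, n_bins) {
  if (f_lo > f_hi) vag_stop("f_lo must be <= f_hi")
  i_lo <- max(0L, min(n_bins - 1L, as.integer(round(f_lo / bin_width))))
  i_hi <- max(0L, min(n_bins - 1L, as.integer(round(f_hi / bin_width))))
  c(i_lo, max(i_lo, i_hi))
}

#' Band-summed spectral feature
#'
#' The normalised sum of family-transformed spectrum values over a frequency
#' band: `1/(f_hi - f_lo) * sum over bins in [f_lo, f_hi]`, both endpoint
#' bins included. The 1/(f_hi - f_lo) factor makes the feature reflect
#' spectral shape rather than band width. A band that snaps to a single bin
#' returns that bin's value (normalisation factor 1): single-frequency
#' optima are first-class citizens of the band search.
#'
#' @param spectrum A `vag_spectrum`.
#' @param f_lo,f_hi Band bounds in Hz.
#' @return Scalar feature value.
#' @export
band_feature <- function(spectrum, f_lo, f_hi) {
  stopifnot(inherits(spectrum, "vag_spectrum"))
  nyquist <- spectrum$frequencies[length(spectrum$frequencies)]
  if (f_lo < 0 || f_hi > nyquist + spectrum$bin_width / 2) {
    vag_stop(sprintf("range [%g, %g] Hz outside [0, %g] Hz", f_lo, f_hi, nyquist))
  }
  idx <- snap_range_to_bins(f_lo, f_hi, spectrum$bin_width, length(spectrum$values))
  if (idx[1L] == idx[2L]) {
    return(spectrum$values[idx[1L] + 1L])
  }
  width_hz <- (idx[2L] - idx[1L]) * spectrum$bin_width
  sum(spectrum$values[(idx[1L] + 1L):(idx[2L] + 1L)]) / width_hz
}

#' Classical comparator features P1, P2, F470, F780
#'
#' The four spectral descriptors used as the state-of-the-art baseline:
#' P1 and P2 are total spectral power over 50-250 Hz and 250-450 Hz from a
#' short-time Fourier transform (150-sample Hanning-windowed segments,
#' 100-sample overlap), summed across all segments; F470 and F780 are the
#' full-signal periodogram power density at the bins nearest 470 Hz and
#' 780 Hz.
#'
#' @param signal A [signal_record()] with at least 150 samples.
#' @return Named numeric vector `c(P1, P2, F470, F780)`.
#' @export
baseline_features <- function(signal) {
  stopifnot(inherits(signal, "vag_signal"))
  x <- signal$samples
  fs <- signal$sample_rate
  seg_len <- 150L
  hop <- 50L  # 100-sample overlap
  if (length(x) < seg_len) {
    vag_stop(sprintf("signal '%s' shorter than one STFT segment (%d < %d samples)",
                     signal$id, length(x), seg_len))
  }
  win <- 0.5 * (1 - cos(2 * pi * (0:(seg_len - 1L)) / (seg_len - 1L)))
  starts <- seq(1L, length(x) - seg_len + 1L, by = hop)
  k <- seg_len %/% 2L
  seg_freq <- (0:k) * fs / seg_len
  band_power <- c(0, 0)
  in_p1 <- seg_freq >= 50 & seg_freq <= 250
  in_p2 <- seg_freq >= 250 & seg_freq <= 450
  for (s in starts) {
    pw <- Mod(stats::fft(x[s:(s + seg_len - 1L)] * win))[seq_len(k + 1L)]^2
    band_power <- band_power + c(sum(pw[in_p1]), sum(pw[in_p2]))
  }
  # full-signal periodogram for the two single-frequency descriptors
  n <- length(x)
  psd <- Mod(stats::fft(x))[seq_len(n %/% 2L + 1L)]^2 / n
  freq <- (0:(n %/% 2L)) * fs / n
  c(
    P1 = band_power[1L],
    P2 = band_power[2L],
    F470 = psd[which.min(abs(freq - 470))],
    F780 = psd[which.min(abs(freq - 780))]
  )
}

# 4-column baseline matrix for a dataset (rows in record order)
baseline_feature_matrix <- function(set) {
  stopifnot(inherits(set, "vag_dataset"))
  m <- t(vapply(set$records, baseline_features, numeric(4)))
  rownames(m) <- names(set$records)
  m
}

#' Export a spectrum as two-column CSV
#'
#' @param spectrum A `vag_spectrum`.
#' @param path Output CSV path (columns `frequency_hz`, `value`).
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "vag_spectrum"))
  utils::write.csv(
    data.frame(frequency_hz = spectrum$frequencies, value = spectrum$values),
    path, row.names = FALSE
  )
  invisible(path)
}
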