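#' Brick-wall FFT band-pass filter
#'
#' Forward FFT, zeroing of every coefficient whose frequency lies outside the
#' half-open band `[f_low, f_high)`, inverse FFT. The half-open convention
#' makes the six classical bands partition the spectrum without double
#' counting bins at touching edges.
#'
#' @param x Numeric time series (length >= 2).
#' @param f_low,f_high Band edges in Hz, `0 < f_low < f_high <= fs/2`.
#' @param fs Sampling frequency in Hz.
#' @return The band-filtered series (real, same length).
#' @export
bandpass_fft <- function(x, f_low, f_high, fs) {
  n <- length(x)
  if (n < 2) abort("series must have length >= 2")
  if (f_high > fs / 2) {
    abort(sprintf("band edge %.6g Hz exceeds the Nyquist frequency %.6g Hz",
                  f_high, fs / 2))
  }
  if (f_low <= 0 || f_high <= f_low) abort("need 0 < f_low < f_high")
  keep <- band_bins(n, fs, f_low, f_high)
  X <- stats::fft(x)
  X[!keep] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

# Logical mask over FFT bins of an n-sample series whose absolute frequency
# lies in [f_low, f_high).
band_bins <- function(n, fs, f_low, f_high) {
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n
  f >= f_low & f < f_high
}

#' Band-specific relative power
#'
#' Fraction of spectral power in one frequency band relative to the total
#' analysed range (default 0.5--48 Hz, the union of the six classical bands).
#' The series is demeaned before the FFT.
#'
#' @param x Numeric time series.
#' @param f_low,f_high Band edges in Hz (half-open band, low edge inclusive).
#' @param fs Sampling frequency in Hz.
#' @param total_range Length-2 denominator range in Hz.
#' @return A fraction in \[0, 1\].
#' @export
relative_power <- function(x, f_low, f_high, fs, total_range = c(0.5, 48)) {
  if (!all(is.finite(x))) abort("series contains non-finite values")
  n <- length(x)
  P <- Mod(stats::fft(x - mean(x)))^2
  den <- sum(P[band_bins(n, fs, total_range[1], total_range[2])])
  if (den <= 0) abort("silent channel: zero total power in the analysed range")
  num <- sum(P[band_bins(n, fs, f_low, f_high)])
  num / den
}

#' Relative power per region, epoch and band
#'
#' @param series Array of virtual-electrode time series,
#'   regions x samples x epochs (broadband).
#' @param bands Band definitions (see [classical_bands()]).
#' @param fs Sampling frequency in Hz.
#' @param total_range Denominator range in Hz.
#' @return A tibble with columns `roi`, `epoch`, `band`, `value`.
#' @export
relative_power_table <- function(series, bands = classical_bands(), fs,
                                 total_range = c(0.5, 48)) {
  validate_bands(bands, fs)
  stopifnot(length(dim(series)) == 3)
  n_roi <- dim(series)[1]; n <- dim(series)[2]; n_ep <- dim(series)[3]
  tot_mask <- band_bins(n, fs, total_range[1], total_range[2])
  masks <- lapply(seq_len(nrow(bands)), function(b) {
    band_bins(n, fs, bands$f_low[b], bands$f_high[b])
  })
  out <- vector("list", n_roi * n_ep)
  idx <- 1
  for (e in seq_len(n_ep)) {
    x <- t(series[, , e, drop = TRUE])
    if (n_roi == 1) x <- matrix(series[1, , e], ncol = 1)
    x <- sweep(x, 2, colMeans(x))
    P <- Mod(stats::mvfft(x))^2
    den <- colSums(P[tot_mask, , drop = FALSE])
    if (any(den <= 0)) abort("silent channel: zero total power")
    for (r in seq_len(n_roi)) {
      out[[idx]] <- tibble::tibble(
        roi = r, epoch = e, band = bands$band,
        value = vapply(masks, function(m) sum(P[m, r]) / den[r], numeric(1)))
      idx <- idx + 1
    }
  }
  dplyr::bind_rows(out)
}
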