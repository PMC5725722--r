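#' The six classical MEG frequency bands
#'
#' Delta (0.5--4 Hz), theta (4--8 Hz), lower alpha (8--10 Hz), upper alpha
#' (10--13 Hz), beta (13--30 Hz) and gamma (30--48 Hz). Band intervals are
#' treated as half-open, `[f_low, f_high)`, so the six bands tile
#' 0.5--48 Hz without double counting spectral bins at the touching edges.
#'
#' @return A tibble with columns `band`, `f_low`, `f_high` (Hz).
#' @export
#' @examples
#' classical_bands()
classical_bands <- function() {
  tibble::tibble(
    band   = c("delta", "theta", "alpha1", "alpha2", "beta", "gamma"),
    f_low  = c(0.5, 4, 8, 10, 13, 30),
    f_high = c(4, 8, 10, 13, 30, 48)
  )
}

validate_bands <- function(bands, fs = NULL) {
  if (!is.data.frame(bands) || !all(c("band", "f_low", "f_high") %in% names(bands))) {
    abort("`bands` must be a data frame with columns band, f_low, f_high")
  }
  if (nrow(bands) < 1) abort("at least one band must be defined")
  if (anyDuplicated(bands$band)) abort("duplicated band names")
  if (any(bands$f_low <= 0) || any(bands$f_high <= bands$f_low)) {
    abort("bands must satisfy 0 < f_low < f_high")
  }
  if (!is.null(fs) && any(bands$f_high > fs / 2)) {
    bad <- bands$band[bands$f_high > fs / 2][1]
    abort(sprintf("band '%s' exceeds the Nyquist frequency %.6g Hz", bad, fs / 2))
  }
  invisible(tibble::as_tibble(bands))
}
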