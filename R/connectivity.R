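#' Instantaneous phase via the analytic signal
#'
#' FFT-based Hilbert transform: negative-frequency components are zeroed,
#' positive ones doubled, and the phase of the resulting analytic signal is
#' returned, wrapped to (-pi, pi].
#'
#' @param x Band-limited numeric series, length >= 16.
#' @return Phase series in radians.
#' @export
instantaneous_phase <- function(x) {
  n <- length(x)
  if (n < 16) abort("series too short for phase estimation (need >= 16 samples)")
  if (stats::sd(x) == 0) abort("no oscillation: constant series")
  Arg(analytic_signal_matrix(matrix(x, ncol = 1)))[, 1]
}

# Analytic signal of each column of a real matrix.
analytic_signal_matrix <- function(x) {
  n <- nrow(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  stats::mvfft(stats::mvfft(x) * h, inverse = TRUE) / n
}

#' Phase lag index
#'
#' `PLI = |< sign(sin(dphi(t_k))) >|`: the absolute mean sign of the sine of
#' the phase-difference series. Exactly zero-lag samples (`sin(dphi) = 0`)
#' contribute nothing, which is what makes the index insensitive to
#' volume-conduction (zero-lag) coupling.
#'
#' @param dphi Phase differences in radians (any real values; the index is
#'   invariant to adding multiples of 2*pi).
#' @return A value in \[0, 1\].
#' @export
pli <- function(dphi) {
  if (length(dphi) < 1) abort("empty phase-difference series")
  abs(mean(sign(sin(dphi))))
}

#' PLI adjacency matrix of regional time series
#'
#' Pairwise phase lag index between every pair of regions, from the
#' instantaneous phases of band-limited series of one epoch.
#'
#' @param x Samples x regions matrix of band-limited series.
#' @return Symmetric regions x regions matrix with zero diagonal,
#'   entries in \[0, 1\].
#' @export
pli_adjacency <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) abort("need at least 2 regions")
  phases <- Arg(analytic_signal_matrix(x))
  A <- pli_matrix_cpp(phases)
  dimnames(A) <- NULL
  A
}
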