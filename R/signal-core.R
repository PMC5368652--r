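#' Convert a signal to a z-score
#'
#' Subtracts the mean and divides by the standard deviation, the first step
#' applied to every raw LFP trace before spectral or coupling analysis.
#'
#' @param x a [prr_signal()].
#' @return a `prr_signal` with mean 0 and SD 1.
#' @export
zscore_signal <- function(x) {
  stopifnot(inherits(x, "prr_signal"))
  if (length(x$samples) < 2L)
    stop("signal too short to z-score (need >= 2 samples)", call. = FALSE)
  s <- stats::sd(x$samples)
  if (s == 0)
    stop("degenerate input: constant signal has zero standard deviation",
         call. = FALSE)
  x$samples <- (x$samples - mean(x$samples)) / s
  x
}

#' Zero-phase Butterworth band-pass filter
#'
#' 2nd-order Butterworth band-pass applied in forward and reverse direction
#' (filtfilt), so the output has zero net phase shift. All band-limited
#' phase/amplitude extraction in the package goes through this filter.
#'
#' @param x a [prr_signal()].
#' @param low_hz,high_hz band edges in Hz; `0 < low_hz < high_hz < fs/2`.
#' @param order filter order (default 2).
#' @return a filtered `prr_signal` with `band_hz` recorded.
#' @export
bandpass <- function(x, low_hz, high_hz, order = 2) {
  stopifnot(inherits(x, "prr_signal"))
  nyq <- x$fs / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop(sprintf("band [%g, %g] Hz must satisfy 0 < low < high < fs/2 = %g",
                 low_hz, high_hz, nyq), call. = FALSE)
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  y <- signal::filtfilt(bf, x$samples)
  prr_signal(y, x$fs, label = x$label, t0 = x$t0, band_hz = c(low_hz, high_hz))
}

# FFT-based analytic signal (half-spectrum method).
analytic_signal <- function(v) {
  n <- length(v)
  if (all(v == 0)) stop("degenerate input: all-zero signal", call. = FALSE)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(v) * h, inverse = TRUE) / n
}

#' Instantaneous phase of a band-limited signal
#'
#' Phase component of the Hilbert (analytic-signal) transform. For a cosine
#' the phase is 0 at waveform peaks and +/- pi at troughs — the convention
#' used by every coupling analysis in this package.
#'
#' @param x a band-limited [prr_signal()] (output of [bandpass()]).
#' @return a [prr_phase_series()] of equal length.
#' @export
analytic_phase <- function(x) {
  stopifnot(inherits(x, "prr_signal"))
  a <- analytic_signal(x$samples)
  prr_phase_series(Arg(a), x$fs, band_hz = x$band_hz, t0 = x$t0)
}

#' Instantaneous amplitude envelope of a band-limited signal
#'
#' Modulus of the analytic signal.
#'
#' @param x a band-limited [prr_signal()] (output of [bandpass()]).
#' @return a [prr_amplitude_series()] of equal length.
#' @export
analytic_amplitude <- function(x) {
  stopifnot(inherits(x, "prr_signal"))
  a <- analytic_signal(x$samples)
  prr_amplitude_series(Mod(a), x$fs, band_hz = x$band_hz, t0 = x$t0)
}

#' Cut a per-sample series into per-epoch segments
#'
#' Filtering and phase extraction are always applied to the full trace first;
#' epoch masking then cuts the result into contiguous segments. Sample `i`
#' (time `t0 + (i-1)/fs`) belongs to an epoch `[a, b)` iff `a <= t < b`.
#'
#' @param x a `prr_signal`, `prr_phase` or `prr_amplitude` series.
#' @param epochs a [prr_epochs()] set; every epoch must lie inside the series.
#' @param trim_s seconds to discard from the start and end of the recording
#'   before masking (suppresses filter edge transients); epochs are clipped
#'   accordingly. Default 0.
#' @return a list of series segments (same class as `x`, `t0` updated).
#' @export
mask_epochs <- function(x, epochs, trim_s = 0) {
  v <- series_values(x)
  n <- length(v)
  dur <- n / x$fs
  if (nrow(epochs) && (any(epochs$start_s < x$t0 - 1e-9) ||
                       any(epochs$end_s > x$t0 + dur + 1e-9)))
    stop("epoch exceeds the recording span", call. = FALSE)
  lo <- x$t0 + trim_s
  hi <- x$t0 + dur - trim_s
  out <- list()
  for (k in seq_len(nrow(epochs))) {
    a <- max(epochs$start_s[k], lo)
    b <- min(epochs$end_s[k], hi)
    if (b <= a) next
    i0 <- ceiling((a - x$t0) * x$fs - 1e-9) + 1L
    i1 <- ceiling((b - x$t0) * x$fs - 1e-9)   # last sample with t < b
    if (i1 < i0) next
    seg <- series_replace(x, v[i0:i1])
    seg$t0 <- x$t0 + (i0 - 1L) / x$fs
    out[[length(out) + 1L]] <- seg
  }
  out
}

# Concatenate the values of masked segments into one numeric vector.
masked_values <- function(x, epochs = NULL, trim_s = 0) {
  if (is.null(epochs)) return(series_values(x))
  segs <- mask_epochs(x, epochs, trim_s = trim_s)
  if (!length(segs)) return(numeric())
  unlist(lapply(segs, series_values), use.names = FALSE)
}

#' Index of the 20-degree phase bin of each phase value
#'
#' The package-wide phase binning: 18 bins of 20 degrees spanning
#' `[-pi, pi)`, bin edges at `-pi + k * pi/9`.
#'
#' @param phi numeric phases (radians, any range; wrapped internally).
#' @param n_bins number of bins (default 18).
#' @return integer bin indices in `1..n_bins`.
#' @export
phase_bin <- function(phi, n_bins = 18L) {
  phi <- wrap_phase(phi)
  b <- floor((phi + pi) / (2 * pi / n_bins)) + 1L
  b[b > n_bins] <- n_bins
  as.integer(b)
}

#' Centers of the package-wide phase bins
#' @param n_bins number of bins (default 18).
#' @return numeric vector of bin-center phases in radians.
#' @export
phase_bin_centers <- function(n_bins = 18L) {
  -pi + (seq_len(n_bins) - 0.5) * 2 * pi / n_bins
}
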