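#' Uniformly sampled time series
#'
#' Container for a continuous recording (LFP, nasal respiration, accelerometer):
#' a numeric sample vector plus its sampling rate, a free-text label and the
#' start time of the first sample.
#'
#' @param samples numeric vector of samples; must be finite.
#' @param fs sampling rate in Hz (> 0).
#' @param label free-text channel label.
#' @param t0 time of the first sample in seconds.
#' @param band_hz optional length-2 numeric, the band (Hz) of the filter that
#'   produced this trace (set automatically by [bandpass()]).
#' @return An object of class `prr_signal`.
#' @examples
#' s <- prr_signal(sin(2 * pi * 3.5 * seq(0, 1, by = 1e-3)), fs = 1000, label = "lfp")
#' s
#' @export
prr_signal <- function(samples, fs, label = "", t0 = 0, band_hz = NULL) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("`samples` must be finite (no NA/NaN/Inf)", call. = FALSE)
  structure(
    list(samples = samples, fs = fs, label = as.character(label)[1L],
         t0 = as.numeric(t0)[1L], band_hz = band_hz),
    class = "prr_signal"
  )
}

#' @export
print.prr_signal <- function(x, ...) {
  cat(sprintf("<prr_signal> %s: %d samples @ %g Hz (%.3f s), t0 = %g s%s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$samples), x$fs, length(x$samples) / x$fs, x$t0,
              if (!is.null(x$band_hz))
                sprintf(", band %g-%g Hz", x$band_hz[1], x$band_hz[2]) else ""))
  invisible(x)
}

#' Duration of a signal in seconds
#' @param x a `prr_signal`, `prr_phase` or `prr_amplitude` object.
#' @return duration in seconds (n_samples / fs).
#' @export
signal_duration <- function(x) length(series_values(x)) / x$fs

# Internal accessor: the sample vector of any per-sample series object.
series_values <- function(x) {
  if (inherits(x, "prr_signal")) return(x$samples)
  if (inherits(x, "prr_phase")) return(x$phase)
  if (inherits(x, "prr_amplitude")) return(x$envelope)
  stop("not a per-sample series object", call. = FALSE)
}

series_replace <- function(x, v) {
  if (inherits(x, "prr_signal")) x$samples <- v
  else if (inherits(x, "prr_phase")) x$phase <- v
  else if (inherits(x, "prr_amplitude")) x$envelope <- v
  x
}

#' Set of non-overlapping analysis epochs
#'
#' Half-open time intervals `[start_s, end_s)` in seconds selecting analysis
#' windows (typically immobility). Intervals are sorted and must not overlap.
#'
#' @param start_s,end_s numeric vectors of equal length; each `start_s[i] <
#'   end_s[i]`.
#' @return An object of class `prr_epochs`: a two-column data.frame
#'   (`start_s`, `end_s`).
#' @examples
#' prr_epochs(c(0, 20), c(10, 30))
#' @export
prr_epochs <- function(start_s = numeric(), end_s = numeric()) {
  start_s <- as.numeric(start_s); end_s <- as.numeric(end_s)
  if (length(start_s) != length(end_s))
    stop("`start_s` and `end_s` must have equal length", call. = FALSE)
  if (length(start_s)) {
    o <- order(start_s)
    start_s <- start_s[o]; end_s <- end_s[o]
    if (any(start_s >= end_s))
      stop("each epoch must satisfy start < end", call. = FALSE)
    if (any(start_s[-1L] < end_s[-length(end_s)]))
      stop("epochs must not overlap", call. = FALSE)
  }
  structure(data.frame(start_s = start_s, end_s = end_s),
            class = c("prr_epochs", "data.frame"))
}

#' @export
print.prr_epochs <- function(x, ...) {
  cat(sprintf("<prr_epochs> %d epoch(s), total %.3f s\n",
              nrow(x), epoch_duration(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

#' Total duration covered by an epoch set
#' @param epochs a `prr_epochs` object.
#' @return summed interval length in seconds.
#' @export
epoch_duration <- function(epochs) {
  if (!nrow(epochs)) return(0)
  sum(epochs$end_s - epochs$start_s)
}

#' Instantaneous-phase series
#'
#' Per-sample phase in `[-pi, pi)` extracted from a band-limited trace. The
#' convention throughout the package is 0 at the oscillation peak and +/- pi at
#' the troughs.
#'
#' @param phase numeric vector of phases in radians.
#' @param fs sampling rate in Hz.
#' @param band_hz length-2 numeric, the band of the generating filter.
#' @param t0 start time in seconds.
#' @return An object of class `prr_phase`.
#' @export
prr_phase_series <- function(phase, fs, band_hz = NULL, t0 = 0) {
  phase <- wrap_phase(as.numeric(phase))
  structure(list(phase = phase, fs = fs, band_hz = band_hz, t0 = t0),
            class = "prr_phase")
}

#' @export
print.prr_phase <- function(x, ...) {
  cat(sprintf("<prr_phase> %d samples @ %g Hz%s\n", length(x$phase), x$fs,
              if (!is.null(x$band_hz))
                sprintf(", band %g-%g Hz", x$band_hz[1], x$band_hz[2]) else ""))
  invisible(x)
}

#' Amplitude-envelope series
#'
#' Per-sample non-negative amplitude envelope of a band-limited trace.
#'
#' @param envelope numeric vector, all values >= 0.
#' @param fs sampling rate in Hz.
#' @param band_hz length-2 numeric band of the generating filter.
#' @param t0 start time in seconds.
#' @return An object of class `prr_amplitude`.
#' @export
prr_amplitude_series <- function(envelope, fs, band_hz = NULL, t0 = 0) {
  envelope <- as.numeric(envelope)
  if (any(envelope < 0)) stop("envelope must be non-negative", call. = FALSE)
  structure(list(envelope = envelope, fs = fs, band_hz = band_hz, t0 = t0),
            class = "prr_amplitude")
}

#' Sorted single-unit spike train
#'
#' Spike times of one sorted unit plus its mean spike waveform.
#'
#' @param spike_times_s strictly increasing spike times in seconds.
#' @param unit_id identifier (integer or character).
#' @param waveform numeric vector, the mean spike waveform (negative-going
#'   trough for extracellular units).
#' @param waveform_fs sampling rate of the waveform in Hz.
#' @return An object of class `prr_spiketrain`.
#' @export
prr_spiketrain <- function(spike_times_s, unit_id = NA, waveform = NULL,
                           waveform_fs = NA_real_) {
  spike_times_s <- as.numeric(spike_times_s)
  if (length(spike_times_s) > 1L && any(diff(spike_times_s) <= 0))
    stop("spike times must be strictly increasing", call. = FALSE)
  structure(list(unit_id = unit_id, spike_times_s = spike_times_s,
                 waveform = waveform, waveform_fs = waveform_fs),
            class = "prr_spiketrain")
}

#' @export
print.prr_spiketrain <- function(x, ...) {
  cat(sprintf("<prr_spiketrain> unit %s: %d spikes%s\n", format(x$unit_id),
              length(x$spike_times_s),
              if (!is.null(x$waveform))
                sprintf(", waveform %d samples @ %g Hz", length(x$waveform),
                        x$waveform_fs) else ""))
  invisible(x)
}

#' Wrap angles to [-pi, pi)
#' @param x numeric vector of angles in radians.
#' @return angles wrapped into `[-pi, pi)`.
#' @export
wrap_phase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  # map the boundary value pi (mod result 2*pi - eps rounding) consistently
  y[y >= pi] <- -pi
  y
}

# Run code with a local RNG state seeded by `seed`, restoring the caller's
# stream afterwards so generators never clobber a user's simulation.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      stats::runif(1L)
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}
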