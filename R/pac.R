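#' @name pac
#' @title Phase-amplitude coupling: Kullback-Leibler modulation index
#' @description The amplitude envelope of a fast oscillation is averaged in
#'   18 bins of slow-rhythm phase and normalized to sum 1; the
#'   Kullback-Leibler distance of that distribution from the uniform
#'   distribution, divided by log of the bin count, is the modulation index
#'   (0 = no modulation, 1 = all envelope mass in one bin). A comodulogram
#'   scans slow bands (2-10 Hz, 1 Hz bandwidth) against fast bands
#'   (30-150 Hz, 10 Hz bandwidth) in non-overlapping 4 s windows.
NULL

# MI from per-bin mean amplitudes (already averaged within bins).
mi_from_bin_means <- function(mean_amp) {
  n_bins <- length(mean_amp)
  tot <- sum(mean_amp)
  if (tot <= 0) return(NA_real_)
  p <- mean_amp / tot
  nz <- p > 0
  kl <- sum(p[nz] * log(p[nz] * n_bins))
  kl / log(n_bins)
}

#' Kullback-Leibler modulation index
#'
#' Bins the amplitude envelope by the simultaneous slow-rhythm phase (18 bins
#' of 20 degrees), normalizes the per-bin mean envelope to sum 1, and returns
#' `D_KL(m || u) / log(N)` against the uniform distribution `u`. Empty phase
#' bins contribute zero mass (the `x log x -> 0` limit).
#'
#' @param phase a [prr_phase_series()].
#' @param amplitude a [prr_amplitude_series()] of equal length and fs.
#' @param epochs optional [prr_epochs()].
#' @param n_bins number of phase bins (default 18).
#' @return list with `mi` (in `[0, 1]`) and `distribution`, a data.frame with
#'   `bin_center_rad` and `mean_amp` (normalized to sum 1).
#' @export
modulation_index <- function(phase, amplitude, epochs = NULL, n_bins = 18L) {
  phi <- masked_values(phase, epochs)
  amp <- masked_values(amplitude, epochs)
  if (length(phi) != length(amp))
    stop("phase and amplitude series must have equal length", call. = FALSE)
  if (!length(phi))
    stop("insufficient data: no samples selected", call. = FALSE)
  if (any(amp < 0)) stop("envelope must be non-negative", call. = FALSE)
  if (sum(amp) <= 0)
    stop("degenerate input: zero total amplitude", call. = FALSE)
  b <- phase_bin(phi, n_bins)
  sums <- vapply(seq_len(n_bins), function(k) sum(amp[b == k]), numeric(1))
  cnts <- tabulate(b, n_bins)
  mean_amp <- ifelse(cnts > 0, sums / pmax(cnts, 1L), 0)
  p <- mean_amp / sum(mean_amp)
  list(mi = mi_from_bin_means(mean_amp),
       distribution = data.frame(bin_center_rad = phase_bin_centers(n_bins),
                                 mean_amp = p))
}

#' Preferred coupling phase of a phase-amplitude distribution
#'
#' Circular mean of the bin centers weighted by the normalized mean envelope.
#' When the weighted resultant length is below `1e-6` (e.g. a uniform or
#' antipodally symmetric distribution) the phase is undefined.
#'
#' @param distribution data.frame with `bin_center_rad` and `mean_amp`
#'   (as returned by [modulation_index()]).
#' @return list with `phase_rad` (NA when undefined), `resultant` and
#'   `defined` (logical).
#' @export
preferred_coupling_phase <- function(distribution) {
  w <- distribution$mean_amp / sum(distribution$mean_amp)
  z <- sum(w * exp(1i * distribution$bin_center_rad))
  defined <- Mod(z) >= 1e-6
  list(phase_rad = if (defined) Arg(z) else NA_real_,
       resultant = Mod(z), defined = defined)
}

# Standard comodulogram frequency grids.
comod_phase_freqs <- function(from = 2, to = 10, step = 1) seq(from, to, by = step)
comod_amp_freqs <- function(from = 30, to = 150, step = 1) seq(from, to, by = step)

#' Phase-amplitude comodulogram
#'
#' For every (slow band, fast band) pair the full trace is band-pass filtered
#' (slow: `phase_bw_hz` wide, fast: `amp_bw_hz` wide), phase and envelope are
#' extracted by the Hilbert transform, and the modulation index is computed in
#' non-overlapping `window_s`-second windows inside the epochs and averaged.
#'
#' @param x a [prr_signal()] (LFP).
#' @param epochs optional [prr_epochs()].
#' @param window_s window length in seconds (default 4).
#' @param phase_freqs_hz centers of the slow (phase-giving) bands, default
#'   2-10 Hz in 1 Hz steps.
#' @param amp_freqs_hz centers of the fast (amplitude-giving) bands, default
#'   30-150 Hz in 1 Hz steps.
#' @param phase_bw_hz,amp_bw_hz filter bandwidths (defaults 1 and 10 Hz).
#' @param n_bins phase bins (default 18).
#' @return a `prr_comodulogram`: list with `phase_freqs_hz`, `amp_freqs_hz`,
#'   `mi` (matrix, rows = phase freqs, cols = amp freqs), `n_windows`, `meta`.
#' @export
comodulogram <- function(x, epochs = NULL, window_s = 4,
                         phase_freqs_hz = comod_phase_freqs(),
                         amp_freqs_hz = comod_amp_freqs(),
                         phase_bw_hz = 1, amp_bw_hz = 10, n_bins = 18L) {
  stopifnot(inherits(x, "prr_signal"))
  if (is.null(epochs))
    epochs <- prr_epochs(x$t0, x$t0 + signal_duration(x))
  win_n <- as.integer(round(window_s * x$fs))
  # window start indices (full windows inside epochs, non-overlapping)
  segs <- mask_epochs(x, epochs)
  starts <- integer()
  for (s in segs) {
    i0 <- as.integer(round((s$t0 - x$t0) * x$fs)) + 1L
    nfull <- length(s$samples) %/% win_n
    if (nfull > 0L) starts <- c(starts, i0 + (0:(nfull - 1L)) * win_n)
  }
  if (!length(starts))
    stop(sprintf("insufficient data: no epoch contains a full %g s window",
                 window_s), call. = FALSE)
  # sample -> (window, bin) group ids; samples outside windows get group 0
  n <- length(x$samples)
  wid <- integer(n)
  for (j in seq_along(starts))
    wid[starts[j]:(starts[j] + win_n - 1L)] <- j
  inw <- wid > 0L
  nW <- length(starts)

  phases <- lapply(phase_freqs_hz, function(f)
    analytic_phase(bandpass(x, f - phase_bw_hz / 2, f + phase_bw_hz / 2))$phase)
  mi <- matrix(NA_real_, length(phase_freqs_hz), length(amp_freqs_hz),
               dimnames = list(phase_freqs_hz, amp_freqs_hz))
  group_of <- lapply(phases, function(ph) {
    b <- phase_bin(ph, n_bins)
    g <- integer(n)
    g[inw] <- (wid[inw] - 1L) * n_bins + b[inw]
    g
  })
  cnts <- lapply(group_of, function(g)
    tabulate(g[inw], nbins = nW * n_bins))
  for (a in seq_along(amp_freqs_hz)) {
    fa <- amp_freqs_hz[a]
    env <- analytic_amplitude(bandpass(x, fa - amp_bw_hz / 2,
                                       fa + amp_bw_hz / 2))$envelope
    for (p in seq_along(phase_freqs_hz)) {
      g <- group_of[[p]]
      sums <- rowsum(env[inw], group = g[inw], reorder = FALSE)
      # rowsum orders by first appearance; rebuild into dense (window, bin)
      dens <- numeric(nW * n_bins)
      dens[as.integer(rownames(sums))] <- sums[, 1L]
      means <- dens / pmax(cnts[[p]], 1L)
      mis <- vapply(seq_len(nW), function(w)
        mi_from_bin_means(means[((w - 1L) * n_bins + 1L):(w * n_bins)]),
        numeric(1))
      mi[p, a] <- mean(mis, na.rm = TRUE)
    }
  }
  structure(list(phase_freqs_hz = phase_freqs_hz, amp_freqs_hz = amp_freqs_hz,
                 mi = mi, n_windows = nW,
                 meta = list(window_s = window_s, phase_bw_hz = phase_bw_hz,
                             amp_bw_hz = amp_bw_hz, n_bins = n_bins)),
            class = "prr_comodulogram")
}

#' @export
print.prr_comodulogram <- function(x, ...) {
  i <- arrayInd(which.max(x$mi), dim(x$mi))
  cat(sprintf(
    "<prr_comodulogram> %d x %d bands; max MI = %.4g at phase %g Hz / amp %g Hz (%d windows)\n",
    nrow(x$mi), ncol(x$mi), max(x$mi), x$phase_freqs_hz[i[1]],
    x$amp_freqs_hz[i[2]], x$n_windows))
  invisible(x)
}

#' Single-band modulation index of an LFP
#'
#' Convenience wrapper: filter `x` in `phase_band_hz` and `amp_band_hz`,
#' extract phase and envelope, and compute the windowed-average modulation
#' index together with the pooled phase-amplitude distribution.
#'
#' @inheritParams comodulogram
#' @param phase_band_hz slow band (default 1-5 Hz).
#' @param amp_band_hz fast band (default 80-100 Hz).
#' @return list with `mi` (mean over windows), `distribution` (pooled over
#'   all selected samples), `preferred` (see [preferred_coupling_phase()]),
#'   `n_windows`.
#' @export
band_mi <- function(x, epochs = NULL, phase_band_hz = c(1, 5),
                    amp_band_hz = c(80, 100), window_s = 4, n_bins = 18L) {
  ph <- analytic_phase(bandpass(x, phase_band_hz[1], phase_band_hz[2]))
  am <- analytic_amplitude(bandpass(x, amp_band_hz[1], amp_band_hz[2]))
  if (is.null(epochs))
    epochs <- prr_epochs(x$t0, x$t0 + signal_duration(x))
  win_n <- as.integer(round(window_s * x$fs))
  segs <- mask_epochs(x, epochs)
  mis <- numeric()
  for (s in segs) {
    i0 <- as.integer(round((s$t0 - x$t0) * x$fs)) + 1L
    nfull <- length(s$samples) %/% win_n
    for (j in seq_len(nfull)) {
      idx <- (i0 + (j - 1L) * win_n):(i0 + j * win_n - 1L)
      b <- phase_bin(ph$phase[idx], n_bins)
      sums <- vapply(seq_len(n_bins), function(k) sum(am$envelope[idx][b == k]),
                     numeric(1))
      cnts <- tabulate(b, n_bins)
      mis <- c(mis, mi_from_bin_means(ifelse(cnts > 0, sums / pmax(cnts, 1L), 0)))
    }
  }
  if (!length(mis))
    stop(sprintf("insufficient data: no epoch contains a full %g s window",
                 window_s), call. = FALSE)
  pooled <- modulation_index(ph, am, epochs, n_bins)
  list(mi = mean(mis), distribution = pooled$distribution,
       preferred = preferred_coupling_phase(pooled$distribution),
       n_windows = length(mis))
}

#' Extract theta-rich epochs by rms thresholding
#'
#' Theta-filters (6-12 Hz) the full trace, computes the root mean square in a
#' sliding window (50% overlap), and thresholds at `mean + 2 SD` of the rms
#' series. Supra-threshold windows are merged into epochs when separated by
#' gaps shorter than the window length.
#'
#' @param x a [prr_signal()] of at least 10 s.
#' @param rms_window_s rms window length in seconds (default 0.5).
#' @param theta_band_hz theta filter band (default 6-12 Hz).
#' @return a [prr_epochs()] with attributes `threshold` and `rms` (the rms
#'   series as a data.frame `t_s`, `rms`).
#' @export
extract_theta_epochs <- function(x, rms_window_s = 0.5,
                                 theta_band_hz = c(6, 12)) {
  stopifnot(inherits(x, "prr_signal"))
  if (signal_duration(x) < 10)
    stop("signal must be at least 10 s long", call. = FALSE)
  if (stats::sd(x$samples) == 0)
    stop("degenerate input: flat signal", call. = FALSE)
  th <- bandpass(x, theta_band_hz[1], theta_band_hz[2])
  win_n <- as.integer(round(rms_window_s * x$fs))
  hop <- max(1L, win_n %/% 2L)
  starts <- seq(1L, length(th$samples) - win_n + 1L, by = hop)
  rms <- vapply(starts, function(i0)
    sqrt(mean(th$samples[i0:(i0 + win_n - 1L)]^2)), numeric(1))
  thr <- mean(rms) + 2 * stats::sd(rms)
  above <- rms > thr
  iv <- list()
  if (any(above)) {
    # each rms value represents its window centre +/- half a hop
    t_center <- x$t0 + (starts - 1L) / x$fs + rms_window_s / 2
    a <- t_center[above] - hop / (2 * x$fs)
    b <- t_center[above] + hop / (2 * x$fs)
    # merge overlapping / close windows (gap < rms_window_s)
    cur_a <- a[1L]; cur_b <- b[1L]
    for (j in seq_along(a)[-1L]) {
      if (a[j] - cur_b < rms_window_s) cur_b <- max(cur_b, b[j])
      else { iv[[length(iv) + 1L]] <- c(cur_a, cur_b); cur_a <- a[j]; cur_b <- b[j] }
    }
    iv[[length(iv) + 1L]] <- c(cur_a, cur_b)
  }
  dur_end <- x$t0 + signal_duration(x)
  ep <- if (length(iv)) {
    m <- do.call(rbind, iv)
    prr_epochs(m[, 1L], pmin(m[, 2L], dur_end))
  } else prr_epochs()
  attr(ep, "threshold") <- thr
  attr(ep, "rms") <- data.frame(t_s = x$t0 + (starts - 1L) / x$fs, rms = rms)
  ep
}

#' Comodulogram restricted to theta-rich epochs, with band-MI ratio
#'
#' Recomputes the comodulogram inside the supplied theta epochs and reports
#' the ratio of the maximal modulation index in the slow-rhythm phase rows
#' (1-5 Hz, clipped to the 2-10 Hz grid) to the maximum in the theta phase
#' rows (6-12 Hz).
#'
#' @param x a [prr_signal()].
#' @param theta_epochs non-empty [prr_epochs()] (from
#'   [extract_theta_epochs()]).
#' @param window_s MI window (default 4 s); if no full window fits in the
#'   epochs and `allow_short_window = TRUE`, the window is shortened to the
#'   longest epoch with a warning.
#' @param allow_short_window fall back to a shorter window when the epochs
#'   cannot host a full one (default FALSE).
#' @param ... passed to [comodulogram()] (e.g. coarser frequency grids).
#' @return list with `comodulogram`, `mi_prr`, `mi_theta`, `ratio`.
#' @export
pac_in_theta_epochs <- function(x, theta_epochs, window_s = 4,
                                allow_short_window = FALSE, ...) {
  if (!nrow(theta_epochs))
    stop("insufficient data: empty theta-epoch set", call. = FALSE)
  max_ep <- max(theta_epochs$end_s - theta_epochs$start_s)
  if (max_ep < window_s) {
    if (!allow_short_window)
      stop(sprintf(
        "insufficient data: no theta epoch can host a %g s window", window_s),
        call. = FALSE)
    window_s <- max_ep
    warning(sprintf("window shortened to %.3g s to fit the theta epochs",
                    window_s), call. = FALSE)
  }
  cm <- comodulogram(x, theta_epochs, window_s = window_s, ...)
  prr_rows <- cm$phase_freqs_hz >= 1 & cm$phase_freqs_hz <= 5
  theta_rows <- cm$phase_freqs_hz >= 6 & cm$phase_freqs_hz <= 12
  mi_prr <- max(cm$mi[prr_rows, , drop = FALSE])
  mi_theta <- max(cm$mi[theta_rows, , drop = FALSE])
  list(comodulogram = cm, mi_prr = mi_prr, mi_theta = mi_theta,
       ratio = mi_prr / mi_theta)
}
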