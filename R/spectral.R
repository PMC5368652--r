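#' @name spectral
#' @title Multitaper spectra, 1/f normalization and LFP-respiration coherence
#' @description Power spectral density is estimated on disjoint 5 s chunks of
#'   the epoch-masked trace with Slepian (DPSS) tapers and averaged; spectra
#'   can be normalized by frequency to compensate the 1/f power decay before
#'   band peaks are read out. Coherence uses Welch averaging with 0.5 s
#'   segments zero-padded to 10 s.
NULL

# Slepian taper cache. Tapers are solutions of the symmetric tridiagonal
# eigenproblem; for long chunks they are computed at length <= 1024 and
# spline-interpolated, which preserves the taper shapes to high accuracy.
.dpss_cache <- new.env(parent = emptyenv())

dpss_tapers <- function(n, nw, k) {
  key <- sprintf("%d_%g_%d", n, nw, k)
  if (!is.null(.dpss_cache[[key]])) return(.dpss_cache[[key]])
  n0 <- min(n, 1024L)
  w <- nw / n0
  i <- 0:(n0 - 1L)
  A <- matrix(0, n0, n0)
  diag(A) <- ((n0 - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off <- (1:(n0 - 1L)) * (n0 - (1:(n0 - 1L))) / 2
  A[cbind(1:(n0 - 1L), 2:n0)] <- off
  A[cbind(2:n0, 1:(n0 - 1L))] <- off
  ev <- eigen(A, symmetric = TRUE)
  v <- ev$vectors[, seq_len(k), drop = FALSE]
  if (n != n0) {
    x0 <- seq(0, 1, length.out = n0)
    x1 <- seq(0, 1, length.out = n)
    v <- vapply(seq_len(k),
                function(j) stats::spline(x0, v[, j], xout = x1)$y,
                numeric(n))
  }
  # unit energy; fix polarity so the leading lobe is positive
  for (j in seq_len(k)) {
    v[, j] <- v[, j] / sqrt(sum(v[, j]^2))
    if (sum(v[seq_len(max(2L, n %/% 8L)), j]) < 0) v[, j] <- -v[, j]
  }
  .dpss_cache[[key]] <- v
  v
}

# One-sided multitaper PSD of one chunk (density units: power per Hz).
mt_chunk_psd <- function(x, tapers, fs) {
  n <- length(x)
  x <- x - mean(x)
  nf <- n %/% 2L + 1L
  p <- numeric(nf)
  for (j in seq_len(ncol(tapers))) {
    X <- stats::fft(x * tapers[, j])
    p <- p + Mod(X[seq_len(nf)])^2
  }
  p <- p / ncol(tapers) / fs
  if (n %% 2L == 0L) p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]
  else p[2:nf] <- 2 * p[2:nf]
  p
}

#' Multitaper power spectral density
#'
#' Averages Slepian-tapered periodograms over all complete, disjoint
#' `chunk_s`-second chunks lying inside the analysis epochs; chunks never span
#' epoch boundaries. The time-bandwidth product is `chunk_s * bandwidth_hz / 2`
#' and `floor(2*NW) - 1` tapers are used (NW = 2.5, 4 tapers at the defaults).
#'
#' @param x a [prr_signal()].
#' @param epochs optional [prr_epochs()]; `NULL` analyses the full trace.
#' @param chunk_s chunk length in seconds (default 5).
#' @param bandwidth_hz spectral bandwidth in Hz (default 1).
#' @return a `prr_spectrum`: list with `freqs_hz`, `power`, `normalized`
#'   (logical) and `meta`.
#' @export
multitaper_psd <- function(x, epochs = NULL, chunk_s = 5, bandwidth_hz = 1) {
  stopifnot(inherits(x, "prr_signal"))
  if (is.null(epochs))
    epochs <- prr_epochs(x$t0, x$t0 + signal_duration(x))
  segs <- mask_epochs(x, epochs)
  nchunk <- as.integer(round(chunk_s * x$fs))
  chunks <- list()
  for (s in segs) {
    v <- s$samples
    nfull <- length(v) %/% nchunk
    for (j in seq_len(nfull))
      chunks[[length(chunks) + 1L]] <- v[((j - 1L) * nchunk + 1L):(j * nchunk)]
  }
  if (!length(chunks))
    stop(sprintf("insufficient data: no epoch contains a full %g s chunk",
                 chunk_s), call. = FALSE)
  nw <- chunk_s * bandwidth_hz / 2
  k <- max(1L, floor(2 * nw) - 1L)
  tp <- dpss_tapers(nchunk, nw, k)
  p <- Reduce(`+`, lapply(chunks, mt_chunk_psd, tapers = tp, fs = x$fs)) /
    length(chunks)
  freqs <- (seq_along(p) - 1L) * x$fs / nchunk
  structure(list(freqs_hz = freqs, power = p, normalized = FALSE,
                 meta = list(chunk_s = chunk_s, bandwidth_hz = bandwidth_hz,
                             nw = nw, n_tapers = k, n_chunks = length(chunks),
                             fs = x$fs)),
            class = "prr_spectrum")
}

#' @export
print.prr_spectrum <- function(x, ...) {
  cat(sprintf("<prr_spectrum> %d bins, 0-%.6g Hz, %s power (%d chunks of %g s)\n",
              length(x$freqs_hz), max(x$freqs_hz),
              if (isTRUE(x$normalized)) "frequency-normalized" else "raw",
              x$meta$n_chunks, x$meta$chunk_s))
  invisible(x)
}

#' Normalize a spectrum by frequency
#'
#' Multiplies power by frequency to compensate the 1/f decay, so that peaks
#' in different bands are comparable. Calling it twice is an error.
#'
#' @param spectrum a `prr_spectrum` with `normalized = FALSE`.
#' @return the frequency-normalized `prr_spectrum`.
#' @export
normalize_1f <- function(spectrum) {
  stopifnot(inherits(spectrum, "prr_spectrum"))
  if (isTRUE(spectrum$normalized))
    stop("spectrum is already frequency-normalized", call. = FALSE)
  spectrum$power <- spectrum$power * spectrum$freqs_hz
  spectrum$normalized <- TRUE
  spectrum
}

#' Peak frequency and band power within a frequency band
#'
#' Restricted to `[low, high]` Hz of the frequency-normalized spectrum (a raw
#' spectrum is normalized internally), returns the argmax frequency (lowest
#' frequency on exact ties), its normalized power, and the mean normalized
#' power over the band.
#'
#' @param spectrum a `prr_spectrum`.
#' @param band_hz length-2 numeric band (Hz), inside the spectrum support.
#' @return list with `peak_freq_hz`, `peak_power`, `band_power`.
#' @export
band_peak <- function(spectrum, band_hz) {
  stopifnot(inherits(spectrum, "prr_spectrum"), length(band_hz) == 2L)
  if (band_hz[1] < min(spectrum$freqs_hz) - 1e-9 ||
      band_hz[2] > max(spectrum$freqs_hz) + 1e-9)
    stop("band outside spectrum support", call. = FALSE)
  if (!isTRUE(spectrum$normalized)) spectrum <- normalize_1f(spectrum)
  sel <- which(spectrum$freqs_hz >= band_hz[1] - 1e-9 &
               spectrum$freqs_hz <= band_hz[2] + 1e-9)
  if (!length(sel)) stop("band contains no frequency bin", call. = FALSE)
  pw <- spectrum$power[sel]
  i <- which.max(pw)  # which.max returns the first (= lowest-frequency) max
  list(peak_freq_hz = spectrum$freqs_hz[sel][i],
       peak_power = pw[i],
       band_power = mean(pw))
}

# Welch averaged auto/cross spectra over a list of per-epoch sample vectors.
welch_csd <- function(xsegs, ysegs, fs, nper, nfft, overlap = 0.5) {
  step <- max(1L, as.integer(round(nper * (1 - overlap))))
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1))  # Hann
  nf <- nfft %/% 2L + 1L
  sxx <- syy <- numeric(nf)
  sxy <- complex(real = numeric(nf), imaginary = numeric(nf))
  nseg <- 0L
  for (k in seq_along(xsegs)) {
    xv <- xsegs[[k]]; yv <- ysegs[[k]]
    nmax <- length(xv) - nper
    if (nmax < 0) next
    starts <- seq(0L, nmax, by = step)
    for (s0 in starts) {
      xi <- (xv[(s0 + 1L):(s0 + nper)] - mean(xv[(s0 + 1L):(s0 + nper)])) * win
      yi <- (yv[(s0 + 1L):(s0 + nper)] - mean(yv[(s0 + 1L):(s0 + nper)])) * win
      X <- stats::fft(c(xi, numeric(nfft - nper)))[seq_len(nf)]
      Y <- stats::fft(c(yi, numeric(nfft - nper)))[seq_len(nf)]
      sxx <- sxx + Mod(X)^2
      syy <- syy + Mod(Y)^2
      sxy <- sxy + X * Conj(Y)
      nseg <- nseg + 1L
    }
  }
  if (nseg == 0L)
    stop("insufficient data: no segment of the required length fits",
         call. = FALSE)
  list(freqs_hz = (seq_len(nf) - 1L) * fs / nfft,
       sxx = sxx / nseg, syy = syy / nseg, sxy = sxy / nseg, n_segments = nseg)
}

#' Magnitude-squared coherence between two signals
#'
#' Welch-style coherence with sliding windows of `0.5 * fs` samples,
#' zero-padded to `10 * fs` points before the transform, 50% overlap, Hann
#' taper. The peak is reported within 1-10 Hz.
#'
#' @param x,y two [prr_signal()]s sharing `fs` and duration.
#' @param epochs optional [prr_epochs()] restricting the analysis.
#' @param peak_band_hz band in which the coherence peak is reported
#'   (default `c(1, 10)`).
#' @return a `prr_coherence`: list with `freqs_hz`, `coherence`, `peak_coh`,
#'   `peak_freq_hz`, `meta`.
#' @export
coherence <- function(x, y, epochs = NULL, peak_band_hz = c(1, 10)) {
  stopifnot(inherits(x, "prr_signal"), inherits(y, "prr_signal"))
  if (x$fs != y$fs)
    stop("`x` and `y` must share the same sampling rate", call. = FALSE)
  if (length(x$samples) != length(y$samples))
    stop("`x` and `y` must share the same duration", call. = FALSE)
  if (is.null(epochs))
    epochs <- prr_epochs(x$t0, x$t0 + signal_duration(x))
  xsegs <- lapply(mask_epochs(x, epochs), `[[`, "samples")
  ysegs <- lapply(mask_epochs(y, epochs), `[[`, "samples")
  nper <- as.integer(round(0.5 * x$fs))
  nfft <- as.integer(round(10 * x$fs))
  w <- welch_csd(xsegs, ysegs, x$fs, nper, nfft)
  coh <- Mod(w$sxy)^2 / (w$sxx * w$syy)
  coh[!is.finite(coh)] <- 0
  coh <- pmin(pmax(coh, 0), 1)
  sel <- which(w$freqs_hz >= peak_band_hz[1] & w$freqs_hz <= peak_band_hz[2])
  i <- sel[which.max(coh[sel])]
  structure(list(freqs_hz = w$freqs_hz, coherence = coh,
                 peak_coh = coh[i], peak_freq_hz = w$freqs_hz[i],
                 meta = list(nper = nper, nfft = nfft, overlap = 0.5,
                             n_segments = w$n_segments)),
            class = "prr_coherence")
}

#' @export
print.prr_coherence <- function(x, ...) {
  cat(sprintf("<prr_coherence> %d bins; peak %.3f at %.3f Hz (%d segments)\n",
              length(x$freqs_hz), x$peak_coh, x$peak_freq_hz,
              x$meta$n_segments))
  invisible(x)
}
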