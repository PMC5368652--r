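#' @name synthetic_data
#' @title Synthetic awake-session generator with ground truth
#' @description Phenomenological generator reproducing the statistical
#'   structure of awake-mouse prefrontal recordings during immobility: an
#'   irregular ~3.5 Hz respiration trace, an LFP composed of a
#'   respiration-locked slow component, a theta component locked 2:1 to the
#'   slow rhythm with von Mises phase jitter, gamma whose amplitude is
#'   modulated by the slow rhythm's phase, and a 1/f background; plus
#'   von Mises phase-locked spike trains with class-specific rates and
#'   waveforms. Every session carries its full ground-truth parameter record
#'   so downstream estimators can be tested by construction-recovery.
NULL

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler; `kappa = 0` returns uniform phases.
#'
#' @param n number of draws.
#' @param mu circular mean (radians).
#' @param kappa concentration (>= 0).
#' @return phases in `[-pi, pi)`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop("kappa must be >= 0", call. = FALSE)
  if (n == 0L) return(numeric())
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, ceiling((n - length(out)) * 1.5))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (u2 < cc * (2 - cc)) | (log(cc / u2) + 1 - cc >= 0)
    out <- c(out, sign(u3[ok] - 0.5) * acos(pmax(pmin(f[ok], 1), -1)))
  }
  wrap_phase(out[seq_len(n)] + mu)
}

#' Generate a 1/f^alpha Gaussian noise trace
#'
#' Spectrally shaped Gaussian noise with power density proportional to
#' `f^-alpha`, scaled to unit standard deviation — the background component
#' of the synthetic LFP.
#'
#' @param duration_s trace duration in seconds.
#' @param fs sampling rate in Hz.
#' @param alpha spectral slope (default 1.5).
#' @param seed optional integer seed; `NULL` uses the ambient RNG stream.
#' @return numeric vector of `round(duration_s * fs)` samples.
#' @export
noise_1f_trace <- function(duration_s, fs, alpha = 1.5, seed = NULL)
  with_seed(seed, noise_1f(as.integer(round(duration_s * fs)), fs, alpha))

# 1/f^alpha Gaussian background, unit SD, via FFT spectral shaping.
noise_1f <- function(n, fs, alpha) {
  X <- stats::fft(stats::rnorm(n))
  f <- (0:(n - 1L)) * fs / n
  f <- pmin(f, fs - f)               # two-sided frequency magnitudes
  g <- c(0, f[-1L]^(-alpha / 2))
  x <- Re(stats::fft(X * g, inverse = TRUE) / n)
  x / stats::sd(x)
}

#' Generate a quasi-periodic respiration trace
#'
#' Cycle periods are i.i.d. gamma-distributed with the requested mean
#' frequency and coefficient of variation; the phase is integrated
#' continuously (piecewise linear across cycles) and the trace is the cosine
#' of that phase, so inspiration deflects positive and phase 0 falls on the
#' inspiration peak.
#'
#' @param duration_s trace duration in seconds (> 0).
#' @param fs sampling rate in Hz (>= 100).
#' @param mean_freq_hz mean breathing frequency in Hz, in (0.5, 12).
#' @param cv coefficient of variation of cycle periods (>= 0).
#' @param seed integer seed.
#' @return a [prr_signal()] labelled "respiration", with attributes
#'   `phase_unwrapped_rad` (continuous phase) and `cycle_periods_s`.
#' @export
generate_respiration <- function(duration_s, fs, mean_freq_hz = 3.5,
                                 cv = 0.1, seed = NULL) {
  if (duration_s <= 0 || fs < 100)
    stop("invalid argument: need duration_s > 0 and fs >= 100", call. = FALSE)
  if (mean_freq_hz <= 0.5 || mean_freq_hz >= 12)
    stop("invalid argument: mean_freq_hz must lie in (0.5, 12)", call. = FALSE)
  if (cv < 0) stop("invalid argument: cv must be >= 0", call. = FALSE)
  mean_period <- 1 / mean_freq_hz
  n_cycles <- ceiling(duration_s / mean_period * (1 + 5 * cv)) + 10L
  periods <- with_seed(seed, {
    if (cv == 0) rep(mean_period, n_cycles)
    else stats::rgamma(n_cycles, shape = 1 / cv^2,
                       scale = mean_period * cv^2)
  })
  bounds <- c(0, cumsum(periods))
  n <- as.integer(round(duration_s * fs))
  t <- (seq_len(n) - 1L) / fs
  ci <- findInterval(t, bounds)
  phi <- 2 * pi * (ci - 1L) + 2 * pi * (t - bounds[ci]) / periods[ci]
  out <- prr_signal(cos(phi), fs, label = "respiration")
  attr(out, "phase_unwrapped_rad") <- phi
  attr(out, "cycle_periods_s") <- periods[seq_len(max(ci))]
  out
}

#' Ground-truth parameter record for a synthetic session
#'
#' @param respiration_freq_hz mean breathing frequency (Hz).
#' @param respiration_cv cycle-period coefficient of variation.
#' @param prr_amp amplitude of the respiration-locked LFP component (z-units).
#' @param prr_lag_rad phase lag of the LFP slow component relative to
#'   respiration.
#' @param theta_freq_ratio integer theta cycles per slow-rhythm cycle.
#' @param theta_lock_kappa von Mises concentration of theta-to-slow locking.
#' @param theta_amp amplitude of the theta component (z-units).
#' @param gamma_band_hz length-2 band of the modulated gamma.
#' @param gamma_amp amplitude of the gamma component (z-units).
#' @param pac_depth fractional gamma-amplitude modulation in `[0, 1]`.
#' @param pac_preferred_phase_rad slow-rhythm phase of maximal gamma
#'   amplitude.
#' @param noise_exponent spectral slope of the 1/f background.
#' @param unit_params optional per-unit data.frame (filled by
#'   [generate_session()]).
#' @param seed integer seed.
#' @return an object of class `prr_truth`.
#' @export
ground_truth <- function(respiration_freq_hz = 3.5, respiration_cv = 0.1,
                         prr_amp = 1, prr_lag_rad = 0,
                         theta_freq_ratio = 2L, theta_lock_kappa = 4,
                         theta_amp = 0.6, gamma_band_hz = c(80, 100),
                         gamma_amp = 0.4, pac_depth = 0.5,
                         pac_preferred_phase_rad = 0, noise_exponent = 1.5,
                         unit_params = NULL, seed = 1L) {
  if (pac_depth < 0 || pac_depth > 1)
    stop("pac_depth must lie in [0, 1]", call. = FALSE)
  if (theta_lock_kappa < 0)
    stop("kappas must be >= 0", call. = FALSE)
  if (theta_freq_ratio != as.integer(theta_freq_ratio) || theta_freq_ratio < 1)
    stop("theta_freq_ratio must be a positive integer", call. = FALSE)
  structure(list(
    respiration_freq_hz = respiration_freq_hz, respiration_cv = respiration_cv,
    prr_amp = prr_amp, prr_lag_rad = prr_lag_rad,
    theta_freq_ratio = as.integer(theta_freq_ratio),
    theta_lock_kappa = theta_lock_kappa, theta_amp = theta_amp,
    gamma_band_hz = gamma_band_hz, gamma_amp = gamma_amp,
    pac_depth = pac_depth, pac_preferred_phase_rad = pac_preferred_phase_rad,
    noise_exponent = noise_exponent, unit_params = unit_params,
    seed = as.integer(seed)), class = "prr_truth")
}

#' @export
print.prr_truth <- function(x, ...) {
  cat(sprintf(
    "<prr_truth> resp %.2f Hz (cv %.2f); prr_amp %.2f; theta %d:1 (kappa %.1f, amp %.2f);\n  gamma %g-%g Hz (amp %.2f, pac_depth %.2f @ %.2f rad); 1/f^%.2f; seed %d; %s units\n",
    x$respiration_freq_hz, x$respiration_cv, x$prr_amp, x$theta_freq_ratio,
    x$theta_lock_kappa, x$theta_amp, x$gamma_band_hz[1], x$gamma_band_hz[2],
    x$gamma_amp, x$pac_depth, x$pac_preferred_phase_rad, x$noise_exponent,
    x$seed, if (is.null(x$unit_params)) "no" else nrow(x$unit_params)))
  invisible(x)
}

# Slow-rhythm phase of the LFP implied by a generated respiration trace.
slow_phase_from_respiration <- function(respiration, prr_lag_rad = 0) {
  phi <- attr(respiration, "phase_unwrapped_rad")
  if (is.null(phi))
    stop("respiration trace lacks the generator's phase record", call. = FALSE)
  phi + prr_lag_rad
}

#' Generate an LFP trace with the session's coupling structure
#'
#' Composes (a) a slow component: the respiration phase shifted by
#' `prr_lag_rad`, scaled by `prr_amp`; (b) a theta component at
#' `theta_freq_ratio` times the instantaneous slow frequency with per-cycle
#' von Mises phase jitter of concentration `theta_lock_kappa`; (c) a gamma
#' carrier (band-limited noise in `gamma_band_hz`) with amplitude envelope
#' `1 + pac_depth * cos(phi_slow - pac_preferred_phase_rad)`; and (d)
#' `1/f^noise_exponent` Gaussian background. The sum is z-scored.
#'
#' @param duration_s duration in seconds; must match `respiration`.
#' @param fs sampling rate in Hz; must match `respiration`.
#' @param truth a [ground_truth()] record.
#' @param respiration a trace from [generate_respiration()].
#' @return a [prr_signal()] labelled "lfp" with attributes
#'   `slow_phase_rad` and `theta_phase_rad` (the generator's wrapped phases).
#' @export
generate_lfp <- function(duration_s, fs, truth, respiration) {
  stopifnot(inherits(truth, "prr_truth"), inherits(respiration, "prr_signal"))
  if (fs != respiration$fs)
    stop("invalid argument: fs mismatch between respiration and LFP",
         call. = FALSE)
  n <- as.integer(round(duration_s * fs))
  if (n != length(respiration$samples))
    stop("invalid argument: duration mismatch with respiration", call. = FALSE)
  phi_slow <- slow_phase_from_respiration(respiration, truth$prr_lag_rad)
  with_seed(truth$seed, {
    slow <- truth$prr_amp * cos(phi_slow)
    # theta: per-slow-cycle von Mises jitter, linearly interpolated
    cyc <- floor(phi_slow / (2 * pi))
    cyc <- cyc - min(cyc) + 1L
    n_cyc <- max(cyc)
    jit <- rvonmises(n_cyc + 1L, 0, truth$theta_lock_kappa)
    frac <- (phi_slow / (2 * pi)) - floor(phi_slow / (2 * pi))
    jit_t <- (1 - frac) * jit[cyc] + frac * jit[cyc + 1L]
    phi_theta <- truth$theta_freq_ratio * phi_slow + jit_t
    theta <- truth$theta_amp * cos(phi_theta)
    # gamma: band-limited carrier, envelope tied to slow phase
    gamma <- numeric(n)
    if (truth$gamma_amp > 0) {
      carrier <- stats::rnorm(n)
      carrier <- bandpass(prr_signal(carrier, fs), truth$gamma_band_hz[1],
                          truth$gamma_band_hz[2], order = 2)$samples
      carrier <- carrier / stats::sd(carrier)
      env <- 1 + truth$pac_depth *
        cos(phi_slow - truth$pac_preferred_phase_rad)
      gamma <- truth$gamma_amp * env * carrier
    }
    bg <- noise_1f(n, fs, truth$noise_exponent)
    out <- zscore_signal(prr_signal(slow + theta + gamma + bg, fs,
                                    label = "lfp"))
    attr(out, "slow_phase_rad") <- wrap_phase(phi_slow)
    attr(out, "theta_phase_rad") <- wrap_phase(phi_theta)
    out
  })
}

#' Biphasic mean-waveform template
#'
#' Negative Gaussian trough lobe followed by a smaller positive after-peak
#' lobe, sampled at `waveform_fs` over -1 to +1.5 ms around the trough. The
#' lobe parameters are calibrated internally (fixed-point iteration against
#' the same metric definitions [classify_unit()] uses) so that the measured
#' half-duration and trough-to-peak time of the template equal the requested
#' values.
#'
#' @param half_ms width of the trough at half depth (ms).
#' @param t2p_ms trough-to-peak time (ms).
#' @param waveform_fs sampling rate (default 30 kHz).
#' @param peak_amp amplitude of the positive after-peak (default 0.5).
#' @return numeric waveform vector (trough depth -1).
#' @export
waveform_template <- function(half_ms, t2p_ms, waveform_fs = 30000,
                              peak_amp = 0.5) {
  t <- seq(-1.0, 1.5, by = 1000 / waveform_fs)
  sigma2 <- max(0.05, 0.25 * t2p_ms)
  build <- function(s1, c2, A) {
    w <- -exp(-t^2 / (2 * s1^2)) + A * exp(-(t - c2)^2 / (2 * sigma2^2))
    w / abs(min(w))
  }
  calibrate <- function(A) {
    meas <- function(s1, c2) classify_unit(build(s1, c2, A), waveform_fs)
    s1 <- half_ms / 2.4
    c2 <- t2p_ms
    for (round in 1:6) {
      for (i in 1:12) {             # half-duration fixed point at current c2
        m <- meas(s1, c2)
        if (m$unclassifiable || abs(m$half_duration_ms - half_ms) < 1e-3)
          break
        s1 <- s1 * half_ms / m$half_duration_ms
      }
      # trough-to-peak rises with the peak-lobe center: grid scan + bisection
      f <- function(c2) {
        m <- meas(s1, c2)
        if (m$unclassifiable) NA_real_ else m$trough_to_peak_ms - t2p_ms
      }
      grid <- seq(0.03, t2p_ms + 0.5, by = 0.005)
      vals <- vapply(grid, f, numeric(1))
      if (any(!is.na(vals))) {
        c2 <- grid[which.min(abs(vals))]
        sw <- which(!is.na(vals[-1L]) & !is.na(vals[-length(vals)]) &
                      vals[-1L] > 0 & vals[-length(vals)] <= 0)
        if (length(sw)) {
          lo <- grid[sw[1L]]; hi <- grid[sw[1L] + 1L]
          for (i in 1:25) {
            mid <- (lo + hi) / 2
            fm <- f(mid)
            if (is.na(fm) || fm < 0) lo <- mid else hi <- mid
          }
          c2 <- (lo + hi) / 2
        }
      }
      m <- meas(s1, c2)
      if (!m$unclassifiable && abs(m$half_duration_ms - half_ms) < 2e-3 &&
          abs(m$trough_to_peak_ms - t2p_ms) < 2e-3) break
    }
    list(s1 = s1, c2 = c2, m = meas(s1, c2))
  }
  # escalate the peak-lobe amplitude until the calibrated waveform keeps a
  # prominent after-peak (>= 25% of trough depth), which noise cannot displace
  best <- NULL
  for (A in peak_amp * c(1, 1.6, 2.6, 4)) {
    cal <- calibrate(A)
    w <- build(cal$s1, cal$c2, A)
    best <- list(w = w, m = cal$m)
    itr <- which.min(w)
    if (!cal$m$unclassifiable && max(w[(itr + 1L):length(w)]) >= 0.25) break
  }
  best$w
}

#' Generate a phase-locked spike train
#'
#' Inhomogeneous point process with intensity proportional to
#' `exp(kappa * cos(phi(t) - preferred_phase_rad))`, normalized to the target
#' mean rate, realized by per-sample Bernoulli thinning and pruned to an
#' absolute refractory period. `kappa = 0` yields a (refractory-thinned)
#' homogeneous Poisson process.
#'
#' @param duration_s duration in seconds (0 gives an empty train).
#' @param rate_hz target mean rate (> 0).
#' @param phase_series [prr_phase_series()] driving the modulation (may be
#'   `NULL` when `kappa = 0`).
#' @param preferred_phase_rad phase of maximal discharge probability.
#' @param kappa von Mises concentration of the locking (>= 0).
#' @param refractory_ms absolute refractory period (default 2 ms).
#' @param seed integer seed.
#' @param unit_id identifier stored in the train.
#' @param waveform,waveform_fs optional mean waveform attached to the train.
#' @return a [prr_spiketrain()].
#' @export
generate_spike_train <- function(duration_s, rate_hz, phase_series = NULL,
                                 preferred_phase_rad = 0, kappa = 0,
                                 refractory_ms = 2, seed = NULL,
                                 unit_id = NA, waveform = NULL,
                                 waveform_fs = 30000) {
  if (rate_hz <= 0) stop("invalid argument: rate_hz must be > 0", call. = FALSE)
  if (kappa < 0) stop("invalid argument: kappa must be >= 0", call. = FALSE)
  if (rate_hz * refractory_ms / 1000 >= 1)
    stop("invalid argument: target rate unattainable under the refractory period",
         call. = FALSE)
  if (duration_s <= 0)
    return(prr_spiketrain(numeric(), unit_id, waveform, waveform_fs))
  fs <- if (!is.null(phase_series)) phase_series$fs else 1000
  n <- as.integer(round(duration_s * fs))
  lambda <- if (kappa > 0) {
    if (is.null(phase_series))
      stop("phase_series required when kappa > 0", call. = FALSE)
    if (length(phase_series$phase) < n)
      stop("phase series shorter than the requested duration", call. = FALSE)
    w <- exp(kappa * cos(phase_series$phase[seq_len(n)] - preferred_phase_rad))
    rate_hz * w / mean(w)
  } else rep(rate_hz, n)
  p <- lambda / fs
  if (max(p) >= 1)
    stop("invalid argument: modulation too strong for this sampling rate",
         call. = FALSE)
  times <- with_seed(seed, {
    hit <- which(stats::runif(n) < p)
    (hit - 1L) / fs
  })
  # absolute refractory period: greedy pruning
  if (length(times) > 1L) {
    refr <- refractory_ms / 1000
    keep <- times[1L]
    last <- times[1L]
    for (tt in times[-1L]) {
      if (tt - last >= refr) { keep <- c(keep, tt); last <- tt }
    }
    times <- keep
  }
  prr_spiketrain(times, unit_id, waveform, waveform_fs)
}

#' Session configuration for the generator
#'
#' Defaults reflect the recorded conditions the generator emulates: ~3.5 Hz
#' breathing with moderate cycle-to-cycle variability, a 2:1 locked theta
#' component, 80-100 Hz gamma modulated at the slow-rhythm peak, pyramidal
#' units at 1.7 Hz with broad waveforms and interneurons at 9.4 Hz with
#' narrow waveforms, and class-specific fractions of units entrained by the
#' slow rhythm and theta.
#'
#' @param duration_s session length (default 300 s).
#' @param fs LFP/respiration sampling rate (default 1000 Hz).
#' @param n_pyr,n_in unit counts per class (defaults 10, 3).
#' @param pyr_rate_hz,in_rate_hz class mean rates (defaults 1.7, 9.4 Hz).
#' @param immobility_fraction fraction of the session covered by immobility
#'   epochs (default 0.6; 1 covers the whole session).
#' @param p_prr,p_theta per-class probabilities that a unit is entrained by
#'   the slow rhythm / theta (named vectors with entries PYR and IN).
#' @param unit_kappa von Mises concentration of entrained units (default 1.5).
#' @param pyr_waveform_ms,in_waveform_ms c(half-duration, trough-to-peak) in
#'   ms for the class templates (defaults 0.47/0.31 and 0.25/0.20).
#' @param waveform_noise_sd SD of Gaussian noise added to the stored mean
#'   waveforms (fraction of trough depth; default 0.02).
#' @param rate_jitter_sdlog log-normal SD of per-unit rate spread (default
#'   0.2).
#' @param ... overrides passed to [ground_truth()] (e.g. `pac_depth`).
#' @return a list of class `prr_config`.
#' @export
session_config <- function(duration_s = 300, fs = 1000, n_pyr = 10L,
                           n_in = 3L, pyr_rate_hz = 1.7, in_rate_hz = 9.4,
                           immobility_fraction = 0.6,
                           p_prr = c(PYR = 0.26, IN = 0.58),
                           p_theta = c(PYR = 0.21, IN = 0.35),
                           unit_kappa = 1.5,
                           pyr_waveform_ms = c(0.47, 0.31),
                           in_waveform_ms = c(0.25, 0.20),
                           waveform_noise_sd = 0.02,
                           rate_jitter_sdlog = 0.2, ...) {
  stopifnot(duration_s > 0, fs >= 100,
            immobility_fraction > 0, immobility_fraction <= 1)
  structure(c(list(duration_s = duration_s, fs = fs, n_pyr = as.integer(n_pyr),
                   n_in = as.integer(n_in), pyr_rate_hz = pyr_rate_hz,
                   in_rate_hz = in_rate_hz,
                   immobility_fraction = immobility_fraction,
                   p_prr = p_prr, p_theta = p_theta, unit_kappa = unit_kappa,
                   pyr_waveform_ms = pyr_waveform_ms,
                   in_waveform_ms = in_waveform_ms,
                   waveform_noise_sd = waveform_noise_sd,
                   rate_jitter_sdlog = rate_jitter_sdlog),
              list(...)), class = "prr_config")
}

# Immobility epochs tiling a fraction of the session in 30 s blocks.
immobility_epochs <- function(duration_s, fraction, block_s = 30) {
  if (fraction >= 1) return(prr_epochs(0, duration_s))
  n_blocks <- ceiling(duration_s / block_s - 1e-9)
  starts <- (seq_len(n_blocks) - 1) * block_s
  ends <- pmin(starts + fraction * block_s, duration_s)
  keep <- (ends - starts) > 0.1
  prr_epochs(starts[keep], ends[keep])
}

#' Generate a complete synthetic session
#'
#' Builds respiration, LFP, immobility epochs and spike trains from one
#' configuration and seed; identical `(config, seed)` yield bit-identical
#' sessions. Each unit's class, rate, entrained rhythm, preferred phase and
#' concentration are recorded in `truth$unit_params`.
#'
#' @param config a [session_config()].
#' @param seed integer seed.
#' @return an object of class `prr_session`: list with `lfp`, `respiration`,
#'   `immobility`, `spike_trains`, `truth`.
#' @export
generate_session <- function(config = session_config(), seed = 1L) {
  stopifnot(inherits(config, "prr_config"))
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 4L))
  gt_args <- config[intersect(names(config), names(formals(ground_truth)))]
  gt_args$seed <- seeds[2L]
  truth <- do.call(ground_truth, gt_args)
  respiration <- generate_respiration(
    config$duration_s, config$fs,
    mean_freq_hz = truth$respiration_freq_hz, cv = truth$respiration_cv,
    seed = seeds[1L])
  lfp <- generate_lfp(config$duration_s, config$fs, truth, respiration)
  immobility <- immobility_epochs(config$duration_s,
                                  config$immobility_fraction)
  phases <- list(
    prr = prr_phase_series(attr(lfp, "slow_phase_rad"), config$fs,
                           band_hz = c(1, 5)),
    theta = prr_phase_series(attr(lfp, "theta_phase_rad"), config$fs,
                             band_hz = c(6, 12)),
    respiration = prr_phase_series(
      wrap_phase(attr(respiration, "phase_unwrapped_rad")), config$fs,
      band_hz = c(1, 10)))
  n_units <- config$n_pyr + config$n_in
  labels <- c(rep("PYR", config$n_pyr), rep("IN", config$n_in))
  pref_mean <- c(prr_PYR = -0.89, prr_IN = 1.34, theta_PYR = 0, theta_IN = 0)
  units <- with_seed(seeds[3L], {
    do.call(rbind, lapply(seq_len(n_units), function(k) {
      cl <- labels[k]
      rate <- (if (cl == "PYR") config$pyr_rate_hz else config$in_rate_hz) *
        stats::rlnorm(1, 0, config$rate_jitter_sdlog)
      u <- stats::runif(1)
      rhythm <- if (u < config$p_prr[[cl]]) "prr"
      else if (u < config$p_prr[[cl]] + config$p_theta[[cl]]) "theta"
      else "none"
      pref <- if (rhythm %in% c("prr", "theta"))
        rvonmises(1, pref_mean[[paste(rhythm, cl, sep = "_")]], 4) else 0
      data.frame(unit_id = sprintf("unit%02d", k), class = cl,
                 rate_hz = rate, coupled_rhythm = rhythm,
                 preferred_phase_rad = pref,
                 kappa = if (rhythm == "none") 0 else config$unit_kappa,
                 seed = sample.int(.Machine$integer.max - 1L, 1L),
                 waveform_seed = sample.int(.Machine$integer.max - 1L, 1L))
    }))
  })
  truth$unit_params <- units
  trains <- lapply(seq_len(n_units), function(k) {
    u <- units[k, ]
    wf_par <- if (u$class == "PYR") config$pyr_waveform_ms else
      config$in_waveform_ms
    wf <- waveform_template(wf_par[1], wf_par[2])
    if (config$waveform_noise_sd > 0)
      wf <- wf + with_seed(u$waveform_seed,
                           stats::rnorm(length(wf), 0,
                                        config$waveform_noise_sd))
    generate_spike_train(
      config$duration_s, u$rate_hz,
      phase_series = if (u$kappa > 0) phases[[u$coupled_rhythm]] else NULL,
      preferred_phase_rad = u$preferred_phase_rad, kappa = u$kappa,
      seed = u$seed, unit_id = u$unit_id, waveform = wf,
      waveform_fs = 30000)
  })
  structure(list(lfp = lfp, respiration = respiration,
                 immobility = immobility, spike_trains = trains,
                 truth = truth),
            class = "prr_session")
}

#' @export
print.prr_session <- function(x, ...) {
  cat(sprintf(
    "<prr_session> %.0f s @ %g Hz; %d immobility epoch(s) (%.0f s); %d units\n",
    signal_duration(x$lfp), x$lfp$fs, nrow(x$immobility),
    epoch_duration(x$immobility), length(x$spike_trains)))
  print(x$truth)
  invisible(x)
}
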