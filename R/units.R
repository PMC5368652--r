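#' @name units
#' @title Cell-type classification and spike-phase entrainment
#' @description Putative interneurons (IN) are separated from pyramidal cells
#'   (PYR) by spike-waveform shape: INs have narrower troughs (half-duration)
#'   and faster trough-to-peak times. Spike-phase locking to band-limited
#'   rhythms is assessed per unit with the mean resultant length and
#'   Rayleigh's test, restricted to units with at least 10 spikes inside the
#'   analysis epochs.
NULL

#' Waveform metrics and cell-type classification
#'
#' Locates the trough (global minimum, which must be negative-going and not
#' at an edge), measures the half-duration (width of the trough lobe at half
#' its depth, linearly interpolated) and the trough-to-peak time (trough to
#' the maximum after it), then classifies the unit as IN when
#' `trough_to_peak_ms < t2p_threshold_ms` and
#' `half_duration_ms < half_threshold_ms`, else PYR. The default thresholds
#' are midpoints between the reported group means (IN half-duration 0.25 ms
#' vs PYR 0.47 ms; IN trough-to-peak 0.20 ms vs PYR 0.31 ms).
#'
#' @param waveform numeric mean spike waveform (negative-going trough).
#' @param waveform_fs sampling rate of the waveform in Hz.
#' @param mean_rate_hz mean firing rate (carried through, not used by the
#'   waveform rule).
#' @param t2p_threshold_ms,half_threshold_ms classification thresholds
#'   (defaults 0.25 and 0.35 ms).
#' @return list with `label` ("PYR"/"IN", or NA when unclassifiable),
#'   `half_duration_ms`, `trough_to_peak_ms`, `mean_rate_hz`,
#'   `unclassifiable` (logical).
#' @export
classify_unit <- function(waveform, waveform_fs, mean_rate_hz = NA_real_,
                          t2p_threshold_ms = 0.25, half_threshold_ms = 0.35) {
  n <- length(waveform)
  unclass_result <- list(label = NA_character_, half_duration_ms = NA_real_,
                         trough_to_peak_ms = NA_real_,
                         mean_rate_hz = mean_rate_hz, unclassifiable = TRUE)
  if (n < 5L) return(unclass_result)
  # light binomial smoothing stabilizes the metrics against waveform noise
  w <- c(waveform[1L],
         0.25 * waveform[1:(n - 2L)] + 0.5 * waveform[2:(n - 1L)] +
           0.25 * waveform[3:n],
         waveform[n])
  # sub-sample refinement of an extremum by parabolic interpolation
  refine <- function(i) {
    if (i <= 1L || i >= n) return(i)
    d <- w[i - 1L] - 2 * w[i] + w[i + 1L]
    if (d == 0) return(i)
    i + 0.5 * (w[i - 1L] - w[i + 1L]) / d
  }
  itr <- which.min(w)
  # extracellular somatic spikes are trough-dominated; a waveform whose
  # positive excursion wins is inverted or otherwise not classifiable
  if (itr <= 1L || itr >= n || w[itr] >= 0 ||
      max(w) >= -w[itr]) return(unclass_result)
  trough <- w[itr]
  half <- trough / 2
  # crossings of the half-depth level on each side of the trough
  left <- NA_real_
  for (i in itr:2L) {
    if (w[i - 1L] > half && w[i] <= half) {
      left <- (i - 1L) + (w[i - 1L] - half) / (w[i - 1L] - w[i])
      break
    }
  }
  right <- NA_real_
  for (i in itr:(n - 1L)) {
    if (w[i] <= half && w[i + 1L] > half) {
      right <- i + (half - w[i]) / (w[i + 1L] - w[i])
      break
    }
  }
  if (is.na(left) || is.na(right)) return(unclass_result)
  half_ms <- (right - left) / waveform_fs * 1000
  ipk <- itr + which.max(w[(itr + 1L):n])
  if (ipk >= n || w[ipk] <= 0) return(unclass_result)
  t2p_ms <- (refine(ipk) - refine(itr)) / waveform_fs * 1000
  label <- if (t2p_ms < t2p_threshold_ms && half_ms < half_threshold_ms)
    "IN" else "PYR"
  list(label = label, half_duration_ms = half_ms, trough_to_peak_ms = t2p_ms,
       mean_rate_hz = mean_rate_hz, unclassifiable = FALSE)
}

#' Mean firing rate within epochs
#'
#' @param train a [prr_spiketrain()].
#' @param epochs a [prr_epochs()] with positive total duration.
#' @return rate in Hz (spike count inside epochs / total epoch duration).
#' @export
firing_rate <- function(train, epochs) {
  dur <- epoch_duration(epochs)
  if (dur <= 0)
    stop("epochs have zero total duration", call. = FALSE)
  n <- sum(vapply(seq_len(nrow(epochs)), function(k)
    sum(train$spike_times_s >= epochs$start_s[k] &
        train$spike_times_s < epochs$end_s[k]), numeric(1)))
  n / dur
}

#' Rhythm phase at each spike time
#'
#' For every spike inside the epochs, returns the phase at the nearest LFP
#' sample (no interpolation, preserving the original sampling alignment).
#' Spikes outside the phase series' span are skipped; their count is attached
#' as attribute `n_skipped`.
#'
#' @param train a [prr_spiketrain()].
#' @param phase a [prr_phase_series()] covering the epochs.
#' @param epochs optional [prr_epochs()]; `NULL` uses all spikes.
#' @return numeric vector of spike phases in `[-pi, pi)`.
#' @export
spike_phases <- function(train, phase, epochs = NULL) {
  t <- train$spike_times_s
  if (!is.null(epochs)) {
    keep <- rep(FALSE, length(t))
    for (k in seq_len(nrow(epochs)))
      keep <- keep | (t >= epochs$start_s[k] & t < epochs$end_s[k])
    t <- t[keep]
  }
  idx <- as.integer(round((t - phase$t0) * phase$fs)) + 1L
  ok <- idx >= 1L & idx <= length(phase$phase)
  out <- phase$phase[idx[ok]]
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Rayleigh test for circular uniformity
#'
#' Mean resultant length `R`, Rayleigh statistic `z = n R^2`, and the
#' standard approximation
#' `p = exp(sqrt(1 + 4n + 4(n^2 - (nR)^2)) - (1 + 2n))`.
#'
#' @param phases numeric vector of phases in radians (n >= 1).
#' @return list with `n`, `R`, `circ_mean_rad`, `z`, `p`.
#' @export
rayleigh_test <- function(phases) {
  n <- length(phases)
  if (n == 0L)
    stop("insufficient data: no phases supplied", call. = FALSE)
  zbar <- mean(exp(1i * phases))
  R <- Mod(zbar)
  z <- n * R^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - (n * R)^2)) - (1 + 2 * n))
  list(n = n, R = R, circ_mean_rad = Arg(zbar), z = z, p = min(p, 1))
}

#' Spike-phase coupling of one unit to one rhythm
#'
#' Collects the spike phases inside the epochs and, when at least
#' `min_spikes` spikes are available, computes the mean resultant length,
#' circular mean and Rayleigh p. Units with fewer spikes are flagged
#' `excluded` rather than tested.
#'
#' @param train a [prr_spiketrain()].
#' @param phase a [prr_phase_series()] of the rhythm.
#' @param epochs optional [prr_epochs()].
#' @param rhythm label recorded in the result (e.g. "prr").
#' @param min_spikes minimum spike count for a p-value (default 10).
#' @param alpha significance level (default 0.05).
#' @return a one-row data.frame: `unit_id`, `rhythm`, `n_spikes`, `R`,
#'   `circ_mean_rad`, `p`, `significant`, `excluded`.
#' @export
unit_coupling <- function(train, phase, epochs = NULL, rhythm = "",
                          min_spikes = 10L, alpha = 0.05) {
  ph <- spike_phases(train, phase, epochs)
  if (length(ph) < min_spikes)
    return(data.frame(unit_id = format(train$unit_id), rhythm = rhythm,
                      n_spikes = length(ph), R = NA_real_,
                      circ_mean_rad = NA_real_, p = NA_real_,
                      significant = FALSE, excluded = TRUE))
  rt <- rayleigh_test(ph)
  data.frame(unit_id = format(train$unit_id), rhythm = rhythm,
             n_spikes = rt$n, R = rt$R, circ_mean_rad = rt$circ_mean_rad,
             p = rt$p, significant = rt$p < alpha, excluded = FALSE)
}

#' Population summary of spike-phase entrainment
#'
#' Per cell class and rhythm: the fraction of (non-excluded) units with
#' significant phase locking; cross-rhythm overlap among significant units;
#' chi-square tests of PYR vs IN proportions with a Bonferroni-adjusted
#' critical p; and 18-bin circular histograms of preferred phases of the
#' significant units.
#'
#' @param results data.frame of per-unit/per-rhythm rows as returned by
#'   [unit_coupling()] (row-bound).
#' @param classes data.frame with `unit_id` and `label` ("PYR"/"IN").
#' @param alpha significance level used for the class-proportion tests
#'   before Bonferroni adjustment (default 0.05).
#' @return list with `fractions` (class x rhythm data.frame), `overlap`,
#'   `class_tests` (chi-square per rhythm, with `p_critical`),
#'   `phase_histograms`.
#' @export
population_summary <- function(results, classes, alpha = 0.05) {
  if (!nrow(results))
    stop("insufficient data: empty results", call. = FALSE)
  res <- merge(results, classes[, c("unit_id", "label")], by = "unit_id")
  res <- res[!res$excluded & !is.na(res$label), ]
  rhythms <- unique(res$rhythm)
  labs <- unique(res$label)
  fr <- do.call(rbind, lapply(labs, function(cl) {
    do.call(rbind, lapply(rhythms, function(rh) {
      sub <- res[res$label == cl & res$rhythm == rh, ]
      data.frame(label = cl, rhythm = rh, n = nrow(sub),
                 n_significant = sum(sub$significant),
                 fraction = if (nrow(sub)) mean(sub$significant) else NA_real_)
    }))
  }))
  # pairwise cross-rhythm overlap among significant units, per class
  overlap <- NULL
  if (length(rhythms) >= 2L) {
    combs <- utils::combn(rhythms, 2L)
    overlap <- do.call(rbind, lapply(labs, function(cl) {
      do.call(rbind, lapply(seq_len(ncol(combs)), function(j) {
        r1 <- combs[1L, j]; r2 <- combs[2L, j]
        s1 <- res$unit_id[res$label == cl & res$rhythm == r1 & res$significant]
        s2 <- res$unit_id[res$label == cl & res$rhythm == r2 & res$significant]
        data.frame(label = cl, rhythm_a = r1, rhythm_b = r2,
                   frac_a_also_b = if (length(s1)) mean(s1 %in% s2) else NA_real_,
                   frac_b_also_a = if (length(s2)) mean(s2 %in% s1) else NA_real_)
      }))
    }))
  }
  # chi-square PYR vs IN per rhythm, Bonferroni-adjusted critical p
  class_tests <- NULL
  if (all(c("PYR", "IN") %in% labs)) {
    p_critical <- alpha / length(rhythms)
    class_tests <- do.call(rbind, lapply(rhythms, function(rh) {
      tab <- vapply(c("PYR", "IN"), function(cl) {
        sub <- res[res$label == cl & res$rhythm == rh, ]
        c(sum(sub$significant), sum(!sub$significant))
      }, numeric(2))
      p <- if (any(colSums(tab) == 0)) NA_real_          # a class is absent
      else if (any(rowSums(tab) == 0)) 1                 # no outcome variation
      else suppressWarnings(stats::chisq.test(tab)$p.value)
      data.frame(rhythm = rh, p = p, p_critical = p_critical,
                 significant = !is.na(p) && p < p_critical)
    }))
  }
  hists <- lapply(stats::setNames(rhythms, rhythms), function(rh) {
    lapply(stats::setNames(labs, labs), function(cl) {
      ph <- res$circ_mean_rad[res$label == cl & res$rhythm == rh &
                              res$significant]
      tabulate(phase_bin(ph), 18L)
    })
  })
  list(fractions = fr, overlap = overlap, class_tests = class_tests,
       phase_histograms = hists)
}
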