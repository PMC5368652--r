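#' @name pipeline
#' @title Orchestration: simulate / analyse / report
#' @description [run_pipeline()] runs every analysis stage on one or more
#'   sessions — spectra and band peaks, LFP-respiration coherence, n:m
#'   phase-phase coupling with surrogates, phase-amplitude coupling,
#'   theta-rich epochs, unit classification and spike-phase entrainment —
#'   and assembles a machine-readable report. Per-session (per-animal)
#'   averages are computed before any group statistic. Group comparisons use
#'   a Shapiro-Wilk normality gate: t-tests when both samples (or the paired
#'   differences) pass, otherwise Mann-Whitney / Wilcoxon signed-rank, all
#'   two-tailed with Bonferroni-adjusted critical p for families of tests.
NULL

#' Analysis configuration
#'
#' Band definitions and stage parameters used throughout the pipeline.
#'
#' @param prr_band_hz slow-rhythm band (default 1-5 Hz).
#' @param theta_band_hz theta band (default 6-12 Hz).
#' @param gamma_band_hz broad gamma band (default 30-100 Hz).
#' @param high_gamma_band_hz modulated gamma band for the headline MI
#'   (default 80-100 Hz).
#' @param respiration_band_hz filter applied to the respiration trace before
#'   phase extraction (default 1-10 Hz).
#' @param psd_chunk_s,psd_bandwidth_hz multitaper parameters (defaults 5 s,
#'   1 Hz).
#' @param mi_window_s modulation-index window (default 4 s).
#' @param rnm_m_max maximum acceleration factor (default 25).
#' @param rnm_segments,rnm_segment_s segment count and length for R_n:m
#'   (defaults 25, 10 s).
#' @param edge_trim_s seconds trimmed from the recording edges before epoch
#'   masking (default 1).
#' @param min_epoch_s epochs shorter than this are excluded from coupling
#'   analyses (default 2 s, two slow-rhythm cycles at the 1 Hz band edge).
#' @param min_spikes minimum spikes for a unit-level p-value (default 10).
#' @param alpha significance level (default 0.05).
#' @param run_comodulogram compute the full comodulogram per session
#'   (default FALSE; the single-band MIs are always computed).
#' @param run_theta_restricted recompute PAC inside extracted theta epochs
#'   (default FALSE).
#' @return a list of class `prr_analysis_config`.
#' @export
analysis_config <- function(prr_band_hz = c(1, 5), theta_band_hz = c(6, 12),
                            gamma_band_hz = c(30, 100),
                            high_gamma_band_hz = c(80, 100),
                            respiration_band_hz = c(1, 10),
                            psd_chunk_s = 5, psd_bandwidth_hz = 1,
                            mi_window_s = 4, rnm_m_max = 25L,
                            rnm_segments = 25L, rnm_segment_s = 10,
                            edge_trim_s = 1, min_epoch_s = 2,
                            min_spikes = 10L, alpha = 0.05,
                            run_comodulogram = FALSE,
                            run_theta_restricted = FALSE) {
  if (prr_band_hz[2] > theta_band_hz[1])
    stop("prr and theta bands must not overlap", call. = FALSE)
  stopifnot(psd_chunk_s > 0, mi_window_s > 0, rnm_segment_s > 0,
            length(prr_band_hz) == 2L, length(theta_band_hz) == 2L)
  structure(as.list(environment()), class = "prr_analysis_config")
}

# Drop epochs shorter than min_s and clip away the recording edges.
prepare_epochs <- function(epochs, x, trim_s, min_s) {
  lo <- x$t0 + trim_s
  hi <- x$t0 + signal_duration(x) - trim_s
  a <- pmax(epochs$start_s, lo)
  b <- pmin(epochs$end_s, hi)
  keep <- (b - a) >= min_s
  prr_epochs(a[keep], b[keep])
}

#' Two-group comparison with a normality gate
#'
#' Shapiro-Wilk on each sample (or on the paired differences); when normality
#' is not rejected at `alpha_normality`, a two-tailed t-test is used,
#' otherwise the Mann-Whitney U test (independent) or Wilcoxon signed-rank
#' test (paired).
#'
#' @param x,y numeric samples.
#' @param paired paired design (default FALSE).
#' @param alpha_normality Shapiro-Wilk gate level (default 0.05).
#' @return list with `test` ("t" or "wilcoxon"), `statistic`, `p`,
#'   `normality_p`, `paired`.
#' @export
compare_groups <- function(x, y, paired = FALSE, alpha_normality = 0.05) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (paired && length(x) != length(y))
    stop("paired samples must have equal length", call. = FALSE)
  norm_p <- tryCatch({
    if (paired) stats::shapiro.test(x - y)$p.value
    else min(stats::shapiro.test(x)$p.value, stats::shapiro.test(y)$p.value)
  }, error = function(e) 0)
  normal <- is.finite(norm_p) && norm_p > alpha_normality
  if (normal) {
    tt <- stats::t.test(x, y, paired = paired)
    list(test = "t", statistic = unname(tt$statistic), p = tt$p.value,
         normality_p = norm_p, paired = paired)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, paired = paired))
    list(test = "wilcoxon", statistic = unname(wt$statistic), p = wt$p.value,
         normality_p = norm_p, paired = paired)
  }
}

analyse_one_session <- function(session, config, seed) {
  lfp <- zscore_signal(session$lfp)
  fs <- lfp$fs
  epochs <- prepare_epochs(session$immobility, lfp, config$edge_trim_s,
                           config$min_epoch_s)
  out <- list()
  # -- spectra and band peaks
  psd <- multitaper_psd(lfp, epochs, config$psd_chunk_s,
                        config$psd_bandwidth_hz)
  psd_n <- normalize_1f(psd)
  out$psd <- psd_n
  out$band_peaks <- list(
    prr = band_peak(psd_n, config$prr_band_hz),
    theta = band_peak(psd_n, config$theta_band_hz),
    gamma = band_peak(psd_n, config$gamma_band_hz),
    gamma_raw = band_peak(psd, config$gamma_band_hz))
  # -- coherence with respiration
  if (!is.null(session$respiration)) {
    out$respiration_psd <- normalize_1f(
      multitaper_psd(session$respiration, epochs, config$psd_chunk_s,
                     config$psd_bandwidth_hz))
    out$respiration_peak <- band_peak(out$respiration_psd,
                                      config$prr_band_hz)
    coh <- coherence(lfp, session$respiration, epochs)
    out$coherence <- list(peak_coh = coh$peak_coh,
                          peak_freq_hz = coh$peak_freq_hz)
  } else {
    out$notes <- c(out$notes,
                   "respiration trace absent: coherence and respiration-phase stages skipped")
  }
  # -- phases
  phi_prr <- analytic_phase(bandpass(lfp, config$prr_band_hz[1],
                                     config$prr_band_hz[2]))
  phi_theta <- analytic_phase(bandpass(lfp, config$theta_band_hz[1],
                                       config$theta_band_hz[2]))
  # -- n:m phase-phase coupling + surrogate
  out$rnm <- tryCatch({
    real <- rnm(phi_theta, phi_prr, epochs, m_values = 1:config$rnm_m_max,
                n_segments = config$rnm_segments,
                segment_len_s = config$rnm_segment_s, seed = seed)
    rnm_surrogate(phi_theta, phi_prr, epochs, m_values = 1:config$rnm_m_max,
                  seed = seed + 1L, real = real)
  }, error = function(e) { out$notes <<- c(out$notes, conditionMessage(e)); NULL })
  # -- phase-amplitude coupling (single-band MIs)
  out$pac <- list(
    prr_gamma = band_mi(lfp, epochs, config$prr_band_hz,
                        config$high_gamma_band_hz, config$mi_window_s),
    theta_gamma = band_mi(lfp, epochs, config$theta_band_hz,
                          config$high_gamma_band_hz, config$mi_window_s))
  out$pac$ratio <- out$pac$prr_gamma$mi / out$pac$theta_gamma$mi
  if (isTRUE(config$run_comodulogram))
    out$comodulogram <- comodulogram(lfp, epochs,
                                     window_s = config$mi_window_s)
  # -- theta-rich epochs
  out$theta_epochs <- tryCatch(extract_theta_epochs(lfp),
                               error = function(e) NULL)
  if (!is.null(out$theta_epochs)) {
    out$theta_epoch_fraction <-
      epoch_duration(out$theta_epochs) / signal_duration(lfp)
    if (isTRUE(config$run_theta_restricted))
      out$pac_theta_restricted <- tryCatch(
        pac_in_theta_epochs(lfp, out$theta_epochs,
                            window_s = config$mi_window_s,
                            allow_short_window = TRUE),
        error = function(e) NULL)
  }
  # -- units
  if (length(session$spike_trains)) {
    rhythms <- list(prr = phi_prr, theta = phi_theta)
    if (!is.null(session$respiration)) {
      resp_f <- bandpass(session$respiration, config$respiration_band_hz[1],
                         config$respiration_band_hz[2])
      rhythms$respiration <- analytic_phase(resp_f)
    }
    classes <- do.call(rbind, lapply(session$spike_trains, function(tr) {
      cl <- classify_unit(tr$waveform, tr$waveform_fs,
                          mean_rate_hz = tryCatch(firing_rate(tr, epochs),
                                                  error = function(e) NA_real_))
      data.frame(unit_id = format(tr$unit_id), label = cl$label,
                 half_duration_ms = cl$half_duration_ms,
                 trough_to_peak_ms = cl$trough_to_peak_ms,
                 rate_hz = cl$mean_rate_hz,
                 unclassifiable = cl$unclassifiable)
    }))
    coupling <- do.call(rbind, lapply(session$spike_trains, function(tr) {
      do.call(rbind, lapply(names(rhythms), function(rh)
        unit_coupling(tr, rhythms[[rh]], epochs, rhythm = rh,
                      min_spikes = config$min_spikes, alpha = config$alpha)))
    }))
    out$unit_classes <- classes
    out$unit_coupling <- coupling
  }
  out
}

#' Run the full analysis pipeline
#'
#' @param sessions a `prr_session`, a directory path, or a list of either.
#' @param config an [analysis_config()].
#' @param seed integer seed for the seeded stages (R_n:m segment placement
#'   and surrogates).
#' @return a `prr_report`: list with `sessions` (per-session stage outputs),
#'   `group` (cross-session statistics when n >= 2, and pooled unit
#'   statistics), `config`, `seed`, `package_version`.
#' @export
run_pipeline <- function(sessions, config = analysis_config(), seed = 1L) {
  if (inherits(sessions, "prr_session") || is.character(sessions))
    sessions <- list(sessions)
  sessions <- lapply(sessions, function(s)
    if (is.character(s)) read_session(s) else s)
  per <- lapply(seq_along(sessions), function(i)
    analyse_one_session(sessions[[i]], config, seed = seed + 1000L * i))
  names(per) <- sprintf("session%02d", seq_along(per))
  group <- list()
  # group-level phase-phase comparison
  profs <- Filter(Negate(is.null), lapply(per, `[[`, "rnm"))
  if (length(profs) >= 3L)
    group$rnm_comparison <- compare_rnm(profs)
  # group-level MI comparison (slow-rhythm vs theta modulation of gamma)
  mi_prr <- vapply(per, function(s) s$pac$prr_gamma$mi, numeric(1))
  mi_theta <- vapply(per, function(s) s$pac$theta_gamma$mi, numeric(1))
  group$mi <- list(prr_gamma = mi_prr, theta_gamma = mi_theta,
                   ratio = mi_prr / mi_theta)
  if (length(per) >= 3L)
    group$mi_comparison <- compare_groups(mi_prr, mi_theta, paired = TRUE)
  # pooled unit statistics
  cls <- do.call(rbind, Filter(Negate(is.null),
                               lapply(per, `[[`, "unit_classes")))
  cpl <- do.call(rbind, Filter(Negate(is.null),
                               lapply(per, `[[`, "unit_coupling")))
  if (!is.null(cls) && nrow(cls)) {
    group$unit_classes <- cls
    rates_pyr <- cls$rate_hz[cls$label == "PYR" & !is.na(cls$label)]
    rates_in <- cls$rate_hz[cls$label == "IN" & !is.na(cls$label)]
    if (length(rates_pyr) >= 3L && length(rates_in) >= 3L)
      group$rate_comparison <- c(compare_groups(rates_in, rates_pyr),
                                 list(mean_in = mean(rates_in),
                                      mean_pyr = mean(rates_pyr)))
    if (!is.null(cpl) && nrow(cpl))
      group$population <- population_summary(cpl, cls, alpha = config$alpha)
  }
  structure(list(sessions = per, group = group, config = unclass(config),
                 seed = seed,
                 package_version = as.character(utils::packageVersion("prr"))),
            class = "prr_report")
}

#' @export
print.prr_report <- function(x, ...) {
  cat(sprintf("<prr_report> %d session(s), seed %d, prr %s\n",
              length(x$sessions), x$seed, x$package_version))
  for (nm in names(x$sessions)) {
    s <- x$sessions[[nm]]
    cat(sprintf(
      " %s: PRR peak %.2f Hz; theta peak %.2f Hz; MI prr-gamma %.4g, theta-gamma %.4g%s\n",
      nm, s$band_peaks$prr$peak_freq_hz, s$band_peaks$theta$peak_freq_hz,
      s$pac$prr_gamma$mi, s$pac$theta_gamma$mi,
      if (!is.null(s$rnm))
        sprintf("; R_n:m max at m = %d", s$rnm$m_values[which.max(s$rnm$R)])
      else ""))
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' `report.json` holds every statistic plus the configuration; per-stage
#' CSVs (`rnm.csv`, `units.csv`, `band_peaks.csv`) hold the tabular outputs.
#'
#' @param report a `prr_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  slim <- report
  for (nm in names(slim$sessions)) {
    slim$sessions[[nm]]$psd <- NULL
    slim$sessions[[nm]]$respiration_psd <- NULL
    if (!is.null(slim$sessions[[nm]]$comodulogram))
      slim$sessions[[nm]]$comodulogram <-
        list(max_mi = max(slim$sessions[[nm]]$comodulogram$mi))
    if (!is.null(slim$sessions[[nm]]$theta_epochs))
      slim$sessions[[nm]]$theta_epochs <-
        as.data.frame(slim$sessions[[nm]]$theta_epochs)
    if (!is.null(slim$sessions[[nm]]$rnm))
      slim$sessions[[nm]]$rnm <- slim$sessions[[nm]]$rnm[
        c("m_values", "R", "R_surrogate", "n_segments", "segment_len_s")]
  }
  jsonlite::write_json(
    lapply(unclass(slim), function(z) z),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE, null = "null", na = "null")
  # tabular outputs
  rnm_rows <- list()
  for (nm in names(report$sessions)) {
    r <- report$sessions[[nm]]$rnm
    if (!is.null(r))
      rnm_rows[[nm]] <- data.frame(session = nm, m = r$m_values, R_real = r$R,
                                   R_surrogate = r$R_surrogate)
  }
  if (length(rnm_rows))
    utils::write.csv(do.call(rbind, rnm_rows), file.path(dir, "rnm.csv"),
                     row.names = FALSE)
  if (!is.null(report$group$unit_classes))
    utils::write.csv(report$group$unit_classes, file.path(dir, "units.csv"),
                     row.names = FALSE)
  peaks <- do.call(rbind, lapply(names(report$sessions), function(nm) {
    bp <- report$sessions[[nm]]$band_peaks
    data.frame(session = nm, band = names(bp),
               peak_freq_hz = vapply(bp, `[[`, numeric(1), "peak_freq_hz"),
               peak_power = vapply(bp, `[[`, numeric(1), "peak_power"),
               band_power = vapply(bp, `[[`, numeric(1), "band_power"))
  }))
  utils::write.csv(peaks, file.path(dir, "band_peaks.csv"), row.names = FALSE)
  invisible(dir)
}
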