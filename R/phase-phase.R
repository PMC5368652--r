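#' @name phase_phase
#' @title n:m phase-phase coupling with time-shift surrogates
#' @description Quantifies integer-ratio locking between a slow rhythm
#'   (respiration-entrained, 1-5 Hz) and theta (6-12 Hz). The slow phase is
#'   accelerated by integer factors m = 1..25 and, for each m, the mean
#'   resultant length of the phase difference `phi_fast - m * phi_slow` is
#'   computed over randomly placed 10 s segments. Time-shift surrogates
#'   (circular shift of the slow phase by 5-10 s) provide the paired control.
NULL

#' Joint phase histogram on an 18 x 18 grid
#'
#' 2-D probability histogram of (slow-phase bin, fast-phase bin) over all
#' epoch-masked samples; 18 bins of 20 degrees per axis. n:m locking shows as
#' diagonal stripes of slope m.
#'
#' @param phi_slow,phi_fast [prr_phase_series()]s of equal `fs` and length.
#' @param epochs optional [prr_epochs()].
#' @param n_bins bins per axis (default 18).
#' @return matrix `n_bins x n_bins` (rows: slow-phase bin, columns:
#'   fast-phase bin) of probabilities summing to 1.
#' @export
joint_phase_histogram <- function(phi_slow, phi_fast, epochs = NULL,
                                  n_bins = 18L) {
  if (phi_slow$fs != phi_fast$fs ||
      length(phi_slow$phase) != length(phi_fast$phase))
    stop("phase series must share fs and duration", call. = FALSE)
  ps <- masked_values(phi_slow, epochs)
  pf <- masked_values(phi_fast, epochs)
  if (!length(ps))
    stop("insufficient data: epochs select no samples", call. = FALSE)
  bs <- phase_bin(ps, n_bins)
  bf <- phase_bin(pf, n_bins)
  h <- matrix(0, n_bins, n_bins)
  tab <- table(factor(bs, levels = seq_len(n_bins)),
               factor(bf, levels = seq_len(n_bins)))
  h[] <- as.numeric(tab)
  h / sum(h)
}

# Mean resultant length of a phase-difference series at acceleration factors m.
rnm_of_segment <- function(phi_fast, phi_slow, m_values) {
  ef <- exp(1i * phi_fast)
  es <- exp(1i * phi_slow)
  vapply(m_values, function(m) Mod(mean(ef * es^(-m))), numeric(1))
}

# Sample-index start positions where a full window fits inside an epoch.
eligible_starts <- function(x, epochs, win_n) {
  segs <- mask_epochs(x, epochs)
  starts <- integer()
  for (s in segs) {
    i0 <- as.integer(round((s$t0 - x$t0) * x$fs)) + 1L
    nmax <- length(series_values(s)) - win_n
    if (nmax >= 0L) starts <- c(starts, i0 + 0:nmax)
  }
  starts
}

#' R_n:m phase-phase coupling profile
#'
#' For each acceleration factor m, computes the length of the mean vector of
#' phase differences between the fast phase and the m-accelerated slow phase,
#' averaged over `n_segments` randomly placed segments of `segment_len_s`
#' seconds drawn entirely within the epochs (without replacement when enough
#' distinct positions exist).
#'
#' @param phi_fast fast-rhythm (theta) [prr_phase_series()].
#' @param phi_slow slow-rhythm [prr_phase_series()], same fs and length.
#' @param epochs optional [prr_epochs()].
#' @param m_values integer acceleration factors (default 1:25).
#' @param n_segments number of random segments (default 25).
#' @param segment_len_s segment length in seconds (default 10).
#' @param seed integer seed for segment placement (optional).
#' @return a `prr_rnm` profile: list with `m_values`, `R`, `R_surrogate`
#'   (NA until [rnm_surrogate()] fills it), `n_segments`, `segment_len_s`.
#' @export
rnm <- function(phi_fast, phi_slow, epochs = NULL, m_values = 1:25,
                n_segments = 25L, segment_len_s = 10, seed = NULL) {
  if (phi_fast$fs != phi_slow$fs ||
      length(phi_fast$phase) != length(phi_slow$phase))
    stop("phase series must share fs and duration", call. = FALSE)
  if (is.null(epochs))
    epochs <- prr_epochs(phi_fast$t0, phi_fast$t0 + signal_duration(phi_fast))
  win_n <- as.integer(round(segment_len_s * phi_fast$fs))
  starts <- eligible_starts(phi_fast, epochs, win_n)
  if (!length(starts))
    stop(sprintf("insufficient data: no %g s window fits in any epoch",
                 segment_len_s), call. = FALSE)
  sel <- with_seed(seed,
    sample(starts, n_segments, replace = length(starts) < n_segments))
  Rmat <- vapply(sel, function(i0) {
    idx <- i0:(i0 + win_n - 1L)
    rnm_of_segment(phi_fast$phase[idx], phi_slow$phase[idx], m_values)
  }, numeric(length(m_values)))
  structure(list(m_values = as.integer(m_values),
                 R = rowMeans(Rmat),
                 R_surrogate = rep(NA_real_, length(m_values)),
                 n_segments = as.integer(n_segments),
                 segment_len_s = segment_len_s,
                 segment_starts = sel),
            class = "prr_rnm")
}

#' @export
print.prr_rnm <- function(x, ...) {
  i <- which.max(x$R)
  cat(sprintf("<prr_rnm> m = %d..%d; max R = %.3f at m = %d (%d segments of %g s)%s\n",
              min(x$m_values), max(x$m_values), x$R[i], x$m_values[i],
              x$n_segments, x$segment_len_s,
              if (all(is.na(x$R_surrogate))) "" else "; surrogate attached"))
  invisible(x)
}

#' Time-shift surrogate R_n:m profile
#'
#' Repeats the R_n:m computation after circularly shifting the slow-phase
#' series by a random offset drawn uniformly from `shift_range_s` seconds, a
#' manipulation that destroys genuine temporal coupling while preserving each
#' series' own statistics. With `n_surrogates > 1` the surrogate profile is
#' the average over independent shifts (an extension beyond the single matched
#' surrogate used for the paired comparison).
#'
#' @inheritParams rnm
#' @param real optional `prr_rnm` computed on the same data; when supplied,
#'   the surrogate uses the same segment placements (matched pairing) and the
#'   returned profile carries its `R` values.
#' @param shift_range_s length-2 numeric, shift range in seconds
#'   (default `c(5, 10)`).
#' @param n_surrogates number of independent shifts averaged (default 1).
#' @return a `prr_rnm` with the `R_surrogate` field populated.
#' @export
rnm_surrogate <- function(phi_fast, phi_slow, epochs = NULL, m_values = 1:25,
                          n_segments = 25L, segment_len_s = 10,
                          shift_range_s = c(5, 10), n_surrogates = 1L,
                          seed = NULL, real = NULL) {
  if (signal_duration(phi_slow) < max(shift_range_s))
    stop("insufficient data: recording shorter than the maximum shift",
         call. = FALSE)
  if (is.null(real))
    real <- rnm(phi_fast, phi_slow, epochs, m_values, n_segments,
                segment_len_s, seed = seed)
  win_n <- as.integer(round(segment_len_s * phi_fast$fs))
  n <- length(phi_slow$phase)
  acc <- with_seed(seed, {
    a <- 0
    for (r in seq_len(n_surrogates)) {
      shift_n <- as.integer(round(stats::runif(1, shift_range_s[1],
                                               shift_range_s[2]) * phi_slow$fs))
      shifted <- phi_slow
      shifted$phase <- phi_slow$phase[((seq_len(n) - 1L + shift_n) %% n) + 1L]
      Rmat <- vapply(real$segment_starts, function(i0) {
        idx <- i0:(i0 + win_n - 1L)
        rnm_of_segment(phi_fast$phase[idx], shifted$phase[idx], m_values)
      }, numeric(length(m_values)))
      a <- a + rowMeans(Rmat)
    }
    a / n_surrogates
  })
  real$R_surrogate <- acc
  real
}

#' Paired comparison of real vs surrogate R_n:m profiles
#'
#' Paired two-tailed t-test of R against the matched surrogate at the factor
#' `m_star`; by default `m_star` is the argmax of the group-mean real profile.
#'
#' @param profiles list of `prr_rnm` objects (one per animal/session) with
#'   surrogate fields populated.
#' @param m_star acceleration factor at which to test; `NULL` (default) uses
#'   the argmax of the group-mean real profile.
#' @return list with `m_star`, `t`, `df`, `p`, `mean_real`, `mean_surrogate`,
#'   `n`.
#' @export
compare_rnm <- function(profiles, m_star = NULL) {
  if (length(profiles) < 3L)
    stop("insufficient data: need >= 3 paired profiles", call. = FALSE)
  m_values <- profiles[[1L]]$m_values
  R <- vapply(profiles, `[[`, numeric(length(m_values)), "R")
  S <- vapply(profiles, `[[`, numeric(length(m_values)), "R_surrogate")
  if (anyNA(S))
    stop("surrogate profiles missing: run rnm_surrogate() first", call. = FALSE)
  if (is.null(m_star)) m_star <- m_values[which.max(rowMeans(R))]
  i <- match(m_star, m_values)
  d <- R[i, ] - S[i, ]
  if (stats::sd(d) == 0) {
    p <- if (all(d == 0)) 1 else 0
    return(list(m_star = m_star, t = NA_real_, df = length(d) - 1L, p = p,
                mean_real = mean(R[i, ]), mean_surrogate = mean(S[i, ]),
                n = length(d)))
  }
  tt <- stats::t.test(R[i, ], S[i, ], paired = TRUE)
  list(m_star = m_star, t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_real = mean(R[i, ]), mean_surrogate = mean(S[i, ]),
       n = length(d))
}
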