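test_that("modulation index hits its analytic bounds exactly", {
  fs <- 1000
  set.seed(1)
  phi <- prr_phase_series(runif(20000, -pi, pi), fs)

  # uniform envelope -> MI = 0
  flat <- prr_amplitude_series(rep(1.7, 20000), fs)
  r0 <- modulation_index(phi, flat)
  expect_equal(r0$mi, 0)
  expect_equal(sum(r0$distribution$mean_amp), 1)

  # all envelope mass in one bin -> MI = 1 (KL = log N)
  b <- phase_bin(phi$phase)
  spike <- prr_amplitude_series(as.numeric(b == 7) * 2.2, fs)
  expect_equal(modulation_index(phi, spike)$mi, 1)

  expect_error(modulation_index(phi, prr_amplitude_series(rep(0, 20000), fs)),
               "degenerate")
})

test_that("MI matches the closed-form cosine oracle at dense sampling", {
  fs <- 1000
  n <- 1e6
  phi <- prr_phase_series(seq(-pi, pi - 2 * pi / n, length.out = n), fs)
  for (d in c(0.25, 0.5)) {
    env <- prr_amplitude_series(1 + d * cos(phi$phase), fs)
    got <- modulation_index(phi, env)$mi
    expect_equal(got, mi_cosine_oracle(d), tolerance = 1e-4)
  }
})

test_that("MI is invariant to envelope rescaling and phase rotation", {
  fs <- 1000
  set.seed(2)
  phi <- prr_phase_series(runif(50000, -pi, pi), fs)
  env <- prr_amplitude_series(1 + 0.4 * cos(phi$phase - 0.8) +
                                0.05 * abs(rnorm(50000)), fs)
  base <- modulation_index(phi, env)$mi
  expect_equal(modulation_index(phi, prr_amplitude_series(env$envelope * 37, fs))$mi,
               base, tolerance = 1e-12)
  rot <- prr_phase_series(wrap_phase(phi$phase + 2 * pi / 18 * 5), fs)
  expect_equal(modulation_index(rot, env)$mi, base, tolerance = 1e-12)
  expect_true(base >= 0 && base <= 1)
})

test_that("preferred coupling phase: point mass, antipodal flag, cosine recovery", {
  centers <- phase_bin_centers()
  # all mass in the bin centred nearest 0
  w <- numeric(18); w[which.min(abs(centers))] <- 1
  p <- preferred_coupling_phase(data.frame(bin_center_rad = centers, mean_amp = w))
  expect_true(p$defined)
  expect_equal(p$phase_rad, centers[which.min(abs(centers))])

  # antipodal split: undefined
  w2 <- numeric(18)
  w2[which.min(abs(centers - pi / 2))] <- 0.5
  w2[which.min(abs(centers + pi / 2))] <- 0.5
  p2 <- preferred_coupling_phase(data.frame(bin_center_rad = centers, mean_amp = w2))
  expect_false(p2$defined)

  # envelope 1 + 0.5 cos(phi - 1)
  n <- 1e5
  fs <- 1000
  phi <- prr_phase_series(seq(-pi, pi, length.out = n), fs)
  env <- prr_amplitude_series(1 + 0.5 * cos(phi$phase - 1.0), fs)
  d <- modulation_index(phi, env)$distribution
  p3 <- preferred_coupling_phase(d)
  expect_lt(abs(p3$phase_rad - 1.0), 0.05)
})

test_that("MI rises monotonically with generated PAC depth", {
  fs <- 1000
  depths <- c(0, 0.25, 0.5, 1.0)
  mi_by_depth <- sapply(depths, function(d) {
    mean(sapply(1:10, function(s) {
      r <- generate_respiration(30, fs, 3.5, 0.1, seed = 100 * s)
      lfp <- generate_lfp(30, fs,
                          ground_truth(pac_depth = d, seed = 100 * s + 1), r)
      band_mi(lfp)$mi
    }))
  })
  expect_true(all(diff(mi_by_depth) > 0))
})

test_that("PAC preferred phase recovers the generator's target phases", {
  fs <- 1000
  for (mu in c(-pi / 2, 0, pi / 2, pi)) {
    est <- sapply(1:6, function(s) {
      r <- generate_respiration(40, fs, 3.5, 0.1, seed = 1000 + s)
      lfp <- generate_lfp(40, fs,
                          ground_truth(pac_depth = 0.8, gamma_amp = 0.6,
                                       pac_preferred_phase_rad = mu,
                                       seed = 2000 + s), r)
      band_mi(lfp)$preferred$phase_rad
    })
    err <- Arg(mean(exp(1i * (est - mu))))
    expect_lt(abs(err), 0.15)
  }
})

test_that("comodulogram peaks at the generated phase/amplitude bands", {
  fs <- 1000
  r <- generate_respiration(60, fs, 3.5, 0.1, seed = 31)
  lfp <- generate_lfp(60, fs, ground_truth(pac_depth = 0.5, seed = 32), r)
  cm <- comodulogram(lfp, amp_freqs_hz = seq(30, 150, by = 5))
  i <- arrayInd(which.max(cm$mi), dim(cm$mi))
  expect_true(cm$phase_freqs_hz[i[1]] >= 3 && cm$phase_freqs_hz[i[1]] <= 4)
  expect_true(cm$amp_freqs_hz[i[2]] >= 75 && cm$amp_freqs_hz[i[2]] <= 105)
  expect_true(all(cm$mi >= 0 & cm$mi <= 1))

  # without PAC the coupled region drops to the estimator's bias floor
  lfp0 <- generate_lfp(60, fs, ground_truth(pac_depth = 0, seed = 33), r)
  cm0 <- comodulogram(lfp0, amp_freqs_hz = seq(30, 150, by = 5))
  reg <- function(z) mean(z$mi[z$phase_freqs_hz %in% 3:4,
                               z$amp_freqs_hz >= 75 & z$amp_freqs_hz <= 105])
  expect_lt(reg(cm0), reg(cm) / 3)
})

test_that("window averaging: identical windows give the window MI", {
  fs <- 500
  t <- (seq_len(8 * fs) - 1) / fs
  x <- prr_signal(rep(cos(2 * pi * 3.5 * t[1:(4 * fs)]), 2) +
                    0.3 * rep(cos(2 * pi * 90 * t[1:(4 * fs)]) *
                                (1 + 0.5 * cos(2 * pi * 3.5 * t[1:(4 * fs)])), 2),
                  fs)
  b <- band_mi(x, phase_band_hz = c(1, 5), amp_band_hz = c(80, 100))
  expect_identical(b$n_windows, 2L)
  one <- band_mi(prr_signal(x$samples[1:(4 * fs)], fs),
                 phase_band_hz = c(1, 5), amp_band_hz = c(80, 100))
  expect_equal(b$mi, one$mi, tolerance = 0.02)
})

test_that("theta-epoch extraction flags bursts, adapts to stationary signals", {
  fs <- 1000
  set.seed(41)
  # stationary 1/f-ish noise: small detected fraction
  x <- generate_lfp(200, fs, ground_truth(prr_amp = 0, theta_amp = 0,
                                          gamma_amp = 0, seed = 42),
                    generate_respiration(200, fs, 3.5, 0.1, seed = 43))
  ep <- extract_theta_epochs(x)
  expect_lt(epoch_duration(ep) / 200, 0.05)

  # bursts at 5x amplitude covering 1% of a 600 s trace
  n <- 600 * fs
  bg <- x$samples[seq_len(200 * fs)]
  y <- c(bg, bg, bg)
  t <- (seq_len(n) - 1) / fs
  burst_starts <- seq(50, 550, length.out = 3)
  for (b0 in burst_starts) {
    idx <- which(t >= b0 & t < b0 + 2)
    y[idx] <- y[idx] + 5 * sd(bg) * sin(2 * pi * 8 * t[idx])
  }
  yy <- prr_signal(y, fs)
  ep2 <- extract_theta_epochs(yy)
  det <- epoch_duration(ep2) / 600
  expect_lt(det, 0.02)
  # >= 80% of burst time recovered
  burst_ep <- prr_epochs(burst_starts, burst_starts + 2)
  rec <- sum(sapply(seq_len(nrow(ep2)), function(i)
    sum(pmax(0, pmin(ep2$end_s[i], burst_ep$end_s) -
               pmax(ep2$start_s[i], burst_ep$start_s)))))
  expect_gt(rec / epoch_duration(burst_ep), 0.8)

  # stationary strong theta: threshold self-adapts, near-zero detections
  th <- prr_signal(10 * sin(2 * pi * 8 * t[seq_len(60 * fs)]) +
                     rnorm(60 * fs, 0, 0.5), fs)
  expect_lt(epoch_duration(extract_theta_epochs(th)) / 60, 0.05)

  expect_error(extract_theta_epochs(prr_signal(rep(1, 20 * fs), fs)),
               "degenerate")
})

test_that("theta-restricted PAC ratio tracks which rhythm drives gamma", {
  fs <- 1000
  r <- generate_respiration(60, fs, 3.5, 0.1, seed = 51)
  # gamma driven by the slow rhythm
  lfp_s <- generate_lfp(60, fs, ground_truth(pac_depth = 0.8, seed = 52), r)
  te <- prr_epochs(seq(0, 55, by = 10), seq(5, 60, by = 10))
  res_s <- pac_in_theta_epochs(lfp_s, te,
                               amp_freqs_hz = seq(70, 110, by = 10))
  expect_gt(res_s$ratio, 1)

  # gamma driven by a theta rhythm that is independent of the slow rhythm
  t <- (seq_len(60 * fs) - 1) / fs
  phi_th <- 2 * pi * 8 * t
  carrier <- bandpass(prr_signal(rnorm(60 * fs), fs), 80, 100)$samples
  x_t <- prr_signal(cos(attr(lfp_s, "slow_phase_rad")) + 0.6 * cos(phi_th) +
                      0.5 * (1 + 0.8 * cos(phi_th)) * carrier / sd(carrier) +
                      0.5 * rnorm(60 * fs), fs)
  # a ~8 Hz modulator puts its envelope sidebands ~8 Hz from the carrier,
  # so the amplitude filters must be wider than the default 10 Hz here
  res_t <- pac_in_theta_epochs(x_t, te,
                               amp_freqs_hz = seq(70, 110, by = 10),
                               amp_bw_hz = 24)
  expect_lt(res_t$ratio, 1)

  expect_error(pac_in_theta_epochs(lfp_s, prr_epochs(0, 2)), "insufficient")
  expect_warning(
    pac_in_theta_epochs(lfp_s, prr_epochs(0, 2), allow_short_window = TRUE,
                        amp_freqs_hz = seq(80, 100, by = 10)),
    "shortened")
})
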