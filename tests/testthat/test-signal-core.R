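test_that("z-scoring centres and scales, is idempotent, rejects constants", {
  s <- zscore_signal(prr_signal(c(1, 2, 3), fs = 10))
  expect_lt(abs(mean(s$samples)), 1e-9)
  expect_lt(abs(sd(s$samples) - 1), 1e-9)

  s2 <- zscore_signal(s)
  expect_equal(s2$samples, s$samples, tolerance = 1e-9)

  expect_error(zscore_signal(prr_signal(c(5, 5, 5), fs = 10)), "degenerate")
  expect_error(prr_signal(c(1, NA, 3), fs = 10), "finite")
})

test_that("band-pass keeps passband tones, kills stopband tones, is zero-phase", {
  fs <- 1000
  # forward+reverse passes square the magnitude response: a 3.5 Hz tone in
  # the 1-5 Hz band keeps ~93% amplitude, a tone at the geometric band
  # centre keeps ~100%
  inband <- bandpass(tone(10, fs, 3.5), 1, 5)
  mid <- 2000:8000
  expect_gt(max(inband$samples[mid]), 0.9)
  expect_lt(max(inband$samples[mid]), 1.05)
  centre <- bandpass(tone(10, fs, sqrt(5)), 1, 5)
  expect_gt(max(centre$samples[mid]), 0.95)
  expect_lt(max(centre$samples[mid]), 1.05)

  out <- bandpass(tone(10, fs, 50), 1, 5)
  expect_lt(max(abs(out$samples[mid])), 0.1)

  # forward-reverse filtering has zero net phase shift: time reversal
  # commutes away from the edge transients
  set.seed(1)
  x <- prr_signal(rnorm(8000), fs)
  xr <- prr_signal(rev(x$samples), fs)
  i <- 2001:6000
  expect_equal(rev(bandpass(xr, 6, 12)$samples)[i],
               bandpass(x, 6, 12)$samples[i], tolerance = 1e-8)

  expect_error(bandpass(x, 6, 600), "fs/2")
  expect_error(bandpass(x, -1, 5), "fs/2")
})

test_that("band-passed white noise concentrates its variance in band (FFT oracle)", {
  set.seed(7)
  fs <- 1000
  y <- bandpass(prr_signal(rnorm(60 * fs), fs), 6, 12)$samples
  pw <- Mod(fft(y))^2
  f <- (seq_along(pw) - 1) * fs / length(pw)
  half <- f <= fs / 2
  inb <- f >= 5 & f <= 13
  expect_gt(sum(pw[half & inb]) / sum(pw[half]), 0.8)
})

test_that("filtering is linear", {
  set.seed(2)
  fs <- 500
  x <- rnorm(3000); y <- rnorm(3000)
  a <- 2.5; b <- -1.2
  lhs <- bandpass(prr_signal(a * x + b * y, fs), 1, 5)$samples
  rhs <- a * bandpass(prr_signal(x, fs), 1, 5)$samples +
    b * bandpass(prr_signal(y, fs), 1, 5)$samples
  expect_equal(lhs, rhs, tolerance = 1e-8)
})

test_that("analytic phase follows the peak-zero / trough-pi convention", {
  fs <- 1000
  s <- tone(10, fs, 3.5)
  ph <- analytic_phase(s)$phase
  t <- (seq_len(10 * fs) - 1) / fs
  peaks <- which(abs(cos(2 * pi * 3.5 * t) - 1) < 1e-9)
  peaks <- peaks[peaks > fs & peaks < 9 * fs]
  expect_lt(max(abs(ph[peaks])), 0.01)

  # sin = cos shifted by -pi/2
  ssin <- prr_signal(sin(2 * pi * 3.5 * t), fs)
  expect_lt(abs(analytic_phase(ssin)$phase[1] + pi / 2), 0.01)

  env <- analytic_amplitude(tone(10, fs, 3.5, amp = 2.5))$envelope
  expect_lt(max(abs(env[fs:(9 * fs)] - 2.5)) / 2.5, 0.01)

  expect_error(analytic_phase(prr_signal(numeric(100) , fs)), "zero")
})

test_that("phase convention holds after band-pass across all analysis bands", {
  fs <- 1000
  for (spec in list(c(1, 5, 3.5), c(6, 12, 8), c(70, 110, 90))) {
    s <- bandpass(tone(12, fs, spec[3]), spec[1], spec[2])
    ph <- analytic_phase(s)$phase
    mid <- (2 * fs):(10 * fs)
    # local maxima of the filtered trace
    v <- s$samples
    pk <- mid[v[mid] > v[mid - 1] & v[mid] > v[mid + 1]]
    # discrete maxima sit up to half a sample off the true peak
    expect_lt(max(abs(ph[pk])), pi * spec[3] / fs + 0.05)
  }
})

test_that("epoch masking cuts half-open segments and validates bounds", {
  fs <- 1000
  x <- prr_signal(seq_len(60 * fs), fs)

  full <- mask_epochs(x, prr_epochs(0, 60))
  expect_length(full, 1)
  expect_identical(full[[1]]$samples, x$samples)

  expect_identical(mask_epochs(x, prr_epochs()), list())

  two <- mask_epochs(x, prr_epochs(c(5, 40), c(10, 45)))
  expect_length(two, 2)
  expect_identical(lengths(lapply(two, `[[`, "samples")), c(5000L, 5000L))
  expect_equal(two[[2]]$t0, 40)

  expect_error(mask_epochs(x, prr_epochs(50, 70)), "exceeds")
})

test_that("epoch sets are validated and edge trimming clips epochs", {
  expect_error(prr_epochs(c(0, 5), c(6, 10)), "overlap")
  expect_error(prr_epochs(5, 5), "start < end")
  fs <- 100
  x <- prr_signal(rep(0, 10 * fs) + 1, fs)
  seg <- mask_epochs(x, prr_epochs(0, 10), trim_s = 1)
  expect_length(seg[[1]]$samples, 8 * fs)
  expect_equal(seg[[1]]$t0, 1)
})

test_that("signal, epoch and spike-train round trips through CSV are exact", {
  d <- withr::local_tempdir()
  set.seed(3)
  s <- prr_signal(rnorm(500), fs = 1234.5, label = "lfp", t0 = 0.25)
  write_signal_csv(s, file.path(d, "sig.csv"))
  s2 <- read_signal_csv(file.path(d, "sig.csv"))
  expect_equal(s2$samples, s$samples, tolerance = 1e-12)
  expect_identical(s2$fs, s$fs)
  expect_identical(s2$label, "lfp")
  expect_identical(s2$t0, 0.25)

  ep <- prr_epochs(c(0.1, 2.34567891), c(1.999999999, 7))
  write_epochs_csv(ep, file.path(d, "ep.csv"))
  expect_equal(as.data.frame(read_epochs_csv(file.path(d, "ep.csv"))),
               as.data.frame(ep), tolerance = 1e-12)

  sess <- generate_session(session_config(duration_s = 20, n_pyr = 2,
                                          n_in = 1), seed = 11)
  write_session(sess, file.path(d, "sess"))
  back <- read_session(file.path(d, "sess"))
  expect_equal(back$lfp$samples, sess$lfp$samples, tolerance = 1e-12)
  expect_equal(back$spike_trains[[1]]$spike_times_s,
               sess$spike_trains[[1]]$spike_times_s, tolerance = 1e-12)
  expect_equal(back$spike_trains[[2]]$waveform,
               sess$spike_trains[[2]]$waveform, tolerance = 1e-12)
  expect_equal(back$truth$respiration_freq_hz,
               sess$truth$respiration_freq_hz)
})
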