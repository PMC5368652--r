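test_that("respiration generator: periodicity, cycle statistics, determinism", {
  fs <- 1000
  r0 <- generate_respiration(60, fs, 3.5, cv = 0, seed = 1)
  sp <- Mod(fft(r0$samples))[2:(30 * 60)]
  f <- (2:(30 * 60) - 1) / 60
  expect_equal(f[which.max(sp)], 3.5, tolerance = 1 / 60)

  r <- generate_respiration(60, fs, 3.5, cv = 0.1, seed = 1)
  n_cycles <- sum(attr(r, "cycle_periods_s") > 0 &
                    cumsum(attr(r, "cycle_periods_s")) <= 60)
  expect_gt(n_cycles, 210 - 15)
  expect_lt(n_cycles, 210 + 15)
  cp <- attr(r, "cycle_periods_s")
  expect_lt(abs(sd(cp) / mean(cp) - 0.1), 0.03)

  r2 <- generate_respiration(60, fs, 3.5, cv = 0.1, seed = 1)
  expect_identical(r$samples, r2$samples)

  expect_error(generate_respiration(-5, fs), "invalid")
  expect_error(generate_respiration(10, 50), "invalid")
})

test_that("LFP generator: z-scored output, coherence with respiration, PAC", {
  fs <- 1000
  r <- generate_respiration(60, fs, 3.5, 0.1, seed = 2)

  lfp <- generate_lfp(60, fs, ground_truth(prr_amp = 2, seed = 3), r)
  expect_lt(abs(mean(lfp$samples)), 1e-9)
  expect_lt(abs(sd(lfp$samples) - 1), 1e-9)
  co <- coherence(lfp, r)
  expect_gt(co$peak_coh, 0.5)
  expect_equal(co$peak_freq_hz, 3.5, tolerance = 0.3)

  # all structured components off -> no discrete peak above the 1/f trend
  quiet <- generate_lfp(60, fs, ground_truth(prr_amp = 0, theta_amp = 0,
                                             gamma_amp = 0, seed = 4), r)
  ps <- normalize_1f(multitaper_psd(quiet))
  inb <- ps$freqs_hz >= 2 & ps$freqs_hz <= 15
  expect_lt(max(ps$power[inb]) / stats::median(ps$power[inb]), 3)

  # gamma envelope follows the commanded modulator (envelope regression)
  lfp_pac <- generate_lfp(60, fs, ground_truth(pac_depth = 0.5, seed = 5), r)
  env <- analytic_amplitude(bandpass(lfp_pac, 80, 100))$envelope
  mod <- 1 + 0.5 * cos(attr(lfp_pac, "slow_phase_rad"))
  expect_gt(cor(env, mod), 0.3)

  expect_error(generate_lfp(60, 500, ground_truth(), r), "mismatch")
})

test_that("generated slow-band PSD peak sits within one bin of respiration rate", {
  fs <- 1000
  for (s in 1:3) {
    r <- generate_respiration(60, fs, 3.5, 0.1, seed = 10 + s)
    lfp <- generate_lfp(60, fs, ground_truth(seed = 20 + s), r)
    pk <- band_peak(multitaper_psd(lfp), c(1, 5))$peak_freq_hz
    expect_lt(abs(pk - 3.5), 0.2 + 1e-9)
  }
})

test_that("spike generator: rate accuracy, uniformity at kappa 0, locking recovery", {
  fs <- 1000
  phi <- phase_ramp(120, fs, 3.5)

  st <- generate_spike_train(120, 5, phi, kappa = 0, seed = 1)
  expect_lt(abs(length(st$spike_times_s) / 120 - 5) / 5, 0.1)
  expect_true(all(diff(st$spike_times_s) >= 0.002 - 1e-12))

  # kappa = 0: Rayleigh non-significant in >= 90% of seeded runs
  ps <- vapply(1:100, function(s) {
    stt <- generate_spike_train(60, 5, phi, kappa = 0, seed = 1000 + s)
    rayleigh_test(spike_phases(stt, phi))$p
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.9)

  # kappa = 2 at pi/2: circular mean within 0.2 rad
  st2 <- generate_spike_train(120, 5, phi, preferred_phase_rad = pi / 2,
                              kappa = 2, seed = 2)
  cm <- circ_stats(spike_phases(st2, phi))$mean
  expect_lt(abs(wrap_phase(cm - pi / 2)), 0.2)

  expect_identical(length(generate_spike_train(0, 5, phi, seed = 3)$spike_times_s), 0L)
  expect_error(generate_spike_train(10, 600, phi, refractory_ms = 2), "unattainable")
  expect_error(generate_spike_train(10, -1, phi), "invalid")
})

test_that("mean resultant of spike phases approaches I1(k)/I0(k)", {
  fs <- 1000
  phi <- phase_ramp(240, fs, 3.5)
  for (k in c(1, 4)) {
    st <- generate_spike_train(240, 8, phi, preferred_phase_rad = 0.5,
                               kappa = k, seed = 10 + k)
    R <- circ_stats(spike_phases(st, phi))$R
    expect_lt(abs(R - vm_resultant(k)), 0.06)
  }
})

test_that("sessions are deterministic, class rates separate, immobility tiles", {
  cfg <- session_config(duration_s = 60, n_pyr = 6, n_in = 3)
  s1 <- generate_session(cfg, seed = 7)
  s2 <- generate_session(cfg, seed = 7)
  expect_identical(s1, s2)

  rates <- vapply(s1$spike_trains, function(tr)
    length(tr$spike_times_s) / 60, numeric(1))
  labs <- s1$truth$unit_params$class
  expect_gt(mean(rates[labs == "IN"]) / mean(rates[labs == "PYR"]), 3)

  expect_equal(epoch_duration(s1$immobility) / 60, 0.6, tolerance = 0.05)
  full <- generate_session(session_config(duration_s = 30, n_pyr = 1,
                                          n_in = 1,
                                          immobility_fraction = 1), seed = 8)
  expect_equal(as.data.frame(full$immobility),
               data.frame(start_s = 0, end_s = 30))

  # spikes fall inside [0, duration)
  expect_true(all(vapply(s1$spike_trains, function(tr)
    all(tr$spike_times_s >= 0 & tr$spike_times_s < 60), logical(1))))
})

test_that("generated coupled fractions are recovered by the coupling analysis", {
  fs <- 500
  phi <- phase_ramp(150, fs, 3.5)
  for (f in c(0, 0.5, 1.0)) {
    n_units <- 40
    n_coupled <- round(f * n_units)
    sig <- vapply(seq_len(n_units), function(i) {
      k <- if (i <= n_coupled) 2 else 0
      st <- generate_spike_train(150, 3, phi, preferred_phase_rad = 1,
                                 kappa = k, seed = 5000 + 100 * f + i)
      unit_coupling(st, phi)$significant
    }, logical(1))
    ci <- binom.test(sum(sig), n_units)$conf.int
    expect_true(f >= ci[1] - 0.05 && f <= ci[2] + 0.05)
  }
})

test_that("ground-truth invariants are enforced", {
  expect_error(ground_truth(pac_depth = 1.5), "pac_depth")
  expect_error(ground_truth(theta_lock_kappa = -1), "kappa")
  expect_error(ground_truth(theta_freq_ratio = 2.5), "integer")
})
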