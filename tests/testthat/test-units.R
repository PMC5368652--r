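test_that("waveform templates are classified into their classes", {
  pyr <- classify_unit(waveform_template(0.47, 0.31), 30000)
  expect_identical(pyr$label, "PYR")
  expect_lt(abs(pyr$half_duration_ms - 0.47), 0.02)
  expect_lt(abs(pyr$trough_to_peak_ms - 0.31), 0.02)

  inw <- classify_unit(waveform_template(0.25, 0.20), 30000)
  expect_identical(inw$label, "IN")
  expect_lt(abs(inw$half_duration_ms - 0.25), 0.02)
  expect_lt(abs(inw$trough_to_peak_ms - 0.20), 0.02)

  # positive-going (inverted) waveform is unclassifiable
  flipped <- classify_unit(-waveform_template(0.47, 0.31), 30000)
  expect_true(flipped$unclassifiable)
  # trough at the edge is unclassifiable
  edge <- classify_unit(c(-1, -0.5, 0, 0.2, 0.1, 0), 30000)
  expect_true(edge$unclassifiable)
})

test_that("classification is >= 95% accurate under 5% waveform noise", {
  set.seed(1)
  wp <- waveform_template(0.47, 0.31)
  wi <- waveform_template(0.25, 0.20)
  n_ok <- 0
  for (i in 1:100) {
    lp <- classify_unit(wp + rnorm(length(wp), 0, 0.05), 30000)$label
    li <- classify_unit(wi + rnorm(length(wi), 0, 0.05), 30000)$label
    n_ok <- n_ok + identical(lp, "PYR") + identical(li, "IN")
  }
  expect_gte(n_ok / 200, 0.95)
})

test_that("firing rates count spikes within epochs only", {
  tr <- prr_spiketrain(seq(0.25, 49.75, length.out = 100))
  expect_equal(firing_rate(tr, prr_epochs(0, 50)), 2)
  expect_equal(firing_rate(prr_spiketrain(numeric()), prr_epochs(0, 50)), 0)
  expect_equal(firing_rate(tr, prr_epochs(0, 25)), 50 / 25)
  expect_error(firing_rate(tr, prr_epochs()), "zero")

  st <- generate_spike_train(120, 9.4, kappa = 0, seed = 3)
  expect_lt(abs(firing_rate(st, prr_epochs(0, 120)) - 9.4), 0.9)
})

test_that("spike phases follow the peak/trough convention and skip out-of-span", {
  fs <- 1000
  phi <- analytic_phase(bandpass(tone(20, fs, 3.5), 1, 5))
  peaks <- seq(1 / 3.5, 18, by = 1 / 3.5)
  tr <- prr_spiketrain(peaks)
  ph <- spike_phases(tr, phi)
  expect_lt(max(abs(ph)), 0.05)

  troughs <- peaks + 1 / 7
  pht <- spike_phases(prr_spiketrain(troughs), phi)
  expect_lt(max(pi - abs(pht)), 0.05)

  expect_length(spike_phases(tr, phi, prr_epochs()), 0)
  out <- spike_phases(prr_spiketrain(c(1, 2, 25)), phi)
  expect_identical(attr(out, "n_skipped"), 1L)
})

test_that("Rayleigh statistics match the direct vector-sum oracle", {
  r <- rayleigh_test(c(0, pi / 2, 0, -pi / 2, 0))
  expect_equal(r$R, 0.6, tolerance = 1e-12)
  expect_equal(r$z, 1.8, tolerance = 1e-12)
  expect_equal(r$circ_mean_rad, 0)

  r2 <- rayleigh_test(rep(1.3, 20))
  expect_equal(r2$R, 1)
  expect_lt(r2$p, 1e-6)

  expect_error(rayleigh_test(numeric()), "insufficient")
})

test_that("Rayleigh test is approximately calibrated under uniformity", {
  set.seed(5)
  rej <- mean(replicate(500, rayleigh_test(runif(50, -pi, pi))$p < 0.05))
  expect_gt(rej, 0.025)
  expect_lt(rej, 0.075)
})

test_that("unit coupling recovers generated locking and excludes sparse units", {
  fs <- 1000
  phi <- phase_ramp(120, fs, 3.5, band = c(1, 5))
  st <- generate_spike_train(120, 5, phi, preferred_phase_rad = -0.89,
                             kappa = 2, seed = 6)
  res <- unit_coupling(st, phi, rhythm = "prr")
  expect_false(res$excluded)
  expect_true(res$significant)
  expect_lt(abs(res$circ_mean_rad - (-0.89)), 0.2)

  sparse <- prr_spiketrain(seq(1, 9) * 0.5)
  res9 <- unit_coupling(sparse, phi)
  expect_true(res9$excluded)
  expect_true(is.na(res9$p))

  # uniform unit: mostly non-significant across seeds
  sig <- vapply(1:50, function(s) {
    stu <- generate_spike_train(100, 5, phi, kappa = 0, seed = 100 + s)
    unit_coupling(stu, phi)$significant
  }, logical(1))
  expect_lt(mean(sig), 0.15)
})

test_that("circular-mean estimates are unbiased under von Mises locking", {
  fs <- 500
  phi <- phase_ramp(200, fs, 3.5)
  errs <- vapply(1:60, function(s) {
    st <- generate_spike_train(200, 4, phi, preferred_phase_rad = 0.7,
                               kappa = 2, seed = 200 + s)
    wrap_phase(unit_coupling(st, phi)$circ_mean_rad - 0.7)
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.05)
})

test_that("population summary: fractions, overlap, class proportions", {
  mk <- function(uid, rhythm, sig, cm = 0)
    data.frame(unit_id = uid, rhythm = rhythm, n_spikes = 100, R = 0.3,
               circ_mean_rad = cm, p = if (sig) 0.001 else 0.5,
               significant = sig, excluded = FALSE)
  classes <- data.frame(unit_id = sprintf("u%02d", 1:20),
                        label = rep(c("PYR", "IN"), each = 10))

  # everyone coupled to both rhythms
  res_all <- do.call(rbind, lapply(sprintf("u%02d", 1:20), function(u)
    rbind(mk(u, "prr", TRUE), mk(u, "theta", TRUE))))
  s <- population_summary(res_all, classes)
  expect_true(all(s$fractions$fraction == 1))
  expect_true(all(s$overlap$frac_a_also_b == 1))
  expect_gt(s$class_tests$p[1], 0.99)

  # disjoint populations: half PRR-only, half theta-only -> zero overlap
  res_disj <- do.call(rbind, lapply(1:20, function(i) {
    u <- sprintf("u%02d", i)
    rbind(mk(u, "prr", i %% 2 == 0), mk(u, "theta", i %% 2 == 1))
  }))
  s2 <- population_summary(res_disj, classes)
  expect_true(all(s2$overlap$frac_a_also_b == 0))

  expect_error(population_summary(res_all[0, ], classes), "insufficient")
})
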