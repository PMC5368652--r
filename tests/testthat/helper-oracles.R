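# Shared helpers: small constructors and independent oracles used across
# the suite. Oracles are deliberately written from first principles (direct
# sums, closed forms) so they stay independent of the package internals.

# linear phase ramp at freq_hz, wrapped, as a phase series
phase_ramp <- function(duration_s, fs, freq_hz, phi0 = -pi, band = NULL) {
  t <- (seq_len(round(duration_s * fs)) - 1) / fs
  prr_phase_series(2 * pi * freq_hz * t + phi0, fs, band_hz = band)
}

# circular mean / resultant by direct vector sum (oracle)
circ_stats <- function(phi) {
  z <- mean(exp(1i * phi))
  list(mean = Arg(z), R = Mod(z))
}

# closed-form 18-bin MI oracle for envelope a(phi) = 1 + d*cos(phi - mu)
# under dense uniform phase sampling: per-bin mass is the bin integral.
mi_cosine_oracle <- function(d, mu = 0, n_bins = 18) {
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  mass <- diff(edges) + d * (sin(edges[-1] - mu) - sin(edges[-(n_bins + 1)] - mu))
  p <- mass / sum(mass)
  sum(p * log(p * n_bins)) / log(n_bins)
}

# mean resultant length of a von Mises distribution: I1(k)/I0(k)
vm_resultant <- function(kappa) besselI(kappa, 1) / besselI(kappa, 0)

# tone signal helper
tone <- function(duration_s, fs, freq_hz, amp = 1, phase = 0) {
  t <- (seq_len(round(duration_s * fs)) - 1) / fs
  prr_signal(amp * cos(2 * pi * freq_hz * t + phase), fs)
}
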