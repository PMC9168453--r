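# Independent oracles, coded from first principles (not via the package's
# linear-algebra or closed-form paths).

# one Krebs-cycle turn written as an explicit per-position case analysis
oracle_turn <- function(s) {
  c(0,
    0,
    s[2] / 2 + s[3] / 2,
    s[2] / 2 + s[3] / 2,
    s[1] / 2 + s[4] / 2,
    s[1] / 2 + s[4] / 2)
}

# brute-force secreted distribution: enumerate generations until the
# geometric weight is negligible
oracle_secreted <- function(d, p, f_p, f_a, pdc_pos, k_max = 400) {
  s0 <- numeric(6)
  s0[pdc_pos] <- (1 - p) * f_a
  s0[3] <- s0[3] + p * f_p / 2
  s0[4] <- s0[4] + p * f_p / 2
  acc <- numeric(6)
  state <- s0
  for (k in 0:k_max) {
    acc <- acc + d * (1 - d)^k * state
    state <- oracle_turn(state)
  }
  acc
}

# build a 13C spectral window directly from known Lorentzian lines
make_lorentzian_spectrum <- function(centers_ppm, integrals, fwhm_hz,
                                     ppm_range = c(40, 80), n = 8192,
                                     nucleus = "13C", mhz = 125.76,
                                     noise_sd = 0, seed = 1) {
  ppm <- seq(ppm_range[1], ppm_range[2], length.out = n)
  y <- numeric(n)
  for (i in seq_along(centers_ppm)) {
    g <- fwhm_hz[min(i, length(fwhm_hz))] / 2
    amp <- integrals[i] / (pi * g)
    x <- (ppm - centers_ppm[i]) * mhz
    y <- y + amp * g^2 / (g^2 + x^2)
  }
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + rnorm(n, 0, noise_sd)
  }
  spectrum_1d(ppm, y, nucleus = nucleus, frequency_mhz = mhz)
}
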