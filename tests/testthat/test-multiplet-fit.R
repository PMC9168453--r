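# Constrained Lorentzian multiplet fitting of the citrate 13C regions.

c24_lines <- function(singlet = 1.0, doublet_side = 0.3) {
  mhz <- 125.76
  list(centers = c(46.5 - 19 / mhz, 46.5, 46.5 + 19 / mhz),
       integrals = c(doublet_side, singlet, doublet_side))
}

test_that("the C2/4 singlet-plus-doublet model recovers known integrals within 3%", {
  tl <- c24_lines()
  # SNR 100 on the tallest line (singlet, lw 8 Hz)
  noise <- (1 / (pi * 4)) / 100
  spec <- make_lorentzian_spectrum(tl$centers, tl$integrals, 8,
                                   noise_sd = noise, seed = 21)
  fit <- fit_citrate_c24_region(spec)
  expect_equal(fit$group_totals$singlet, 1.0, tolerance = 0.03)
  expect_equal(fit$group_totals$doublet, 0.6, tolerance = 0.03)
  expect_equal(fit$total_integral, 1.6, tolerance = 0.03)
  expect_equal(fit$gof, 1, tolerance = 0.35)
})

test_that("a zero-signal window fits integrals at the noise floor", {
  spec <- make_lorentzian_spectrum(46.5, 0, 8, noise_sd = 1e-3, seed = 4)
  fit <- fit_citrate_c24_region(spec)
  # noise-floor scale: sigma x pi x lw/2 per line
  expect_lt(fit$total_integral, 3 * (3 * 1e-3 * pi * 10))
})

test_that("linewidths beyond the prior-knowledge bound clamp at 20 Hz and are flagged", {
  tl <- c24_lines()
  spec <- make_lorentzian_spectrum(tl$centers, tl$integrals, 25,
                                   noise_sd = 1e-5, seed = 9)
  fit <- fit_citrate_c24_region(spec)
  expect_true(all(fit$components$fwhm_hz <= 20 + 1e-9))
  expect_true(any(fit$components$at_lw_bound))
  expect_output(print(fit), "boundary")
})

test_that("the five-line C3 model recovers a known symmetric pattern within 3%", {
  mhz <- 125.76
  offs <- c(-38, -19, 0, 19, 38) / mhz
  ints <- c(0.1, 0.2, 0.4, 0.2, 0.1) * 2.5
  noise <- (ints[3] / (pi * 4)) / 100
  spec <- make_lorentzian_spectrum(76.2 + offs, ints, 8,
                                   ppm_range = c(70, 82),
                                   noise_sd = noise, seed = 13)
  fit <- fit_citrate_c3_region(spec)
  expect_equal(fit$total_integral, 2.5, tolerance = 0.03)
  expect_equal(fit$group_totals$center, 1.0, tolerance = 0.03)
})

test_that("a lone central C3 line yields near-zero outer amplitudes", {
  spec <- make_lorentzian_spectrum(76.2, 1.0, 8, ppm_range = c(70, 82),
                                   noise_sd = 1e-4, seed = 2)
  fit <- fit_citrate_c3_region(spec)
  outer <- fit$components$integral[fit$components$label != "center"]
  expect_true(all(outer < 0.01))
  expect_equal(fit$group_totals$center, 1.0, tolerance = 0.01)
})

test_that("an extraneous resonance inside the window inflates the fit residual", {
  mhz <- 125.76
  tl <- c24_lines()
  clean <- make_lorentzian_spectrum(tl$centers, tl$integrals, 8,
                                    noise_sd = 1e-3, seed = 5)
  dirty <- make_lorentzian_spectrum(c(tl$centers, 46.5 + 60 / mhz),
                                    c(tl$integrals, 0.8), 8,
                                    noise_sd = 1e-3, seed = 5)
  gof_clean <- fit_citrate_c24_region(clean)$gof
  gof_dirty <- fit_citrate_c24_region(dirty)$gof
  expect_lt(gof_clean, 2)
  expect_gt(gof_dirty, 5 * gof_clean)
})

test_that("doubling all intensities doubles every fitted integral (linearity)", {
  tl <- c24_lines(singlet = 0.8, doublet_side = 0.25)
  spec1 <- make_lorentzian_spectrum(tl$centers, tl$integrals, 10)
  spec2 <- spectrum_1d(spec1$ppm, 2 * spec1$intensity, nucleus = "13C",
                       frequency_mhz = spec1$frequency_mhz)
  f1 <- fit_citrate_c24_region(spec1)
  f2 <- fit_citrate_c24_region(spec2)
  expect_equal(f2$components$integral, 2 * f1$components$integral,
               tolerance = 1e-6)
})

test_that("a fixed transferred linewidth is honored and bounds are validated", {
  tl <- c24_lines()
  spec <- make_lorentzian_spectrum(tl$centers, tl$integrals, 8)
  fit <- fit_citrate_c24_region(spec, lw_fixed_hz = 8)
  expect_true(all(fit$components$fwhm_hz == 8))
  expect_equal(fit$total_integral, 1.6, tolerance = 1e-4)
  expect_error(fit_citrate_c24_region(spec, lw_fixed_hz = 30), "lw_bounds")
})

test_that("a missing spectral window is reported as such", {
  spec <- make_lorentzian_spectrum(46.5, 1, 8, ppm_range = c(40, 50))
  expect_error(fit_citrate_c3_region(spec), "not covered")
})

test_that("group totals equal the sum of their components", {
  tl <- c24_lines()
  spec <- make_lorentzian_spectrum(tl$centers, tl$integrals, 8,
                                   noise_sd = 5e-4, seed = 30)
  fit <- fit_citrate_c24_region(spec)
  expect_equal(fit$group_totals$c24_total,
               sum(fit$components$integral))
  expect_equal(fit$group_totals$singlet + fit$group_totals$doublet,
               fit$group_totals$c24_total)
  expect_true(all(fit$components$integral >= 0))
})
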