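# TSP-referenced quantification, rates, and enrichment estimators.

cfg <- quant_config(medium_volume_mL = 10, n_cells = 1e6)

test_that("measured R1 reproduces the documented arithmetic", {
  expect_equal(measured_ratio_R1(4, 1), 0.75)
  expect_equal(measured_ratio_R1(2, 1), 0.5)
  expect_equal(measured_ratio_R1(3, 0), 1)
  expect_error(measured_ratio_R1(0, 1), "zero")
})

test_that("TSP referencing converts integrals to concentrations per proton", {
  expect_equal(quantify_vs_tsp(1, 9, 1, cfg), 0.2)
  expect_equal(quantify_vs_tsp(1 / 3, 3, 1, cfg), 0.2)
  expect_equal(quantify_vs_tsp(2, 3, 1, cfg), 0.2 * 2 * 3)
  expect_error(quantify_vs_tsp(1, 9, 0, cfg), "TSP")
  expect_error(quantify_vs_tsp(1, 0, 1, cfg), "n_protons")
})

test_that("production rate follows the unit definition and proportionalities", {
  expect_equal(production_rate(0.0268, cfg), 0.0268 * 10 * 1000 / 48,
               tolerance = 1e-12)
  expect_equal(production_rate(0.0268, cfg), 5.58, tolerance = 1e-2)
  expect_equal(production_rate(0, cfg), 0)
  cfg2 <- quant_config(medium_volume_mL = 10, n_cells = 2e6)
  expect_equal(production_rate(0.0268, cfg2), production_rate(0.0268, cfg) / 2)
  expect_error(production_rate(1, quant_config(tsp_conc_mM = 0.2)),
               "must be set")
})

test_that("satellite enrichment reproduces the measured pool enrichments", {
  expect_equal(enrichment_from_satellites(1, 4), 0.80)
  expect_equal(enrichment_from_satellites(1, 3), 0.75)
  expect_equal(enrichment_from_satellites(1, 0), 0)
  expect_error(enrichment_from_satellites(0, 0), "both")
  # scale invariance
  expect_equal(enrichment_from_satellites(3.3, 7.7),
               enrichment_from_satellites(3.3e4, 7.7e4))
})

test_that("acetyl-CoA enrichment is the labeled fraction of the glutamate pattern", {
  expect_equal(acetyl_enrichment(0.56, 0.44), 0.56)
  expect_equal(acetyl_enrichment(0.50, 0.50), 0.50)
  expect_equal(acetyl_enrichment(0, 1), 0)
})

test_that("glucose consumption is anchored to the 13C lactate concentration", {
  # construct inputs so that consumption is exactly 255 nmol/h per 1e6 cells:
  # consumed conc = 255 * 48 * 1e6/1e6 / (10 * 1000) = 1.224 mM
  consumed <- 255 * 48 / (10 * 1000)
  initial <- 11
  remaining <- initial - consumed
  lac13 <- 7.2  # mM, arbitrary anchor
  # choose integrals consistent: I_glc/I_lac = remaining * 2 / lac13
  i_lac <- 3.5
  i_glc <- i_lac * remaining * 2 / lac13
  rate <- glucose_consumption_rate(i_glc, i_lac, lac13, initial, cfg)
  expect_equal(rate, 255, tolerance = 1e-10)
  # no depletion
  i_glc_full <- i_lac * initial * 2 / lac13
  expect_equal(glucose_consumption_rate(i_glc_full, i_lac, lac13, initial, cfg), 0)
  # over-full estimate clamps with a warning
  expect_warning(glucose_consumption_rate(2 * i_glc_full, i_lac, lac13,
                                          initial, cfg), "clamping")
  expect_error(glucose_consumption_rate(1, 0, lac13, initial, cfg), "zero")
})

test_that("oxidative triose rate is the glucose-doubled balance with a floor", {
  expect_equal(oxidative_triose_rate(255, 200, 30, 30), 250)
  expect_equal(oxidative_triose_rate(0, 0, 0), 0)
  expect_warning(out <- oxidative_triose_rate(100, 250, 0), "flooring")
  expect_equal(out, 0)
  expect_error(oxidative_triose_rate(-1, 0, 0), "nonnegative")
})

test_that("PC anaplerotic rate is the triose rate scaled by the PC fraction", {
  expect_equal(pc_anaplerotic_rate(250, 0.21), 52.5)
  expect_equal(pc_anaplerotic_rate(100, 0.5), 50)
  expect_equal(pc_anaplerotic_rate(250, 0), 0)
  expect_error(pc_anaplerotic_rate(250, 1), "\\[0, 1\\)")
})

test_that("rate and concentration chain reproduces generator ground truth", {
  tr <- ground_truth(seed = 19)
  ex <- generate_experiment(tr)
  tsp <- fit_tsp_proton(ex$spectrum_1h)
  cit <- fit_citrate_proton(ex$spectrum_1h)
  conc <- quantify_vs_tsp(cit$total_integral, 4, tsp$total_integral, tr$cfg)
  expect_equal(conc, tr$citrate_conc_mM, tolerance = 0.03)
  rate <- production_rate(conc, tr$cfg)
  truth_rate <- tr$citrate_conc_mM * 10 * 1000 / (48 * 5)
  expect_equal(rate, truth_rate, tolerance = 0.03)
})
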