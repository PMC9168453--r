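# Joint inversion of (R1, R2) for the secretion fraction d and PC fraction p.

test_that("the LNCaP worked example inverts to d near 0.79 and p near 0.21", {
  fit <- fit_citrate_flux(0.75, 5.2)
  expect_s3_class(fit, "citrate_flux_fit")
  expect_equal(coef(fit)[["d"]], 0.79, tolerance = 0.02 / 0.79)
  expect_equal(coef(fit)[["p"]], 0.21, tolerance = 0.02 / 0.21)
  expect_lt(fit$residual, 1e-8)
  expect_true(fit$converged)
  expect_equal(fit$expected_turns,
               (1 - coef(fit)[["d"]]) / coef(fit)[["d"]])
  # fitted ratios reproduce the observations
  expect_equal(unname(residuals(fit)), c(0, 0), tolerance = 1e-8)
})

test_that("noiseless round-trip recovers (d, p) to 1e-6 over the parameter grid", {
  glc <- tracer_spec("glucose_1_6")
  pyr <- tracer_spec("pyruvate_2")
  for (d in c(0.1, 0.3, 0.5, 0.7, 0.9, 0.95)) {
    for (p in c(0.02, 0.1, 0.25, 0.4, 0.5)) {
      r1 <- ratio_R1(secreted_distribution(glc, model_params(d, p), method = "closed"))
      r2 <- ratio_R2(secreted_distribution(pyr, model_params(d, p), method = "closed"))
      fit <- fit_citrate_flux(r1, r2, tol = 1e-10)
      expect_equal(unname(coef(fit)), c(d, p), tolerance = 1e-6)
    }
  }
})

test_that("ratios outside the attainable envelope fail loudly", {
  # R1 = 0.4 is unattainable jointly with R2 = 5.2 (a low R1 needs a large
  # PC fraction, a large R2 a small one)
  expect_error(fit_citrate_flux(0.4, 5.2), "outside model range")
  expect_error(fit_citrate_flux(1.2, 5.2), "admissible range")
  expect_error(fit_citrate_flux(0.75, -1), "positive")
})

test_that("R1 is monotone in d at fixed p and R2 monotone in p at fixed d", {
  glc <- tracer_spec("glucose_1_6")
  pyr <- tracer_spec("pyruvate_2")
  d_grid <- seq(0.05, 1, by = 0.05)
  for (p in c(0.05, 0.21, 0.5)) {
    r1 <- vapply(d_grid, function(d) {
      ratio_R1(secreted_distribution(glc, model_params(d, p), method = "closed"))
    }, numeric(1))
    expect_true(all(diff(r1) > 0))
  }
  p_grid <- seq(0.02, 0.9, by = 0.02)
  for (d in c(0.2, 0.79)) {
    r2 <- vapply(p_grid, function(p) {
      ratio_R2(secreted_distribution(pyr, model_params(d, p), method = "closed"))
    }, numeric(1))
    expect_true(all(diff(r2) < 0))
  }
})

test_that("R2 grows without bound as the PC fraction vanishes", {
  pyr <- tracer_spec("pyruvate_2")
  r2 <- vapply(c(1e-2, 1e-4, 1e-6), function(p) {
    ratio_R2(secreted_distribution(pyr, model_params(0.79, p), method = "closed"))
  }, numeric(1))
  expect_true(all(diff(r2) > 0))
  expect_gt(r2[3], 1e5)
})

test_that("PC-versus-d curves intersect at the joint inversion solution", {
  curves <- pc_vs_d_curves(0.75, 5.2, d_grid = seq(0.5, 1, by = 0.01))
  fit <- fit_citrate_flux(0.75, 5.2)
  # the gap between the two curves changes sign at d_hat
  gap <- curves$p_R1 - curves$p_R2
  ok <- stats::complete.cases(gap)
  crossing <- curves$d[ok][which.min(abs(gap[ok]))]
  expect_equal(crossing, coef(fit)[["d"]], tolerance = 0.011)
  # at the fitted d both curves give the fitted p
  at_fit <- pc_vs_d_curves(0.75, 5.2, d_grid = coef(fit)[["d"]])
  expect_equal(at_fit$p_R1, coef(fit)[["p"]], tolerance = 1e-6)
  expect_equal(at_fit$p_R2, coef(fit)[["p"]], tolerance = 1e-6)
  expect_error(pc_vs_d_curves(0.75, 5.2, d_grid = numeric(0)), "non-empty")
})

test_that("the R2 curve of p against d is monotone decreasing in p at fixed d", {
  # solving R2(d, p) = r2 for increasing r2 at fixed d must give decreasing p
  p_at <- vapply(c(4, 5.2, 8, 13.8), function(r2) {
    pc_vs_d_curves(0.75, r2, d_grid = 0.79)$p_R2
  }, numeric(1))
  expect_true(all(diff(p_at) < 0))
})

test_that("inversion under ratio measurement noise keeps d within 0.05 (median)", {
  fit <- fit_citrate_flux(0.75, 5.2)
  sims <- simulate(fit, nsim = 200, seed = 42, sd_r1 = 0.02, sd_r2 = 0.5)
  expect_equal(nrow(sims), 200)
  expect_gt(mean(!is.na(sims$d)), 0.9)
  expect_lt(stats::median(abs(sims$d - 0.79), na.rm = TRUE), 0.05)
})

test_that("predict and summary expose the model surface", {
  fit <- fit_citrate_flux(0.75, 5.2)
  pred <- predict(fit)
  expect_equal(pred$R1, 0.75, tolerance = 1e-8)
  expect_equal(pred$R2, 5.2, tolerance = 1e-7)
  grid <- predict(fit, newdata = data.frame(d = c(0.79, 0.9), p = c(0.21, 0.1)))
  expect_equal(nrow(grid), 2)
  expect_output(print(summary(fit)), "upper bound")
})
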