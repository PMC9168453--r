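# Forward positional-labeling model: entry patterns, turn transitions,
# accumulated secreted distributions, and the ratios R1/R2.

test_that("tracer construction carries the correct entry positions and enrichments", {
  glc <- tracer_spec("glucose_1_6")
  expect_identical(glc$pdc_entry_positions, 2L)
  expect_identical(glc$pc_entry_positions, c(3L, 4L))
  expect_equal(glc$f_p, 0.80)
  expect_equal(glc$f_a, 0.56)

  pyr <- tracer_spec("pyruvate_2")
  expect_identical(pyr$pdc_entry_positions, 1L)
  expect_identical(pyr$pc_entry_positions, c(3L, 4L))
  expect_equal(pyr$f_a / pyr$f_p, 0.70)

  gln <- tracer_spec("glutamine_5")
  expect_identical(gln$reductive_entry_position, 1L)
  expect_identical(gln$oxidative_entry_positions, c(5L, 6L))

  expect_error(tracer_spec("acetate_2"), "supported tracers")
  expect_error(tracer_spec("glucose_1_6", f_p = 1.2), "\\[0, 1\\]")
})

test_that("model parameter validation enforces the admissible ranges", {
  expect_error(model_params(0, 0.2), "\\(0, 1\\]")
  expect_error(model_params(0.5, 1), "\\[0, 1\\)")
  expect_error(model_params(0.5, 0.2, tol = 0), "tol")
  expect_error(model_params(0.5, 0.2, max_turns = 0), "max_turns")
  expect_silent(model_params(1, 0))
})

test_that("generation-0 pattern places PDC and PC entry weights correctly", {
  # PDC-only pyruvate at full enrichment: all weight on C1
  c0 <- initial_label_pattern(tracer_spec("pyruvate_2", f_p = 1, f_a = 1),
                              model_params(0.5, 0))
  expect_equal(unclass(c0), c(C1 = 1, C2 = 0, C3 = 0, C4 = 0, C5 = 0, C6 = 0))

  # glucose with mixed entries: (1-p) f_a on C2, p f_p split on C3/C4
  c0 <- initial_label_pattern(tracer_spec("glucose_1_6", f_p = 0.80, f_a = 0.56),
                              model_params(0.5, 0.21))
  expect_equal(c0[["C2"]], 0.79 * 0.56)
  expect_equal(c0[["C3"]], 0.21 * 0.80 / 2)
  expect_equal(c0[["C4"]], 0.21 * 0.80 / 2)
  expect_equal(c0[["C1"]] + c0[["C5"]] + c0[["C6"]], 0)

  # PC-only at full scrambling: half on each of C3/C4
  c0 <- initial_label_pattern(tracer_spec("pyruvate_2", f_p = 1, f_a = 1),
                              model_params(0.5, 1 - 1e-12))
  expect_equal(unclass(c0), c(C1 = 0, C2 = 0, C3 = 0.5, C4 = 0.5, C5 = 0, C6 = 0),
               tolerance = 1e-9)

  expect_error(initial_label_pattern(tracer_spec("glutamine_5"),
                                     model_params(0.5, 0)),
               "Krebs-cycle engine")
})

test_that("one turn moves C1/C4 to C5+C6, redistributes C2/C3 over C3+C4, loses C5/C6", {
  expect_equal(unname(unclass(turn_transition(c(1, 0, 0, 0, 0, 0)))),
               c(0, 0, 0, 0, 0.5, 0.5))
  expect_equal(unname(unclass(turn_transition(c(0, 0, 1, 0, 0, 0)))),
               c(0, 0, 0.5, 0.5, 0, 0))
  expect_equal(unname(unclass(turn_transition(c(0, 0, 0, 0, 1, 1)))),
               rep(0, 6))
  expect_error(turn_transition(c(-1, 0, 0, 0, 0, 0)), "nonnegative")
})

test_that("the transition map is sub-stochastic: C1..C4 conserve weight, C5/C6 vanish", {
  t_mat <- turn_transition_matrix()
  expect_equal(unname(colSums(t_mat)[1:4]), rep(1, 4))
  expect_equal(unname(colSums(t_mat)[5:6]), rep(0, 2))
  expect_true(all(t_mat >= 0))
})

test_that("iterative secreted distribution matches the brute-force generation sum", {
  for (tr_id in c("glucose_1_6", "pyruvate_2")) {
    tr <- tracer_spec(tr_id)
    pdc <- tr$pdc_entry_positions
    for (d in c(0.05, 0.3, 0.79, 1)) {
      for (p in c(0, 0.21, 0.6)) {
        got <- secreted_distribution(tr, model_params(d, p))
        want <- oracle_secreted(d, p, tr$f_p, tr$f_a, pdc)
        expect_equal(unname(got$s), want, tolerance = 1e-10)
        expect_true(got$converged)
      }
    }
  }
})

test_that("iterative and closed-form secreted distributions agree to 1e-10 over the grid", {
  for (tr_id in c("glucose_1_6", "pyruvate_2")) {
    tr <- tracer_spec(tr_id)
    for (d in seq(0.05, 1, by = 0.05)) {
      for (p in seq(0, 0.9, by = 0.1)) {
        it <- secreted_distribution(tr, model_params(d, p))$s
        cf <- secreted_distribution(tr, model_params(d, p), method = "closed")$s
        expect_lt(max(abs(it - cf)), 1e-10)
      }
    }
  }
})

test_that("secretion weights form a normalized geometric series at truncation", {
  for (d in c(0.05, 0.5, 0.79, 1)) {
    sd_obj <- secreted_distribution(tracer_spec("glucose_1_6"),
                                    model_params(d, 0.21))
    k <- sd_obj$n_turns_used
    w <- sum(d * (1 - d)^(0:k))
    expect_lte(w, 1 + 1e-12)
    # remaining geometric mass bounded by the truncation tolerance scale
    expect_lt(1 - w, (1 - d)^k + 1e-12)
  }
})

test_that("complete scrambling forces s3 = s4 and s5 = s6 exactly", {
  for (tr_id in c("glucose_1_6", "pyruvate_2")) {
    for (d in c(0.1, 0.79)) {
      for (p in c(0.05, 0.5)) {
        s <- secreted_distribution(tracer_spec(tr_id), model_params(d, p))$s
        expect_identical(s[["C3"]], s[["C4"]])
        expect_identical(s[["C5"]], s[["C6"]])
      }
    }
  }
})

test_that("spec'd closed-form example values for the glucose tracer reproduce", {
  # independent symbolic evaluation: a = (1-p) f_a, q = p f_p, r = (1-d)/2,
  # s2 = d*a, s3 = d q/2 + d (a + q/2) r/(1-r)
  d <- 0.79; p <- 0.21; f_p <- 0.80; f_a <- 0.56
  a <- (1 - p) * f_a; q <- p * f_p; r <- (1 - d) / 2
  s <- secreted_distribution(tracer_spec("glucose_1_6", f_p = f_p, f_a = f_a),
                             model_params(d, p))$s
  expect_equal(s[["C2"]], d * a, tolerance = 1e-10)
  expect_equal(s[["C3"]], d * q / 2 + d * (a + q / 2) * r / (1 - r),
               tolerance = 1e-10)
  expect_equal(s[["C2"]], 0.3495, tolerance = 1e-3)
  expect_equal(s[["C3"]], 0.1151, tolerance = 1e-3)
})

test_that("d = 0 is rejected and a zero input stays zero by linearity", {
  expect_error(secreted_distribution(tracer_spec("glucose_1_6"),
                                     model_params(1e-300, 0))$s,
               NA)  # tiny positive d is fine
  expect_error(model_params(0, 0.2), "\\(0, 1\\]")
  # d = 1: everything secreted at generation 0
  s <- secreted_distribution(tracer_spec("pyruvate_2", f_p = 1, f_a = 1),
                             model_params(1, 0))$s
  expect_equal(unname(s), c(1, 0, 0, 0, 0, 0))
})

test_that("R1 and R2 compute the documented ratios and reject degenerate input", {
  expect_equal(ratio_R1(c(0, 2, 1, 1, 0, 0)), 2 / 3)
  expect_equal(ratio_R1(c(0, 1, 1, 1, 0, 0)), 0.5)  # equal C2 = C3 = C4
  expect_equal(ratio_R1(c(0, 1, 0, 0, 0, 0)), 1)
  expect_error(ratio_R1(c(1, 0, 0, 0, 0, 0)), "C2 \\+ C4")

  expect_equal(ratio_R2(c(5, 0, 1, 1, 0.2, 0.2)), 5.2)
  expect_error(ratio_R2(c(1, 0, 0, 0, 1, 0)), "C3")
})

test_that("forward R2 at the fitted LNCaP parameters lands near the measured 5.2", {
  r2 <- ratio_R2(secreted_distribution(tracer_spec("pyruvate_2", f_p = 1, f_a = 0.7),
                                       model_params(0.79, 0.21)))
  expect_gt(r2, 5.2)
  expect_lt(r2, 5.35)
  # R2 depends only on the enrichment ratio f_a/f_p
  r2b <- ratio_R2(secreted_distribution(tracer_spec("pyruvate_2", f_p = 0.83,
                                                    f_a = 0.83 * 0.7),
                                        model_params(0.79, 0.21)))
  expect_equal(r2, r2b, tolerance = 1e-12)
})

test_that("expected turn count is the geometric mean (1-d)/d", {
  expect_equal(expected_turns(1), 0)
  expect_equal(expected_turns(0.5), 1)
  expect_equal(expected_turns(0.79), 0.21 / 0.79)
  expect_equal(round(expected_turns(0.7911631), 2), 0.26)
  expect_error(expected_turns(0), "\\(0, 1\\]")
  expect_error(expected_turns(1.2), "\\(0, 1\\]")
})

test_that("the R1-versus-d curve has the documented limits and monotonicity at p = 0", {
  curve <- r1_vs_d_curve(0, d_grid = seq(0.001, 1, length.out = 100))
  expect_equal(curve$R1[1], 0.5, tolerance = 1e-3)
  expect_equal(curve$R1[100], 1)
  expect_true(all(diff(curve$R1) >= 0))
  # p > 0 lowers the small-d end below the p = 0 curve (PC offset)
  curve_pc <- r1_vs_d_curve(0.3, d_grid = seq(0.001, 1, length.out = 100))
  expect_true(all(curve_pc$R1 < curve$R1))
  # single-point grid at d = 1 equals the generation-0 ratio
  single <- r1_vs_d_curve(0.21, d_grid = 1)
  g0 <- ratio_R1(initial_label_pattern(tracer_spec("glucose_1_6"),
                                       model_params(1, 0.21)))
  expect_equal(single$R1, g0)
  expect_error(r1_vs_d_curve(0, d_grid = numeric(0)), "non-empty")
  expect_error(r1_vs_d_curve(0, d_grid = c(0.5, 0)), "\\(0, 1\\]")
})
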