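## Seeded synthetic 1H and 13C media spectra from ground-truth parameters.
## Every estimator in the quantification chain can be validated against the
## generator's known inputs with no external data.

## arbitrary intensity scale: integral units per (mM x nucleus count)
INTENSITY_SCALE_1H <- 1000
INTENSITY_SCALE_13C <- 1000

#' Ground truth for a synthetic incubation experiment
#'
#' Collects the model parameters, pool enrichments, metabolite
#' concentrations, lineshape settings and noise level from which
#' [generate_experiment()] renders spectra. Defaults represent a confluent
#' LNCaP flask incubated for 48 h with a 13C tracer: d = 0.79, p = 0.21,
#' pyruvate-pool enrichment 0.80, acetyl-CoA enrichment 0.56, citrate
#' 0.134 mM (5.6 nmol/h per 1e6 cells over 48 h, 5e6 cells, 10 mL), lactate
#' 9 mM, alanine 0.6 mM, TSP 0.2 mM.
#'
#' @param d,p model parameters (see [model_params()]).
#' @param tracer_id tracer identity (see [tracer_spec()]).
#' @param f_p,f_a pool enrichments; `NULL` takes the tracer defaults.
#' @param citrate_conc_mM,lactate_conc_mM,alanine_conc_mM medium
#'   concentrations.
#' @param doublet_fraction_c2 fraction of the C2/4 signal rendered as the
#'   +/-19 Hz doublet. Multiplet fine structure reflects pairwise 13C-13C
#'   co-labeling, which the first-moment positional model does not track, so
#'   this is a free generator parameter, not derived from (d, p).
#' @param c3_pattern relative intensities of the five C3 lines
#'   (-38, -19, 0, +19, +38 Hz); normalized internally.
#' @param snr signal-to-noise ratio: tallest citrate line height over the
#'   per-point Gaussian noise standard deviation.
#' @param linewidth_13c_hz,linewidth_1h_hz Lorentzian FWHM of rendered lines.
#' @param glucose_remaining_mM remaining labeled glucose to render in the 13C
#'   spectrum (`NULL` omits the glucose resonances).
#' @param seed RNG seed for the noise.
#' @param cfg a [quant_config()].
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(d = 0.79, p = 0.21, tracer_id = "glucose_1_6",
                         f_p = NULL, f_a = NULL,
                         citrate_conc_mM = 0.134, lactate_conc_mM = 9,
                         alanine_conc_mM = 0.6,
                         doublet_fraction_c2 = 0.3,
                         c3_pattern = c(0.1, 0.2, 0.4, 0.2, 0.1),
                         snr = 100,
                         linewidth_13c_hz = 8, linewidth_1h_hz = 1.2,
                         glucose_remaining_mM = NULL,
                         seed = 1L,
                         cfg = quant_config(medium_volume_mL = 10,
                                            n_cells = 5e6)) {
  tracer <- tracer_spec(tracer_id, f_p = f_p, f_a = f_a)
  params <- model_params(d, p)
  stopifnot(citrate_conc_mM >= 0, lactate_conc_mM >= 0, alanine_conc_mM >= 0,
            snr > 0, doublet_fraction_c2 >= 0, doublet_fraction_c2 <= 1,
            length(c3_pattern) == 5L, all(c3_pattern >= 0),
            linewidth_13c_hz > 0, linewidth_1h_hz > 0)
  structure(list(tracer = tracer, params = params,
                 citrate_conc_mM = citrate_conc_mM,
                 lactate_conc_mM = lactate_conc_mM,
                 alanine_conc_mM = alanine_conc_mM,
                 doublet_fraction_c2 = doublet_fraction_c2,
                 c3_pattern = c3_pattern / sum(c3_pattern),
                 snr = snr,
                 linewidth_13c_hz = linewidth_13c_hz,
                 linewidth_1h_hz = linewidth_1h_hz,
                 glucose_remaining_mM = glucose_remaining_mM,
                 seed = as.integer(seed), cfg = cfg),
            class = "ground_truth")
}

## render a set of Lorentzian lines (ppm centers, integrals) onto an axis
render_lines <- function(ppm_axis, centers_ppm, integrals, fwhm_hz, mhz) {
  y <- numeric(length(ppm_axis))
  g <- fwhm_hz / 2
  for (i in seq_along(centers_ppm)) {
    if (integrals[i] <= 0) next
    amp <- integrals[i] / (pi * g)
    x <- (ppm_axis - centers_ppm[i]) * mhz
    y <- y + amp * g^2 / (g^2 + x^2)
  }
  y
}

#' Generate a synthetic incubation experiment
#'
#' Renders the 1H and 13C media spectra implied by a [ground_truth()]:
#'
#' * 13C: citrate C2/4 multiplet at 46.5 ppm (singlet plus +/-19 Hz doublet,
#'   split by `doublet_fraction_c2`), the five-line C3 pattern at 76.2 ppm,
#'   carboxyl C1/5 (179.7 ppm) and C6 (181.9 ppm) lines, lactate C3 at
#'   20.8 ppm, optional remaining-glucose lines, and the TSP reference at
#'   -2.0 ppm. Positional integrals follow the forward secretion model at the
#'   ground-truth (d, p, enrichments).
#' * 1H: citrate AB quartet (2.54-2.71 ppm), lactate methyl doublet at
#'   1.33 ppm with 13C satellites whose fraction equals `f_p`, alanine
#'   doublet at 1.48 ppm, and the TSP singlet at 0 ppm scaled to 0.2 mM and
#'   nine protons.
#'
#' Gaussian i.i.d. noise is added per point at the requested SNR (tallest
#' citrate line over noise sigma), seeded for bit-identical reproducibility.
#'
#' @param truth a [ground_truth()].
#' @return a list with `spectrum_1h`, `spectrum_13c`, and `metadata`
#'   (all ground-truth values plus the positional distribution used).
#' @export
generate_experiment <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  s <- secreted_distribution(truth$tracer, truth$params, method = "closed")
  pos_conc <- truth$citrate_conc_mM * s$s  # mM 13C at citrate C1..C6

  ## ---- 13C spectrum: -5..200 ppm, 32k points
  mhz_c <- 125.76
  ppm_c <- seq(-5, 200, length.out = 32768)
  k13 <- INTENSITY_SCALE_13C
  centers <- numeric(0); ints <- numeric(0)
  ## C2/4 multiplet: singlet + doublet at +/-19 Hz
  i24 <- k13 * (pos_conc[["C2"]] + pos_conc[["C4"]])
  df <- truth$doublet_fraction_c2
  centers <- c(centers, 46.5 - (J_C2C3_HZ / 2) / mhz_c, 46.5,
               46.5 + (J_C2C3_HZ / 2) / mhz_c)
  ints <- c(ints, i24 * df / 2, i24 * (1 - df), i24 * df / 2)
  ## C3 five-line pattern
  i3 <- k13 * pos_conc[["C3"]]
  off3 <- c(-J_C2C3_HZ, -J_C2C3_HZ / 2, 0, J_C2C3_HZ / 2, J_C2C3_HZ) / mhz_c
  centers <- c(centers, 76.2 + off3)
  ints <- c(ints, i3 * truth$c3_pattern)
  ## carboxyl region: combined C1/5 and C6
  centers <- c(centers, 179.7, 181.9)
  ints <- c(ints, k13 * (pos_conc[["C1"]] + pos_conc[["C5"]]),
            k13 * pos_conc[["C6"]])
  ## 13C lactate C3 (labeled fraction of the lactate pool)
  centers <- c(centers, 20.8)
  ints <- c(ints, k13 * truth$tracer$f_p * truth$lactate_conc_mM)
  ## remaining labeled glucose (two labeled carbons: C1 anomeric region, C6)
  if (!is.null(truth$glucose_remaining_mM)) {
    centers <- c(centers, 96.8, 61.4)
    ints <- c(ints, rep(k13 * 0.99 * truth$glucose_remaining_mM, 2))
  }
  ## TSP reference (nine equivalent methyl carbons not modeled; one line)
  centers <- c(centers, -2.0)
  ints <- c(ints, k13 * truth$cfg$tsp_conc_mM * 9)
  y_c <- render_lines(ppm_c, centers, ints, truth$linewidth_13c_hz, mhz_c)
  citrate_idx <- seq_along(centers) <= 10L  # citrate lines rendered first
  peak_heights_c <- ints / (pi * truth$linewidth_13c_hz / 2)
  tallest_cit_c <- max(peak_heights_c[citrate_idx], 0)
  sigma_c <- if (tallest_cit_c > 0) tallest_cit_c / truth$snr else
    max(peak_heights_c) / truth$snr

  ## ---- 1H spectrum: -0.5..10 ppm, 16k points (margin below 0 so the TSP
  ## reference window is fully covered)
  mhz_h <- 500.13
  ppm_h <- seq(-0.5, 10, length.out = 16384)
  k1 <- INTENSITY_SCALE_1H
  ch <- numeric(0); ih <- numeric(0)
  ## TSP singlet, 9 protons, 0.2 mM
  ch <- c(ch, 0); ih <- c(ih, k1 * truth$cfg$tsp_conc_mM * 9)
  ## citrate AB quartet, 4 protons (equal line intensities; idealized)
  cit_h <- k1 * truth$citrate_conc_mM * 4
  ch <- c(ch, 2.71, 2.68, 2.57, 2.54); ih <- c(ih, rep(cit_h / 4, 4))
  ## lactate methyl doublet + 13C satellites at +/- 1J_CH/2
  lac_h <- k1 * truth$lactate_conc_mM * 3
  f_p <- truth$tracer$f_p
  j_hh <- 6.9 / mhz_h; j_ch <- 127 / mhz_h
  ch <- c(ch, 1.33 - j_hh / 2, 1.33 + j_hh / 2)
  ih <- c(ih, rep(lac_h * (1 - f_p) / 2, 2))
  sat_each <- lac_h * f_p / 4
  ch <- c(ch, 1.33 - j_ch / 2 - j_hh / 2, 1.33 - j_ch / 2 + j_hh / 2,
          1.33 + j_ch / 2 - j_hh / 2, 1.33 + j_ch / 2 + j_hh / 2)
  ih <- c(ih, rep(sat_each, 4))
  ## alanine doublet
  ala_h <- k1 * truth$alanine_conc_mM * 3
  j_ala <- 7.2 / mhz_h
  ch <- c(ch, 1.48 - j_ala / 2, 1.48 + j_ala / 2); ih <- c(ih, rep(ala_h / 2, 2))
  y_h <- render_lines(ppm_h, ch, ih, truth$linewidth_1h_hz, mhz_h)
  heights_h <- ih / (pi * truth$linewidth_1h_hz / 2)
  tallest_cit_h <- max(heights_h[2:5], 0)
  sigma_h <- if (tallest_cit_h > 0) tallest_cit_h / truth$snr else
    max(heights_h) / truth$snr

  noise <- with_seed(truth$seed, list(
    c = stats::rnorm(length(y_c), 0, sigma_c),
    h = stats::rnorm(length(y_h), 0, sigma_h)))

  metadata <- list(
    tracer_id = truth$tracer$tracer_id, d = truth$params$d, p = truth$params$p,
    f_p = truth$tracer$f_p, f_a = truth$tracer$f_a,
    citrate_conc_mM = truth$citrate_conc_mM,
    lactate_conc_mM = truth$lactate_conc_mM,
    alanine_conc_mM = truth$alanine_conc_mM,
    doublet_fraction_c2 = truth$doublet_fraction_c2,
    snr = truth$snr, seed = truth$seed,
    linewidth_13c_hz = truth$linewidth_13c_hz,
    linewidth_1h_hz = truth$linewidth_1h_hz,
    glucose_remaining_mM = truth$glucose_remaining_mM,
    tsp_conc_mM = truth$cfg$tsp_conc_mM,
    medium_volume_mL = truth$cfg$medium_volume_mL,
    n_cells = truth$cfg$n_cells, incubation_h = truth$cfg$incubation_h,
    secreted_distribution = as.list(s$s),
    noise_sigma_13c = sigma_c, noise_sigma_1h = sigma_h)

  list(spectrum_1h = spectrum_1d(ppm_h, y_h + noise$h, nucleus = "1H",
                                 frequency_mhz = mhz_h),
       spectrum_13c = spectrum_1d(ppm_c, y_c + noise$c, nucleus = "13C",
                                  frequency_mhz = mhz_c),
       metadata = metadata)
}

#' Write a synthetic experiment to disk
#'
#' Writes the two spectra as tabular CSV (or JCAMP-DX) files plus a YAML
#' metadata sidecar recording every ground-truth value.
#'
#' @param experiment result of [generate_experiment()].
#' @param dir output directory (created if needed).
#' @param basename file basename stem.
#' @param format `"table"` (CSV) or `"jcamp"`.
#' @return (invisibly) the paths written.
#' @export
write_experiment <- function(experiment, dir, basename = "experiment",
                             format = c("table", "jcamp")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "table") "csv" else "jdx"
  p1 <- file.path(dir, paste0(basename, "_1H.", ext))
  p2 <- file.path(dir, paste0(basename, "_13C.", ext))
  pm <- file.path(dir, paste0(basename, "_meta.yaml"))
  if (format == "table") {
    write_spectrum_table(experiment$spectrum_1h, p1)
    write_spectrum_table(experiment$spectrum_13c, p2)
  } else {
    write_spectrum_jcamp(experiment$spectrum_1h, p1)
    write_spectrum_jcamp(experiment$spectrum_13c, p2)
  }
  write_metadata_yaml(experiment$metadata, pm)
  invisible(c(p1, p2, pm))
}

#' Write a standard suite of seeded fixture experiments
#'
#' Emits a reproducible set of synthetic experiments covering both engine
#' tracers, a range of secretion/PC parameters and SNRs, for use as test
#' fixtures by downstream tooling. Seeds are fixed, so repeated calls write
#' identical files.
#'
#' @param dir output directory.
#' @param format `"table"` or `"jcamp"` (see [write_experiment()]).
#' @return (invisibly) a data.frame indexing the written experiments.
#' @export
write_fixture_suite <- function(dir, format = c("table", "jcamp")) {
  format <- match.arg(format)
  grid <- expand.grid(tracer_id = c("glucose_1_6", "pyruvate_2"),
                      d = c(0.4, 0.79), p = c(0.1, 0.21),
                      snr = c(60, 150), stringsAsFactors = FALSE)
  grid <- grid[seq_len(12), ]
  grid$seed <- seq_len(nrow(grid))
  grid$basename <- sprintf("fixture%02d_%s", seq_len(nrow(grid)),
                           grid$tracer_id)
  for (i in seq_len(nrow(grid))) {
    tr <- ground_truth(d = grid$d[i], p = grid$p[i],
                       tracer_id = grid$tracer_id[i], snr = grid$snr[i],
                       seed = grid$seed[i])
    write_experiment(generate_experiment(tr), dir, grid$basename[i],
                     format = format)
  }
  utils::write.csv(grid, file.path(dir, "fixtures_index.csv"),
                   row.names = FALSE)
  invisible(grid)
}

#' End-to-end parameter recovery on synthetic spectra
#'
#' Runs the full analysis chain on a paired pair of synthetic experiments:
#' generate a glucose-tracer and a pyruvate-tracer experiment at the same
#' (d, p), fit the citrate 13C regions, form the measured ratios R1 and R2,
#' estimate the pyruvate enrichment from the 1H lactate satellites, and
#' invert the model. Reports estimates against the ground truth at every
#' stage.
#'
#' @param truth_glucose a [ground_truth()] with a glucose tracer.
#' @param truth_pyruvate optional [ground_truth()] with a pyruvate tracer;
#'   by default derived from `truth_glucose` (same d, p, concentrations,
#'   SNR; seed offset by 1; default pyruvate enrichments).
#' @return an object of class `recovery_report`: list with `truth`,
#'   `estimates` (R1, R2, f_p, d, p), `errors`, and the underlying `fit`.
#' @export
end_to_end_recovery <- function(truth_glucose, truth_pyruvate = NULL) {
  stopifnot(inherits(truth_glucose, "ground_truth"))
  if (truth_glucose$tracer$tracer_id != "glucose_1_6") {
    stop("truth_glucose must use the glucose_1_6 tracer", call. = FALSE)
  }
  if (is.null(truth_pyruvate)) {
    truth_pyruvate <- ground_truth(
      d = truth_glucose$params$d, p = truth_glucose$params$p,
      tracer_id = "pyruvate_2",
      citrate_conc_mM = truth_glucose$citrate_conc_mM,
      lactate_conc_mM = truth_glucose$lactate_conc_mM,
      alanine_conc_mM = truth_glucose$alanine_conc_mM,
      doublet_fraction_c2 = truth_glucose$doublet_fraction_c2,
      c3_pattern = truth_glucose$c3_pattern, snr = truth_glucose$snr,
      linewidth_13c_hz = truth_glucose$linewidth_13c_hz,
      linewidth_1h_hz = truth_glucose$linewidth_1h_hz,
      seed = truth_glucose$seed + 1L, cfg = truth_glucose$cfg)
  }
  if (truth_glucose$citrate_conc_mM <= 0) {
    stop("fit stage: citrate concentration is zero; no citrate signal to fit",
         call. = FALSE)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
    })
  }
  exp_g <- run_stage("generate/glucose", generate_experiment(truth_glucose))
  exp_p <- run_stage("generate/pyruvate", generate_experiment(truth_pyruvate))
  c24 <- run_stage("fit/C2-4", fit_citrate_c24_region(exp_g$spectrum_13c))
  ## transfer the linewidth fitted on the strong C2/4 multiplet to the much
  ## weaker C3 multiplet of the same molecule
  lw_g <- min(max(c24$components$fwhm_hz[2], 4), 20)
  c3g <- run_stage("fit/C3-glucose",
                   fit_citrate_c3_region(exp_g$spectrum_13c,
                                         lw_fixed_hz = lw_g))
  r1_hat <- run_stage("ratios/R1", measured_ratio_R1(c24, c3g))
  c15 <- run_stage("fit/C1-5", fit_singlet(exp_p$spectrum_13c, 179.7,
                                           label = "C1/5"))
  lw_p <- min(max(c15$components$fwhm_hz[1], 4), 20)
  c3p <- run_stage("fit/C3-pyruvate",
                   fit_citrate_c3_region(exp_p$spectrum_13c,
                                         lw_fixed_hz = lw_p))
  r2_hat <- run_stage("ratios/R2", measured_ratio_R2(c15, c3p))
  lac <- run_stage("fit/lactate-1H", fit_lactate_region(exp_g$spectrum_1h))
  f_p_hat <- run_stage("enrichment",
                       enrichment_from_satellites(lac$group_totals$main,
                                                  lac$group_totals$satellite))
  fit <- run_stage("invert",
                   fit_citrate_flux(r1_hat, r2_hat,
                                    glucose_tracer = truth_glucose$tracer,
                                    pyruvate_tracer = truth_pyruvate$tracer))
  d_true <- truth_glucose$params$d
  p_true <- truth_glucose$params$p
  r1_true <- ratio_R1(secreted_distribution(truth_glucose$tracer,
                                            truth_glucose$params,
                                            method = "closed"))
  r2_true <- ratio_R2(secreted_distribution(truth_pyruvate$tracer,
                                            truth_pyruvate$params,
                                            method = "closed"))
  estimates <- c(R1 = r1_hat, R2 = r2_hat, f_p = f_p_hat,
                 d = fit$coefficients[["d"]], p = fit$coefficients[["p"]])
  truth_vec <- c(R1 = r1_true, R2 = r2_true, f_p = truth_glucose$tracer$f_p,
                 d = d_true, p = p_true)
  structure(list(truth = truth_vec, estimates = estimates,
                 errors = estimates - truth_vec, fit = fit),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("End-to-end synthetic recovery\n")
  tab <- rbind(truth = x$truth, estimate = x$estimates, error = x$errors)
  print(round(tab, 4))
  invisible(x)
}
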