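## TSP-referenced quantification, production/consumption rates, and
## fractional 13C enrichment estimators.

group_total <- function(fit, name) {
  if (inherits(fit, "multiplet_fit")) {
    if (!is.null(fit$group_totals[[name]])) return(fit$group_totals[[name]])
    return(fit$total_integral)
  }
  if (is.numeric(fit) && length(fit) == 1L) return(fit)
  stop("expected a multiplet_fit or a single numeric integral", call. = FALSE)
}

#' Measured citrate carbon ratio R1 from region fits
#'
#' `R1 = ((C2/4 total) - (C3 total)) / (C2/4 total)` from the fitted group
#' integrals of the two citrate 13C regions of a \[1,6-13C2\]glucose
#' experiment.
#'
#' @param c24 result of [fit_citrate_c24_region()] (or its total integral).
#' @param c3 result of [fit_citrate_c3_region()] (or its total integral).
#' @return the measured ratio R1.
#' @export
measured_ratio_R1 <- function(c24, c3) {
  i24 <- group_total(c24, "c24_total")
  i3 <- group_total(c3, "c3_total")
  if (i24 <= 0) stop("undefined ratio: C2/4 total integral is zero", call. = FALSE)
  (i24 - i3) / i24
}

#' Measured citrate carbon ratio R2 from region fits
#'
#' `R2 = (C1/5 total) / (C3 total)` from the fitted citrate carboxyl C1/5
#' resonance and the C3 region of a \[2-13C\]pyruvate experiment.
#'
#' @param c15 fit of the combined citrate C1/C5 carboxyl resonance
#'   (e.g. [fit_singlet()]) or its total integral.
#' @param c3 result of [fit_citrate_c3_region()] (or its total integral).
#' @return the measured ratio R2.
#' @export
measured_ratio_R2 <- function(c15, c3) {
  i15 <- group_total(c15, "c15_total")
  i3 <- group_total(c3, "c3_total")
  if (i3 <= 0) stop("undefined ratio: C3 total integral is zero", call. = FALSE)
  i15 / i3
}

#' Concentration from a TSP-referenced 1H integral
#'
#' `conc = (I_met / n_protons) / (I_TSP / 9) * tsp_conc_mM`: the metabolite
#' integral per contributing proton against the TSP reference integral per
#' proton, scaled by the known TSP concentration (0.2 mM by default).
#'
#' @param metabolite_integral 1H integral of the metabolite multiplet.
#' @param n_protons number of protons contributing to that multiplet.
#' @param tsp_integral 1H integral of the TSP singlet from the same spectrum.
#' @param cfg a [quant_config()].
#' @return concentration in mM.
#' @examples
#' cfg <- quant_config(medium_volume_mL = 10, n_cells = 1e6)
#' quantify_vs_tsp(1, 9, 1, cfg)  # 0.2 mM
#' @export
quantify_vs_tsp <- function(metabolite_integral, n_protons, tsp_integral, cfg) {
  stopifnot(inherits(cfg, "quant_config"))
  metabolite_integral <- group_total(metabolite_integral, "total")
  tsp_integral <- group_total(tsp_integral, "total")
  if (n_protons < 1) stop("n_protons must be >= 1", call. = FALSE)
  if (tsp_integral <= 0) stop("TSP integral is zero; cannot reference", call. = FALSE)
  (metabolite_integral / n_protons) / (tsp_integral / cfg$tsp_protons) *
    cfg$tsp_conc_mM
}

#' Average production rate over the incubation
#'
#' Converts an end-point medium concentration into an average production rate
#' in nmol/h per 1e6 cells:
#' `rate = conc_mM * medium_volume_mL * 1000 / (incubation_h * n_cells / 1e6)`.
#'
#' @param conc_mM metabolite concentration in the medium (mM).
#' @param cfg a [quant_config()] with `medium_volume_mL` and `n_cells` set.
#' @return rate in nmol/h per 1e6 cells.
#' @export
production_rate <- function(conc_mM, cfg) {
  stopifnot(inherits(cfg, "quant_config"))
  if (is.null(cfg$medium_volume_mL) || is.null(cfg$n_cells)) {
    stop("medium_volume_mL and n_cells must be set in the quant_config for rates",
         call. = FALSE)
  }
  if (conc_mM < 0) stop("concentration must be nonnegative", call. = FALSE)
  conc_mM * cfg$medium_volume_mL * 1000 / (cfg$incubation_h * cfg$n_cells / 1e6)
}

#' Fractional 13C enrichment from satellite integrals
#'
#' `f = satellite / (satellite + unlabeled)`: the fraction of molecules
#' carrying 13C at the observed position, from the 13C satellite multiplet
#' and the unlabeled (centerband) multiplet of the same proton signal.
#' Applied to the lactate methyl signal this estimates the pyruvate-pool
#' enrichment.
#'
#' @param unlabeled_multiplet_integral integral of the unlabeled multiplet.
#' @param satellite_multiplet_integral integral of the 13C satellites.
#' @return enrichment fraction in \[0, 1\].
#' @examples
#' enrichment_from_satellites(1, 4)  # 0.8
#' @export
enrichment_from_satellites <- function(unlabeled_multiplet_integral,
                                       satellite_multiplet_integral) {
  u <- unlabeled_multiplet_integral
  s <- satellite_multiplet_integral
  if (u < 0 || s < 0) stop("integrals must be nonnegative", call. = FALSE)
  if (u + s == 0) stop("both integrals are zero; enrichment undefined", call. = FALSE)
  s / (s + u)
}

#' Acetyl-CoA 13C enrichment from glutamate labeling
#'
#' The acetyl-CoA pool enrichment is estimated from the 13C labeling pattern
#' of secreted glutamate (label entering via acetyl-CoA appears at glutamate
#' C4). The multiplet decomposition into labeled and unlabeled components is
#' supplied by the caller; the arithmetic is the same fraction as
#' [enrichment_from_satellites()].
#'
#' @param labeled_integral integral of the 13C-labeled component.
#' @param unlabeled_integral integral of the unlabeled component.
#' @return enrichment fraction in \[0, 1\].
#' @export
acetyl_enrichment <- function(labeled_integral, unlabeled_integral) {
  enrichment_from_satellites(unlabeled_integral, labeled_integral)
}

#' Glucose consumption rate from 13C integrals
#'
#' Estimates the remaining labeled glucose by comparing the glucose 13C
#' integral with the 13C-lactate integral in the same 13C spectrum, anchored
#' to the absolute 13C-lactate concentration obtained from the 1H spectrum
#' (satellites referenced to TSP):
#' `remaining = lac13_conc_mM * (I_glc / I_lac) / carbons_per_glucose`.
#' The doubly labeled glucose carries two 13C carbons per molecule against
#' one for \[3-13C\]lactate, hence the default division by 2. Consumption is
#' `initial - remaining`, converted to a rate as in [production_rate()].
#'
#' @param glc13C_integral 13C integral of the labeled glucose resonances.
#' @param lac13C_integral 13C integral of the labeled lactate resonance.
#' @param lac_conc_mM concentration of 13C-labeled lactate (mM), from
#'   [quantify_vs_tsp()] on the satellite integrals.
#' @param glucose_initial_mM initial labeled glucose concentration (mM).
#' @param cfg a [quant_config()].
#' @param carbons_per_glucose labeled carbons per glucose molecule relative
#'   to one per lactate (default 2 for \[1,6-13C2\]glucose).
#' @return consumption rate in nmol/h per 1e6 cells.
#' @export
glucose_consumption_rate <- function(glc13C_integral, lac13C_integral,
                                     lac_conc_mM, glucose_initial_mM, cfg,
                                     carbons_per_glucose = 2) {
  if (lac13C_integral <= 0) {
    stop("13C lactate integral is zero; cannot anchor the glucose integral",
         call. = FALSE)
  }
  if (glc13C_integral < 0) stop("integrals must be nonnegative", call. = FALSE)
  remaining <- lac_conc_mM * (glc13C_integral / lac13C_integral) /
    carbons_per_glucose
  consumed <- glucose_initial_mM - remaining
  if (consumed < -1e-9 * glucose_initial_mM) {
    warning("estimated remaining glucose exceeds the initial concentration; ",
            "clamping consumption to zero")
  }
  consumed <- max(0, consumed)
  production_rate(consumed, cfg)
}

#' Oxidative triose consumption rate
#'
#' Each consumed glucose yields two trioses; trioses leaving as lactate,
#' alanine or other measured effluxes are not oxidized, so the residual
#' `2 * glucose_rate - lactate_rate - alanine_rate - other_efflux` estimates
#' the triose flux into oxidative metabolism. Negative balances are floored
#' at zero with a warning.
#'
#' @param glucose_rate glucose consumption rate (nmol/h per 1e6 cells).
#' @param lactate_rate,alanine_rate production rates of lactate and alanine.
#' @param other_efflux other measured triose effluxes (default 0).
#' @return oxidative triose consumption rate (nmol/h per 1e6 cells).
#' @examples
#' oxidative_triose_rate(255, 200, 30, 30)  # 250
#' @export
oxidative_triose_rate <- function(glucose_rate, lactate_rate, alanine_rate,
                                  other_efflux = 0) {
  rates <- c(glucose_rate, lactate_rate, alanine_rate, other_efflux)
  if (any(rates < 0)) stop("rates must be nonnegative", call. = FALSE)
  out <- 2 * glucose_rate - lactate_rate - alanine_rate - other_efflux
  if (out < 0) {
    warning("triose balance is negative (effluxes exceed 2 x glucose); flooring at 0")
    out <- 0
  }
  out
}

#' Anaplerotic flux through pyruvate carboxylase
#'
#' The part of the oxidative triose consumption entering the Krebs cycle via
#' PC: `triose_rate * p`.
#'
#' @param triose_rate oxidative triose consumption rate (nmol/h per 1e6
#'   cells), see [oxidative_triose_rate()].
#' @param p PC fraction in \[0, 1).
#' @return PC anaplerotic rate in the same units.
#' @examples
#' pc_anaplerotic_rate(250, 0.21)  # 52.5
#' @export
pc_anaplerotic_rate <- function(triose_rate, p) {
  if (p < 0 || p >= 1) stop("p must lie in [0, 1)", call. = FALSE)
  if (triose_rate < 0) stop("triose_rate must be nonnegative", call. = FALSE)
  triose_rate * p
}
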