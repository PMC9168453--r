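#' Tracer specification
#'
#' Describes a 13C-labeled substrate experiment: which citrate carbon
#' positions receive label via the pyruvate dehydrogenase complex
#' (acetyl-CoA) route and which via pyruvate carboxylase (PC)-derived
#' oxaloacetate, together with the fractional 13C enrichments of the
#' pyruvate pool (`f_p`) and the acetyl-CoA pool (`f_a`).
#'
#' Supported tracers:
#' \describe{
#'   \item{`glucose_1_6`}{\[1,6-13C2\]glucose, glycolysed to \[3-13C\]pyruvate.
#'     Acetyl-CoA entry labels citrate C2; PC entry labels C3/C4 (scrambled).
#'     Default enrichments `f_p = 0.80`, `f_a = 0.56` (LNCaP values).}
#'   \item{`pyruvate_2`}{\[2-13C\]pyruvate. Acetyl-CoA entry labels citrate C1;
#'     PC entry labels C3/C4. The acetyl-CoA enrichment for this experiment is
#'     not directly measurable from the media spectra; by convention the
#'     default keeps the acetyl-CoA/pyruvate enrichment ratio observed in the
#'     glucose experiment (0.56/0.80 = 0.70), applied to the measured pyruvate
#'     enrichment of 0.83, i.e. `f_p = 0.83`, `f_a = 0.581`. Both can be
#'     overridden. Only the ratio `f_a/f_p` affects the ratio R2.}
#'   \item{`glutamine_5`}{\[5-13C\]glutamine. Label enters citrate directly at
#'     C1 (reductive carboxylation) or at C5/C6 (oxidative Krebs-cycle route);
#'     this tracer is handled by the glutamine split functions
#'     (see [reductive_fraction()]) and is not run through the turn-transition
#'     engine.}
#' }
#'
#' @param tracer_id one of `"glucose_1_6"`, `"pyruvate_2"`, `"glutamine_5"`.
#' @param f_p fractional 13C enrichment of the pyruvate pool, in \[0, 1\].
#' @param f_a fractional 13C enrichment of the acetyl-CoA pool, in \[0, 1\].
#' @return an object of class `tracer_spec`.
#' @examples
#' tracer_spec("glucose_1_6")
#' tracer_spec("pyruvate_2", f_p = 1, f_a = 0.7)
#' @export
tracer_spec <- function(tracer_id = c("glucose_1_6", "pyruvate_2", "glutamine_5"),
                        f_p = NULL, f_a = NULL) {
  if (!is.character(tracer_id) || length(tracer_id) != 1L ||
      !tracer_id %in% c("glucose_1_6", "pyruvate_2", "glutamine_5")) {
    stop("unknown tracer_id; supported tracers: 'glucose_1_6', 'pyruvate_2', 'glutamine_5'",
         call. = FALSE)
  }
  defaults <- switch(tracer_id,
    glucose_1_6 = list(f_p = 0.80, f_a = 0.56,  pdc = 2L, pc = c(3L, 4L)),
    pyruvate_2  = list(f_p = 0.83, f_a = 0.83 * 0.70, pdc = 1L, pc = c(3L, 4L)),
    glutamine_5 = list(f_p = 1.0,  f_a = 1.0,   pdc = integer(0), pc = integer(0))
  )
  if (is.null(f_p)) f_p <- defaults$f_p
  if (is.null(f_a)) f_a <- defaults$f_a
  stopifnot(is.numeric(f_p), length(f_p) == 1L, is.finite(f_p),
            is.numeric(f_a), length(f_a) == 1L, is.finite(f_a))
  if (f_p < 0 || f_p > 1 || f_a < 0 || f_a > 1) {
    stop("enrichments f_p and f_a must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(tracer_id = tracer_id,
         pdc_entry_positions = defaults$pdc,
         pc_entry_positions = defaults$pc,
         # direct citrate entry positions for [5-13C]glutamine
         reductive_entry_position = if (tracer_id == "glutamine_5") 1L else integer(0),
         oxidative_entry_positions = if (tracer_id == "glutamine_5") c(5L, 6L) else integer(0),
         f_p = f_p, f_a = f_a),
    class = "tracer_spec"
  )
}

#' @export
print.tracer_spec <- function(x, ...) {
  cat("<tracer_spec> ", x$tracer_id, "\n", sep = "")
  if (length(x$pdc_entry_positions)) {
    cat("  acetyl-CoA (PDC) entry at citrate C", x$pdc_entry_positions,
        "; PC entry at C", paste(x$pc_entry_positions, collapse = "/C"), "\n", sep = "")
  } else {
    cat("  direct entry: C1 (reductive), C5/C6 (oxidative)\n")
  }
  cat(sprintf("  pool enrichments: f_p = %.3f, f_a = %.3f\n", x$f_p, x$f_a))
  invisible(x)
}

#' Model parameters for the citrate secretion model
#'
#' @param d apparent per-turn citrate secretion fraction, in (0, 1]. The
#'   fraction of citrate-equivalents diverging from the Krebs cycle at every
#'   turn; an upper bound on the true citrate secretion fraction when other
#'   cataplerotic effluxes exist.
#' @param p PC fraction: the fraction of labeled-carbon entry events per
#'   citrate that arrive via pyruvate carboxylase, in \[0, 1).
#' @param max_turns maximum number of Krebs-cycle turns simulated.
#' @param tol convergence threshold on the largest positional increment.
#' @return an object of class `model_params`.
#' @export
model_params <- function(d, p, max_turns = 200L, tol = 1e-12) {
  stopifnot(is.numeric(d), length(d) == 1L, is.finite(d),
            is.numeric(p), length(p) == 1L, is.finite(p))
  if (d <= 0 || d > 1) stop("secretion fraction d must lie in (0, 1]", call. = FALSE)
  if (p < 0 || p >= 1) stop("PC fraction p must lie in [0, 1)", call. = FALSE)
  max_turns <- as.integer(max_turns)
  if (is.na(max_turns) || max_turns < 1L) stop("max_turns must be >= 1", call. = FALSE)
  if (!is.numeric(tol) || length(tol) != 1L || !is.finite(tol) || tol <= 0) {
    stop("tol must be a positive number", call. = FALSE)
  }
  structure(list(d = d, p = p, max_turns = max_turns, tol = tol),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> d = %.4f, p = %.4f (max_turns = %d, tol = %g)\n",
              x$d, x$p, x$max_turns, x$tol))
  invisible(x)
}

#' Quantification configuration
#'
#' Experiment-level constants needed to convert TSP-referenced integrals into
#' concentrations and production rates. The medium volume has no default: the
#' total incubation volume must be supplied explicitly to avoid silent unit
#' errors (only aliquot volumes are fixed by the sample-preparation protocol).
#'
#' @param medium_volume_mL total incubation medium volume in mL (required for
#'   rate calculations).
#' @param n_cells number of cells in the flask (required for rate
#'   calculations).
#' @param tsp_conc_mM TSP internal reference concentration, default 0.2 mM.
#' @param tsp_protons number of TSP protons contributing to its singlet (9).
#' @param incubation_h incubation time in hours, default 48.
#' @return an object of class `quant_config`.
#' @export
quant_config <- function(medium_volume_mL = NULL, n_cells = NULL,
                         tsp_conc_mM = 0.2, tsp_protons = 9L,
                         incubation_h = 48) {
  chk_pos <- function(x, nm, allow_null = FALSE) {
    if (is.null(x)) {
      if (allow_null) return(invisible(NULL))
      stop(nm, " must be supplied", call. = FALSE)
    }
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      stop(nm, " must be a positive number", call. = FALSE)
    }
  }
  chk_pos(medium_volume_mL, "medium_volume_mL", allow_null = TRUE)
  chk_pos(n_cells, "n_cells", allow_null = TRUE)
  chk_pos(tsp_conc_mM, "tsp_conc_mM")
  chk_pos(tsp_protons, "tsp_protons")
  chk_pos(incubation_h, "incubation_h")
  structure(list(medium_volume_mL = medium_volume_mL, n_cells = n_cells,
                 tsp_conc_mM = tsp_conc_mM, tsp_protons = as.integer(tsp_protons),
                 incubation_h = incubation_h),
            class = "quant_config")
}
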