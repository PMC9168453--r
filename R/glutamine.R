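## Reductive vs oxidative split of [5-13C]glutamine-derived citrate label.
## Reductive carboxylation places label at citrate C1; the oxidative
## Krebs-cycle route places it (before any exchange loss) equally at C5 and
## C6. HMBC detection bias per carbon pair is absorbed by a single
## multiplicative correction factor calibrated on unlabeled citrate.

#' HMBC detection-bias correction factor
#'
#' In an unlabeled (natural-abundance) citrate sample the true C1/5:C6 13C
#' ratio is 2:1; comparing this to the observed HMBC peak-intensity ratio
#' gives a multiplicative correction factor `2 / observed` such that
#' `factor * observed = 2` exactly.
#'
#' @param observed_unlabeled_ratio observed C1/5:C6 intensity ratio of the
#'   unlabeled reference sample (> 0).
#' @return the correction factor.
#' @examples
#' hmbc_correction_factor(1.6)  # 1.25
#' @export
hmbc_correction_factor <- function(observed_unlabeled_ratio) {
  if (!is.numeric(observed_unlabeled_ratio) ||
      length(observed_unlabeled_ratio) != 1L ||
      !is.finite(observed_unlabeled_ratio) || observed_unlabeled_ratio <= 0) {
    stop("observed unlabeled C1/5:C6 ratio must be a positive number",
         call. = FALSE)
  }
  2 / observed_unlabeled_ratio
}

#' Reductive fraction of glutamine-derived citrate label
#'
#' With oxidative labeling `C5 = x` and `C6 = lambda * x` (lambda models
#' possible loss of C6 label by exchange with unlabeled CO2; lambda = 1 means
#' C5 and C6 equally labeled) and reductive labeling `C1 = y`, the corrected
#' ratio `rho = (C1 + C5)/C6 = (y + x)/(lambda x)` gives
#' `y/x = lambda * rho - 1` and the reductive fraction of the observed label
#' `f_red = (lambda * rho - 1) / (lambda * rho + lambda)`; at lambda = 1 this
#' is `(rho - 1)/(rho + 1)`.
#'
#' @param rho_corrected corrected (C1+C5):C6 ratio; must be at least
#'   `1/lambda` (the purely oxidative floor).
#' @param lambda C6 retention factor in (0, 1\], default 1.
#' @return reductive fraction in \[0, 1\].
#' @examples
#' reductive_fraction(4)  # 0.6
#' @export
reductive_fraction <- function(rho_corrected, lambda = 1) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0 || lambda > 1) {
    stop("lambda must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(rho_corrected) || length(rho_corrected) != 1L ||
      !is.finite(rho_corrected)) {
    stop("rho_corrected must be a finite number", call. = FALSE)
  }
  if (rho_corrected < 1 / lambda) {
    stop(sprintf(paste0("corrected ratio rho = %.3f is below the purely ",
                        "oxidative floor 1/lambda = %.3f; integrals are ",
                        "inconsistent with the labeling model"),
                 rho_corrected, 1 / lambda), call. = FALSE)
  }
  yx <- lambda * rho_corrected - 1
  yx / (yx + 1 + lambda)
}

#' Reductive/oxidative split of glutamine-derived citrate label
#'
#' Applies the HMBC correction factor to the observed labeled-sample
#' C1/5:C6 intensity ratio and computes the reductive and oxidative
#' fractions.
#'
#' @param observed_labeled_ratio observed C1/5:C6 intensity ratio of the
#'   \[5-13C\]glutamine sample.
#' @param observed_unlabeled_ratio observed C1/5:C6 intensity ratio of the
#'   unlabeled reference sample (used for the correction factor); ignore by
#'   passing `correction_factor` directly.
#' @param correction_factor optional explicit correction factor (overrides
#'   `observed_unlabeled_ratio`).
#' @param lambda C6 retention factor in (0, 1\], default 1.
#' @return an object of class `glutamine_split` with fields
#'   `correction_factor`, `corrected_ratio_rho`, `reductive_fraction`,
#'   `oxidative_fraction`, `c6_attenuation_lambda`.
#' @examples
#' glutamine_split(3.2, observed_unlabeled_ratio = 1.6)  # corrected rho = 4
#' @export
glutamine_split <- function(observed_labeled_ratio,
                            observed_unlabeled_ratio = NULL,
                            correction_factor = NULL, lambda = 1) {
  if (is.null(correction_factor)) {
    if (is.null(observed_unlabeled_ratio)) {
      stop("supply either observed_unlabeled_ratio or correction_factor",
           call. = FALSE)
    }
    correction_factor <- hmbc_correction_factor(observed_unlabeled_ratio)
  }
  if (observed_labeled_ratio <= 0) {
    stop("observed labeled C1/5:C6 ratio must be positive", call. = FALSE)
  }
  rho <- correction_factor * observed_labeled_ratio
  f_red <- reductive_fraction(rho, lambda)
  structure(list(correction_factor = correction_factor,
                 corrected_ratio_rho = rho,
                 reductive_fraction = f_red,
                 oxidative_fraction = 1 - f_red,
                 c6_attenuation_lambda = lambda),
            class = "glutamine_split")
}

#' @export
print.glutamine_split <- function(x, ...) {
  cat("<glutamine_split>\n")
  cat(sprintf("  corrected C1/5:C6 ratio rho = %.3f (correction factor %.3f)\n",
              x$corrected_ratio_rho, x$correction_factor))
  cat(sprintf("  reductive fraction = %.3f, oxidative fraction = %.3f (lambda = %.2f)\n",
              x$reductive_fraction, x$oxidative_fraction,
              x$c6_attenuation_lambda))
  invisible(x)
}

#' Percent contribution of glutamine carbons to the citrate C1/C5/C6 pool
#'
#' Infers the total labeled C1 + C5 + C6 citrate carbon concentration from
#' the measured labeled C1/5 concentration and the reductive/oxidative split
#' (with `C5 = x`, `C6 = lambda * x`, `C1 = y` and
#' `rho = (y + x)/(lambda x)` the observed total is
#' `c15 * (1 + 1/rho)` -- note lambda cancels when rho is measured), and
#' expresses it as a percentage of the full C1,5,6 carbon pool of secreted
#' citrate (`3 * citrate_conc`).
#'
#' With `include_lost_c6 = TRUE` the label inferred to have been lost from C6
#' by exchange (lambda < 1) is added back, counting label as it entered
#' citrate: total `c15 * (1 + 1/(lambda * rho))`.
#'
#' @param c15_labeled_conc concentration of 13C label at citrate C1 + C5
#'   (mM carbon equivalents).
#' @param split a [glutamine_split()].
#' @param citrate_conc total secreted citrate concentration (mM).
#' @param include_lost_c6 add back C6 label inferred lost to exchange.
#' @return percent contribution in \[0, 100\].
#' @export
glutamine_contribution_pct <- function(c15_labeled_conc, split, citrate_conc,
                                       include_lost_c6 = FALSE) {
  stopifnot(inherits(split, "glutamine_split"))
  if (citrate_conc <= 0) stop("citrate concentration must be positive", call. = FALSE)
  if (c15_labeled_conc < 0) stop("labeled concentration must be nonnegative", call. = FALSE)
  rho <- split$corrected_ratio_rho
  lam <- split$c6_attenuation_lambda
  c6 <- if (include_lost_c6) c15_labeled_conc / (lam * rho) else
    c15_labeled_conc / rho
  total_labeled <- c15_labeled_conc + c6
  100 * total_labeled / (3 * citrate_conc)
}
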