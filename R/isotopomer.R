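## Forward positional labeling model of citrate through repeated Krebs-cycle
## turns. The state vector c = (C1..C6) holds the expected fractional 13C
## excess at each citrate carbon for one citrate generation; only first
## moments are tracked (the ratios R1 and R2 are linear in positional
## integrals, so no isotopomer bond patterns are needed).

position_names <- paste0("C", 1:6)

#' Generation-0 citrate labeling pattern
#'
#' Places the per-citrate labeled-carbon entry weights: `(1 - p) * f_a` on the
#' single acetyl-CoA (PDC) entry position and `p * f_p` split equally over the
#' two PC entry positions C3/C4 (complete scrambling of the PC-derived
#' oxaloacetate over the malate/fumarate/oxaloacetate pool).
#'
#' @param tracer a [tracer_spec()]; must be a tracer that is run through the
#'   Krebs-cycle engine (`glucose_1_6` or `pyruvate_2`).
#' @param params a [model_params()].
#' @return a named numeric vector of length 6 (citrate C1..C6), class
#'   `citrate_label_state`.
#' @examples
#' initial_label_pattern(tracer_spec("pyruvate_2", f_p = 1, f_a = 1),
#'                       model_params(d = 0.5, p = 0))
#' @export
initial_label_pattern <- function(tracer, params) {
  stopifnot(inherits(tracer, "tracer_spec"), inherits(params, "model_params"))
  if (length(tracer$pdc_entry_positions) == 0L) {
    stop("tracer '", tracer$tracer_id,
         "' does not pass through the Krebs-cycle engine; supported tracers: ",
         "'glucose_1_6', 'pyruvate_2'", call. = FALSE)
  }
  c0 <- stats::setNames(numeric(6), position_names)
  c0[tracer$pdc_entry_positions] <- (1 - params$p) * tracer$f_a
  c0[tracer$pc_entry_positions] <- params$p * tracer$f_p / 2
  structure(c0, class = c("citrate_label_state", "numeric"))
}

#' Krebs-cycle turn transition matrix
#'
#' The linear map taking the positional label of one citrate generation to the
#' next: C1 and C4 move to C5/C6 (half each), C2 and C3 redistribute over
#' C3/C4 (half each, complete scrambling at the symmetric four-carbon pool),
#' and C5/C6 are lost as CO2. Columns are source positions, rows targets;
#' columns C1..C4 each sum to 1, columns C5/C6 to 0 (sub-stochastic).
#'
#' @return a 6 x 6 numeric matrix.
#' @export
turn_transition_matrix <- function() {
  t_mat <- matrix(0, 6, 6, dimnames = list(position_names, position_names))
  t_mat[c("C5", "C6"), "C1"] <- 0.5
  t_mat[c("C3", "C4"), "C2"] <- 0.5
  t_mat[c("C3", "C4"), "C3"] <- 0.5
  t_mat[c("C5", "C6"), "C4"] <- 0.5
  t_mat
}

#' Apply one Krebs-cycle turn to a citrate label state
#'
#' @param state numeric vector of length 6 (citrate C1..C6 positional label).
#' @return the positional label of the next citrate generation; no fresh
#'   label is added by this operation.
#' @examples
#' turn_transition(c(1, 0, 0, 0, 0, 0))  # C1 -> C5/C6
#' @export
turn_transition <- function(state) {
  state <- validate_label_state(state)
  out <- drop(turn_transition_matrix() %*% state)
  structure(stats::setNames(out, position_names),
            class = c("citrate_label_state", "numeric"))
}

validate_label_state <- function(state) {
  state <- unclass(state)
  if (!is.numeric(state) || length(state) != 6L || anyNA(state)) {
    stop("a citrate label state is a numeric vector of length 6 (C1..C6)",
         call. = FALSE)
  }
  if (any(state < 0)) stop("positional label must be nonnegative", call. = FALSE)
  as.numeric(state)
}

#' Accumulated positional label of secreted citrate
#'
#' Sums the positional labeling patterns over all secreted citrate
#' generations: a fraction `d` of citrate diverges from the Krebs cycle each
#' turn, so generation k (having completed k turns) contributes with weight
#' `d * (1 - d)^k`. The default iterative evaluation truncates when the
#' largest positional increment falls below `params$tol`; the closed-form
#' geometric evaluation (`method = "closed"`) sums the three-step position
#' lineage analytically and agrees with the iterative sum to within `tol`.
#'
#' @param tracer a [tracer_spec()] (`glucose_1_6` or `pyruvate_2`).
#' @param params a [model_params()]; `params$d` must be positive (at `d = 0`
#'   nothing is secreted and the distribution is undefined).
#' @param method `"iterative"` (the defining sum) or `"closed"` (analytic
#'   geometric evaluation).
#' @return an object of class `secreted_distribution`: list with `s` (named
#'   positional vector C1..C6), `n_turns_used`, `converged`, and the `tracer`
#'   and `params` used.
#' @examples
#' secreted_distribution(tracer_spec("glucose_1_6"),
#'                       model_params(d = 0.79, p = 0.21))
#' @export
secreted_distribution <- function(tracer, params,
                                  method = c("iterative", "closed")) {
  method <- match.arg(method)
  stopifnot(inherits(tracer, "tracer_spec"), inherits(params, "model_params"))
  if (params$d <= 0) {
    stop("no secretion; distribution undefined (d = 0). ",
         "Evaluate small-d limits explicitly.", call. = FALSE)
  }
  if (method == "closed") {
    s <- closed_form_secreted(tracer, params$d, params$p)
    return(structure(list(s = s, n_turns_used = NA_integer_, converged = TRUE,
                          method = "closed", tracer = tracer, params = params),
                     class = "secreted_distribution"))
  }
  state <- unclass(initial_label_pattern(tracer, params))
  t_mat <- turn_transition_matrix()
  d <- params$d
  s <- numeric(6)
  converged <- FALSE
  k_used <- 0L
  for (k in 0:params$max_turns) {
    increment <- d * (1 - d)^k * state
    s <- s + increment
    k_used <- k
    if (max(increment) < params$tol) {
      converged <- TRUE
      break
    }
    state <- drop(t_mat %*% state)
  }
  structure(list(s = stats::setNames(s, position_names),
                 n_turns_used = k_used, converged = converged,
                 method = "iterative", tracer = tracer, params = params),
            class = "secreted_distribution")
}

#' @export
print.secreted_distribution <- function(x, digits = 4, ...) {
  cat("<secreted_distribution> tracer:", x$tracer$tracer_id,
      sprintf("(d = %.3f, p = %.3f)\n", x$params$d, x$params$p))
  print(round(x$s, digits))
  if (identical(x$method, "iterative")) {
    cat(sprintf("  turns used: %d (%s)\n", x$n_turns_used,
                if (x$converged) "converged" else "max_turns reached"))
  }
  invisible(x)
}

## Analytic geometric sums for the accumulated secreted label. Writing
## a = (1 - p) f_a (acetyl entry), q = p f_p (PC entry, split q/2 on C3/C4)
## and r = (1 - d)/2, the per-generation lineages give, for the glucose
## tracer (acetyl entry at C2):
##   s2 = d a;  s3 = s4 = d q/2 + d (a + q/2) r/(1-r);  s5 = s6 = r s3
## and for the pyruvate tracer (acetyl entry at C1):
##   s1 = d a;  s3 = s4 = d (q/2)/(1-r)
##   s5 = s6 = d (1-d)(a + q/2)/2 + d (q/2) r^2/(1-r)
closed_form_secreted <- function(tracer, d, p) {
  a <- (1 - p) * tracer$f_a
  q <- p * tracer$f_p
  r <- (1 - d) / 2
  s <- stats::setNames(numeric(6), position_names)
  pdc <- tracer$pdc_entry_positions
  if (identical(pdc, 2L)) {
    s[2] <- d * a
    s[3] <- s[4] <- d * q / 2 + d * (a + q / 2) * r / (1 - r)
    s[5] <- s[6] <- r * s[3]
  } else if (identical(pdc, 1L)) {
    s[1] <- d * a
    s[3] <- s[4] <- d * (q / 2) / (1 - r)
    s[5] <- s[6] <- d * (1 - d) * (a + q / 2) / 2 + d * (q / 2) * r^2 / (1 - r)
  } else {
    stop("closed form available only for tracers entering via acetyl-CoA at C1 or C2",
         call. = FALSE)
  }
  s
}

extract_positions <- function(dist) {
  if (inherits(dist, "secreted_distribution")) return(dist$s)
  s <- unclass(dist)
  if (is.numeric(s) && length(s) == 6L && !anyNA(s)) {
    return(stats::setNames(as.numeric(s), position_names))
  }
  stop("expected a secreted_distribution or a numeric vector of 6 positional integrals",
       call. = FALSE)
}

#' Citrate carbon ratio R1
#'
#' `R1 = ((C2 + C4) - C3) / (C2 + C4)`, the first measure of the apparent
#' fraction of citrate molecules diverging from the Krebs cycle, computed
#' from the combined C2/C4 and the C3 signal integrals of the
#' \[1,6-13C2\]glucose experiment. R1 approaches 1 when most citrate diverges
#' at the first turn and 0.5 when carbons are extensively recycled
#' (equal C2, C3, C4 labeling).
#'
#' @param dist a `secreted_distribution` or numeric vector of 6 positional
#'   integrals (C1..C6).
#' @return the ratio R1.
#' @examples
#' ratio_R1(c(0, 2, 1, 1, 0, 0))  # 2/3
#' @export
ratio_R1 <- function(dist) {
  s <- extract_positions(dist)
  denom <- s[2] + s[4]
  if (denom <= 0) stop("undefined ratio: C2 + C4 integral is zero", call. = FALSE)
  unname((denom - s[3]) / denom)
}

#' Citrate carbon ratio R2
#'
#' `R2 = (C1 + C5) / C3`, computed from the \[2-13C\]pyruvate experiment.
#' Citrate C3 can only acquire 13C via the pyruvate carboxylase route, so R2
#' measures the relative contribution of the acetyl-CoA (PDC) route against
#' PC; R2 grows without bound as the PC fraction tends to zero.
#'
#' @inheritParams ratio_R1
#' @return the ratio R2.
#' @examples
#' ratio_R2(c(5, 0, 1, 1, 0.2, 0.2))  # 5.2
#' @export
ratio_R2 <- function(dist) {
  s <- extract_positions(dist)
  if (s[3] <= 0) {
    stop("undefined ratio: C3 integral is zero (no PC-derived label, p = 0?)",
         call. = FALSE)
  }
  unname((s[1] + s[5]) / s[3])
}

#' Mean number of Krebs-cycle turns before secretion
#'
#' The mean of the geometric turn count with per-turn exit probability `d`,
#' `(1 - d)/d`: the average number of full Krebs-cycle turns a label completes
#' before leaving the cycle.
#'
#' @param d apparent per-turn secretion fraction, in (0, 1].
#' @return expected number of turns.
#' @examples
#' expected_turns(0.79)  # about 0.27 turns
#' @export
expected_turns <- function(d) {
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0 || d > 1) {
    stop("d must lie in (0, 1]", call. = FALSE)
  }
  (1 - d) / d
}

#' R1 as a function of the secretion fraction d
#'
#' Evaluates the forward model over a grid of secretion fractions at a fixed
#' PC fraction, giving the diagnostic curve of R1 versus d. For `p = 0` the
#' curve runs from 0.5 (d -> 0, extensive recycling) to 1 (d = 1, all citrate
#' diverging at the first turn); a PC contribution shifts the small-d end
#' downward (the offset at d = 0).
#'
#' @param p PC fraction in \[0, 1).
#' @param tracer a [tracer_spec()], default the glucose tracer.
#' @param d_grid vector of secretion fractions in (0, 1].
#' @return a data.frame with columns `d` and `R1`.
#' @export
r1_vs_d_curve <- function(p, tracer = tracer_spec("glucose_1_6"),
                          d_grid = seq(0.01, 1, by = 0.01)) {
  if (length(d_grid) == 0L) stop("d_grid must be non-empty", call. = FALSE)
  if (any(d_grid <= 0 | d_grid > 1)) stop("all d must lie in (0, 1]", call. = FALSE)
  r1 <- vapply(d_grid, function(d) {
    ratio_R1(secreted_distribution(tracer, model_params(d, p), method = "closed"))
  }, numeric(1))
  data.frame(d = d_grid, R1 = r1)
}
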