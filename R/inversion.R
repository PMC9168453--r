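## Inversion of the two-parameter secretion model: solve R1(d, p) = R1_obs
## (glucose tracer) and R2(d, p) = R2_obs (pyruvate tracer) jointly for the
## apparent secretion fraction d and the PC fraction p.

model_ratios <- function(d, p, glucose_tracer, pyruvate_tracer) {
  c(R1 = ratio_R1(closed_form_secreted(glucose_tracer, d, p)),
    R2 = ratio_R2(closed_form_secreted(pyruvate_tracer, d, p)))
}

## vectorized over equal-length d, p (p > 0 required for R2)
model_ratios_vec <- function(d, p, glucose_tracer, pyruvate_tracer) {
  r <- (1 - d) / 2
  ag <- (1 - p) * glucose_tracer$f_a
  qg <- p * glucose_tracer$f_p
  s2 <- d * ag
  s3g <- d * qg / 2 + d * (ag + qg / 2) * r / (1 - r)
  r1 <- (s2 + s3g - s3g) / (s2 + s3g)  # ((C2+C4)-C3)/(C2+C4) with C4 = C3
  ap <- (1 - p) * pyruvate_tracer$f_a
  qp <- p * pyruvate_tracer$f_p
  s1 <- d * ap
  s3p <- d * (qp / 2) / (1 - r)
  s5 <- d * (1 - d) * (ap + qp / 2) / 2 + d * (qp / 2) * r^2 / (1 - r)
  r2 <- (s1 + s5) / s3p
  list(R1 = r1, R2 = r2)
}

#' Fit the citrate secretion model to measured carbon ratios
#'
#' Jointly inverts the forward positional-labeling model for the apparent
#' per-turn Krebs-cycle secretion fraction `d` and the pyruvate carboxylase
#' fraction `p` from the measured citrate carbon integral ratios
#' `R1 = ((C2+C4)-C3)/(C2+C4)` (glucose tracer) and `R2 = (C1+C5)/C3`
#' (pyruvate tracer). The solver scans a coarse (d, p) grid, refines every
#' candidate basin by damped Newton iteration on the two-component residual,
#' and asserts uniqueness of the root; out-of-range ratios fail with the
#' attainable R1/R2 envelope.
#'
#' The fitted `d` is an upper bound on the true citrate secretion fraction:
#' other cataplerotic effluxes (glutamate exchange, PEPCK, malic enzyme)
#' contribute to the apparent divergence per turn.
#'
#' @param r1 measured ratio R1 from the \[1,6-13C2\]glucose experiment,
#'   in (0.5, 1\].
#' @param r2 measured ratio R2 from the \[2-13C\]pyruvate experiment, > 0.
#'   If replicate values exist, average them before calling.
#' @param glucose_tracer,pyruvate_tracer [tracer_spec()] objects carrying the
#'   pool enrichments; defaults are the LNCaP values (see [tracer_spec()] for
#'   the pyruvate-experiment acetyl-CoA enrichment convention).
#' @param grid_step coarse scan step for d and p.
#' @param tol convergence tolerance on the maximum absolute ratio residual.
#' @param max_iter Newton iteration cap per candidate.
#' @return an object of class `citrate_flux_fit` with components
#'   `coefficients` (named `d`, `p`), `residual`, `expected_turns`,
#'   `observed`, `fitted.values`, `tracers`, `envelope`, and `converged`.
#' @examples
#' fit <- fit_citrate_flux(0.75, 5.2)
#' coef(fit)
#' summary(fit)
#' @export
fit_citrate_flux <- function(r1, r2,
                             glucose_tracer = tracer_spec("glucose_1_6"),
                             pyruvate_tracer = tracer_spec("pyruvate_2"),
                             grid_step = 0.01, tol = 1e-8, max_iter = 100L) {
  stopifnot(is.numeric(r1), length(r1) == 1L, is.finite(r1),
            is.numeric(r2), length(r2) == 1L, is.finite(r2))
  if (r2 <= 0) stop("R2 must be positive", call. = FALSE)
  if (r1 <= 0 || r1 > 1) {
    stop(sprintf("R1 = %.3f is outside the admissible range (0, 1]", r1),
         call. = FALSE)
  }
  d_grid <- seq(grid_step, 1, by = grid_step)
  p_grid <- seq(grid_step, 1 - grid_step, by = grid_step)
  grid <- expand.grid(d = d_grid, p = p_grid)
  mr <- model_ratios_vec(grid$d, grid$p, glucose_tracer, pyruvate_tracer)
  envelope <- list(R1 = range(mr$R1), R2 = range(mr$R2))
  resid_inf <- pmax(abs(mr$R1 - r1), abs(mr$R2 - r2) / max(1, r2))
  ## candidate basins: local minima of the scaled residual on the grid
  rmat <- matrix(resid_inf, nrow = length(d_grid))
  cand <- local_minima_idx(rmat)
  objective <- function(x) {
    m <- model_ratios(x[1], x[2], glucose_tracer, pyruvate_tracer)
    c(m[["R1"]] - r1, m[["R2"]] - r2)
  }
  roots <- list()
  for (idx in cand) {
    ij <- arrayInd(idx, dim(rmat))
    x <- c(d_grid[ij[1]], p_grid[ij[2]])
    x <- newton_2d(objective, x, tol = tol, max_iter = max_iter)
    if (!is.null(x)) roots[[length(roots) + 1L]] <- x
  }
  if (length(roots) == 0L) {
    stop(sprintf(paste0("ratios outside model range: no (d, p) root found for ",
                        "R1 = %.3f, R2 = %.3f; attainable envelope R1 in (%.3f, %.3f], ",
                        "R2 in (%.2f, %.2f)"),
                 r1, r2, envelope$R1[1], envelope$R1[2],
                 envelope$R2[1], envelope$R2[2]), call. = FALSE)
  }
  uniq <- unique(do.call(rbind, lapply(roots, round, digits = 6)))
  if (nrow(uniq) > 1L) {
    stop("multiple (d, p) roots found: ",
         paste(apply(uniq, 1, function(r) sprintf("(d = %.4f, p = %.4f)", r[1], r[2])),
               collapse = ", "), call. = FALSE)
  }
  x <- roots[[1]]
  fitted <- model_ratios(x[1], x[2], glucose_tracer, pyruvate_tracer)
  residual <- max(abs(fitted - c(r1, r2)))
  structure(
    list(coefficients = c(d = unname(x[1]), p = unname(x[2])),
         residual = residual,
         converged = residual < tol,
         expected_turns = expected_turns(x[1]),
         observed = c(R1 = r1, R2 = r2),
         fitted.values = fitted,
         tracers = list(glucose = glucose_tracer, pyruvate = pyruvate_tracer),
         envelope = envelope,
         control = list(grid_step = grid_step, tol = tol, max_iter = max_iter),
         call = match.call()),
    class = "citrate_flux_fit")
}

## indices of (strict-or-plateau) local minima of a matrix over 4-neighbours
local_minima_idx <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  idx <- integer(0)
  best <- which.min(m)
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      v <- m[i, j]
      nb <- c(if (i > 1) m[i - 1, j], if (i < nr) m[i + 1, j],
              if (j > 1) m[i, j - 1], if (j < nc) m[i, j + 1])
      if (all(v <= nb)) idx <- c(idx, (j - 1L) * nr + i)
    }
  }
  unique(c(best, idx))
}

## damped Newton with numerical Jacobian, box-constrained to the admissible
## (d, p) region; returns NULL when the iteration fails to converge
newton_2d <- function(fn, x0, tol, max_iter,
                      lower = c(1e-9, 0), upper = c(1, 0.999999)) {
  x <- pmin(pmax(x0, lower + 1e-9), upper)
  f <- fn(x)
  for (iter in seq_len(max_iter)) {
    if (max(abs(f)) < tol) return(x)
    jac <- matrix(0, 2, 2)
    h <- 1e-7
    for (j in 1:2) {
      xp <- x
      xp[j] <- xp[j] + h
      jac[, j] <- (fn(xp) - f) / h
    }
    step <- tryCatch(solve(jac, f), error = function(e) NULL)
    if (is.null(step) || anyNA(step)) return(NULL)
    lam <- 1
    repeat {
      xn <- pmin(pmax(x - lam * step, lower), upper)
      fn_new <- fn(xn)
      if (max(abs(fn_new)) < max(abs(f)) || lam < 1e-6) break
      lam <- lam / 2
    }
    if (lam < 1e-6 && max(abs(fn_new)) >= max(abs(f))) return(NULL)
    x <- xn
    f <- fn_new
  }
  if (max(abs(f)) < tol) x else NULL
}

#' @export
print.citrate_flux_fit <- function(x, digits = 4, ...) {
  cat("Citrate secretion model fit\n")
  cat(sprintf("  observed ratios: R1 = %.3f, R2 = %.3f\n",
              x$observed[["R1"]], x$observed[["R2"]]))
  cat(sprintf("  apparent secretion fraction d = %.*f\n", digits,
              x$coefficients[["d"]]))
  cat(sprintf("  PC fraction                 p = %.*f\n", digits,
              x$coefficients[["p"]]))
  cat(sprintf("  expected Krebs-cycle turns before secretion: %.2f\n",
              x$expected_turns))
  invisible(x)
}

#' @export
coef.citrate_flux_fit <- function(object, ...) object$coefficients

#' @export
residuals.citrate_flux_fit <- function(object, ...) {
  object$fitted.values - object$observed
}

#' @export
fitted.citrate_flux_fit <- function(object, ...) object$fitted.values

#' Summary of a citrate secretion model fit
#'
#' @param object a `citrate_flux_fit`.
#' @param ... unused.
#' @export
summary.citrate_flux_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.citrate_flux_fit")
}

#' @export
print.summary.citrate_flux_fit <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat(sprintf("  max |ratio residual|: %.2e (%s)\n", fit$residual,
              if (fit$converged) "converged" else "not converged"))
  cat(sprintf("  enrichments: glucose f_p = %.2f, f_a = %.2f; pyruvate f_p = %.2f, f_a = %.2f\n",
              fit$tracers$glucose$f_p, fit$tracers$glucose$f_a,
              fit$tracers$pyruvate$f_p, fit$tracers$pyruvate$f_a))
  cat("  note: d is an upper bound on the true citrate secretion fraction c;\n")
  cat("  other cataplerotic effluxes inflate the apparent per-turn divergence.\n")
  invisible(x)
}

#' Predict model ratios at given parameters
#'
#' Evaluates the forward model ratios R1 and R2 at the fitted parameters, or
#' at user-supplied `(d, p)` pairs.
#'
#' @param object a `citrate_flux_fit`.
#' @param newdata optional data.frame with columns `d` and `p`.
#' @param ... unused.
#' @return a data.frame with columns `d`, `p`, `R1`, `R2`.
#' @export
predict.citrate_flux_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    newdata <- data.frame(d = object$coefficients[["d"]],
                          p = object$coefficients[["p"]])
  }
  stopifnot(is.data.frame(newdata), all(c("d", "p") %in% names(newdata)))
  mr <- model_ratios_vec(newdata$d, newdata$p,
                         object$tracers$glucose, object$tracers$pyruvate)
  data.frame(d = newdata$d, p = newdata$p, R1 = mr$R1, R2 = mr$R2)
}

#' Re-invert the model under ratio measurement noise
#'
#' Draws Gaussian measurement noise on the observed ratios and re-inverts the
#' model for each replicate, giving an empirical spread of `(d, p)` under the
#' stated ratio uncertainties. Replicates whose noisy ratios fall outside the
#' attainable model envelope are returned as `NA`.
#'
#' @param object a `citrate_flux_fit`.
#' @param nsim number of noise replicates.
#' @param seed optional RNG seed.
#' @param sd_r1,sd_r2 measurement standard deviations of R1 and R2.
#' @param ... unused.
#' @return a data.frame with columns `R1`, `R2`, `d`, `p` (one row per
#'   replicate).
#' @export
simulate.citrate_flux_fit <- function(object, nsim = 200, seed = NULL,
                                      sd_r1 = 0.02, sd_r2 = 0.5, ...) {
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  r1s <- stats::rnorm(nsim, object$observed[["R1"]], sd_r1)
  r2s <- stats::rnorm(nsim, object$observed[["R2"]], sd_r2)
  out <- data.frame(R1 = r1s, R2 = r2s, d = NA_real_, p = NA_real_)
  for (i in seq_len(nsim)) {
    fit <- tryCatch(
      fit_citrate_flux(r1s[i], r2s[i],
                       glucose_tracer = object$tracers$glucose,
                       pyruvate_tracer = object$tracers$pyruvate,
                       grid_step = object$control$grid_step,
                       tol = object$control$tol),
      error = function(e) NULL)
    if (!is.null(fit)) {
      out$d[i] <- fit$coefficients[["d"]]
      out$p[i] <- fit$coefficients[["p"]]
    }
  }
  out
}

#' Diagnostic curves of the PC fraction versus the secretion fraction
#'
#' For each secretion fraction in `d_grid`, solves the one-dimensional
#' problems `R1(d, p) = r1` and `R2(d, p) = r2` for the PC fraction `p`. The
#' two curves intersect at the joint solution returned by
#' [fit_citrate_flux()]. Grid points admitting no solution are reported as
#' `NA` (with a message).
#'
#' @inheritParams fit_citrate_flux
#' @param d_grid vector of secretion fractions in (0, 1].
#' @return a data.frame with columns `d`, `p_R1`, `p_R2`.
#' @export
pc_vs_d_curves <- function(r1, r2,
                           glucose_tracer = tracer_spec("glucose_1_6"),
                           pyruvate_tracer = tracer_spec("pyruvate_2"),
                           d_grid = seq(0.01, 1, by = 0.01)) {
  if (length(d_grid) == 0L) stop("d_grid must be non-empty", call. = FALSE)
  if (any(d_grid <= 0 | d_grid > 1)) stop("all d must lie in (0, 1]", call. = FALSE)
  solve_p <- function(d, target_fn) {
    f <- function(p) target_fn(d, p)
    lo <- 1e-9; hi <- 0.999999
    flo <- f(lo); fhi <- f(hi)
    if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) return(NA_real_)
    stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  }
  p_r1 <- vapply(d_grid, solve_p, numeric(1), target_fn = function(d, p) {
    model_ratios_vec(d, p, glucose_tracer, pyruvate_tracer)$R1 - r1
  })
  p_r2 <- vapply(d_grid, solve_p, numeric(1), target_fn = function(d, p) {
    model_ratios_vec(d, p, glucose_tracer, pyruvate_tracer)$R2 - r2
  })
  n_miss <- sum(is.na(p_r1)) + sum(is.na(p_r2))
  if (n_miss > 0) {
    message(n_miss, " grid point(s) admit no PC-fraction solution and were omitted")
  }
  data.frame(d = d_grid, p_R1 = p_r1, p_R2 = p_r2)
}

#' Plot a citrate secretion model fit
#'
#' Two diagnostic panels: R1 versus the secretion fraction d at the fitted PC
#' fraction (with the observed R1 marked) and the PC-fraction-versus-d curves
#' for the two measured ratios, whose intersection is the fitted parameter
#' pair.
#'
#' @param x a `citrate_flux_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.citrate_flux_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op), add = TRUE)
  d_hat <- x$coefficients[["d"]]
  p_hat <- x$coefficients[["p"]]
  curve1 <- r1_vs_d_curve(p_hat, x$tracers$glucose)
  graphics::plot(curve1$d, curve1$R1, type = "l", xlab = "secretion fraction d",
                 ylab = expression(R[1]), ylim = c(0, 1), ...)
  graphics::abline(h = x$observed[["R1"]], lty = 2)
  graphics::points(d_hat, x$fitted.values[["R1"]], pch = 19)
  curves <- pc_vs_d_curves(x$observed[["R1"]], x$observed[["R2"]],
                           x$tracers$glucose, x$tracers$pyruvate)
  graphics::matplot(curves$d, cbind(curves$p_R1, curves$p_R2), type = "l",
                    lty = 1:2, col = 1, xlab = "secretion fraction d",
                    ylab = "PC fraction p")
  graphics::points(d_hat, p_hat, pch = 19)
  graphics::legend("topright", legend = c("from R1", "from R2"),
                   lty = 1:2, bty = "n")
  invisible(x)
}
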