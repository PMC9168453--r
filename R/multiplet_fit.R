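## Constrained Lorentzian multiplet fitting with prior knowledge: fixed
## multiplet offsets (in Hz, from the one-bond 13C-13C coupling of citrate),
## per-line amplitudes and linewidths, a single shared frequency shift of the
## whole multiplet, and a single shared phase. Integrals are analytic over
## the fitted components (amplitude x pi x half-width at half-maximum), not
## trapezoidal sums over raw points.

## one-bond coupling between citrate C2 (or C4) and C3; the C2-C4 coupling is
## smaller than the 13C linewidth and is neglected
J_C2C3_HZ <- 38

## phased Lorentzian: absorption mixed with dispersion by a shared phase
lorentzian_line <- function(x_hz, amplitude, fwhm_hz, phase = 0) {
  g <- fwhm_hz / 2
  denom <- g^2 + x_hz^2
  amplitude * (cos(phase) * g^2 / denom - sin(phase) * g * x_hz / denom)
}

#' Fit a constrained Lorentzian multiplet
#'
#' Least-squares fit of a multiplet of Lorentzian lines at fixed relative
#' offsets to a spectral window. Free parameters are the per-line amplitudes
#' and linewidths (bounded), one shared frequency shift of the whole
#' multiplet relative to `anchor_ppm`, and (optionally) one shared phase.
#' Fitting uses box-constrained Levenberg-Marquardt
#' ([minpack.lm::nls.lm()]); integrals are evaluated analytically as
#' `amplitude * pi * fwhm / 2`.
#'
#' @param spec a [spectrum_1d()].
#' @param anchor_ppm nominal chemical shift of the multiplet center (ppm).
#' @param offsets_hz numeric vector of line offsets from the anchor, in Hz.
#' @param labels optional component labels (same length as `offsets_hz`).
#' @param window_hz half-width of the fit window around the anchor, in Hz.
#' @param lw_bounds_hz allowed linewidth (FWHM) range in Hz; citrate 13C fits
#'   use the standard prior-knowledge bounds \[4, 20\].
#' @param lw_start_hz starting linewidth.
#' @param shared_linewidth constrain all lines of the multiplet to one common
#'   linewidth (default). The lines of one citrate carbon multiplet differ
#'   only in their J-coupling state, so their transverse relaxation -- and
#'   hence linewidth -- is shared; the constraint markedly stabilizes
#'   low-SNR fits. Set `FALSE` for independent per-line linewidths.
#' @param fit_phase estimate a single shared phase (default: fixed at 0).
#' @param amplitude_groups optional integer vector (one entry per line)
#'   tying lines to a common amplitude parameter; symmetric multiplet halves
#'   (the two lines of a J doublet) have equal intensity by construction, so
#'   constraining them removes spurious degrees of freedom at low SNR.
#'   Default: every line has its own amplitude.
#' @param lw_fixed_hz optionally fix the (shared) linewidth to a known value
#'   in Hz instead of fitting it -- e.g. transfer the linewidth fitted on a
#'   strong multiplet of the same molecule to a weak one; must lie within
#'   `lw_bounds_hz`.
#' @param baseline `"none"` (default, windows are assumed flat and zero) or
#'   `"linear"`.
#' @return an object of class `multiplet_fit`: a list with `components`
#'   (data.frame: label, offset_hz, amplitude, fwhm_hz, integral,
#'   se_integral, at_lw_bound), `total_integral`, `shift_hz`, `phase`,
#'   `noise_sigma`, `gof` (residual RMS / noise sigma), `converged`, and the
#'   window data.
#' @export
fit_multiplet <- function(spec, anchor_ppm, offsets_hz,
                          labels = NULL, window_hz = 120,
                          lw_bounds_hz = c(4, 20), lw_start_hz = 8,
                          shared_linewidth = TRUE, fit_phase = FALSE,
                          amplitude_groups = NULL, lw_fixed_hz = NULL,
                          baseline = c("none", "linear")) {
  baseline <- match.arg(baseline)
  stopifnot(inherits(spec, "spectrum_1d"), length(offsets_hz) >= 1L)
  if (is.null(labels)) labels <- paste0("line", seq_along(offsets_hz))
  stopifnot(length(labels) == length(offsets_hz))
  mhz <- spec$frequency_mhz
  win <- spectrum_window(spec, anchor_ppm + c(-1, 1) * window_hz / mhz)
  x_hz <- (win$ppm - anchor_ppm) * mhz
  y <- win$intensity
  sigma <- estimate_noise_sigma(y)
  n_lines <- length(offsets_hz)

  if (is.null(amplitude_groups)) amplitude_groups <- seq_len(n_lines)
  stopifnot(length(amplitude_groups) == n_lines)
  amplitude_groups <- match(amplitude_groups, unique(amplitude_groups))
  n_amp <- max(amplitude_groups)

  ## starting amplitudes from the data near each line position
  amp0_line <- vapply(offsets_hz, function(o) {
    near <- abs(x_hz - o) <= max(2, lw_start_hz / 2)
    a <- max(y[near], 0)
    max(a, sigma)
  }, numeric(1))
  amp0 <- vapply(seq_len(n_amp), function(g) {
    mean(amp0_line[amplitude_groups == g])
  }, numeric(1))

  fixed_lw <- !is.null(lw_fixed_hz)
  if (fixed_lw) {
    stopifnot(is.numeric(lw_fixed_hz), length(lw_fixed_hz) == 1L)
    if (lw_fixed_hz < lw_bounds_hz[1] || lw_fixed_hz > lw_bounds_hz[2]) {
      stop("lw_fixed_hz must lie within lw_bounds_hz", call. = FALSE)
    }
  }
  n_lw <- if (fixed_lw) 0L else if (shared_linewidth) 1L else n_lines
  lw_names <- if (fixed_lw) character(0) else
    if (shared_linewidth) "lw" else paste0("lw", seq_len(n_lines))
  par_names <- c(paste0("A", seq_len(n_amp)), lw_names,
                 "shift", if (fit_phase) "phase",
                 if (baseline == "linear") c("b0", "b1"))
  start <- c(amp0, rep(lw_start_hz, n_lw), 0,
             if (fit_phase) 0, if (baseline == "linear") c(0, 0))
  lower <- c(rep(0, n_amp), rep(lw_bounds_hz[1], n_lw), -window_hz / 3,
             if (fit_phase) -pi / 2,
             if (baseline == "linear") c(-Inf, -Inf))
  upper <- c(rep(Inf, n_amp), rep(lw_bounds_hz[2], n_lw), window_hz / 3,
             if (fit_phase) pi / 2,
             if (baseline == "linear") c(Inf, Inf))
  names(start) <- names(lower) <- names(upper) <- par_names

  lw_of <- function(par, i) {
    if (fixed_lw) lw_fixed_hz else
      par[[if (shared_linewidth) "lw" else paste0("lw", i)]]
  }
  lw_name_of <- function(i) if (shared_linewidth) "lw" else paste0("lw", i)
  amp_name_of <- function(i) paste0("A", amplitude_groups[i])
  model_fn <- function(par) {
    yhat <- numeric(length(x_hz))
    phase <- if (fit_phase) par[["phase"]] else 0
    for (i in seq_len(n_lines)) {
      yhat <- yhat + lorentzian_line(x_hz - offsets_hz[i] - par[["shift"]],
                                     par[[amp_name_of(i)]],
                                     lw_of(par, i), phase)
    }
    if (baseline == "linear") yhat <- yhat + par[["b0"]] + par[["b1"]] * x_hz
    yhat
  }

  fit <- fit_multiplet_lm(x_hz, y, model_fn, start, lower, upper)
  if (inherits(fit, "error")) {
    stop("multiplet fit did not converge: ", conditionMessage(fit),
         "; residual diagnostics unavailable", call. = FALSE)
  }
  est <- fit$par
  resid <- y - model_fn(est)
  gof <- sqrt(mean(resid^2)) / sigma
  amp <- unname(vapply(seq_len(n_lines),
                       function(i) est[[amp_name_of(i)]], numeric(1)))
  lw <- unname(vapply(seq_len(n_lines),
                      function(i) lw_of(est, i), numeric(1)))
  integral <- amp * pi * lw / 2
  se_int <- rep(NA_real_, n_lines)
  if (!is.null(fit$cov)) {
    for (i in seq_len(n_lines)) {
      ai <- amp_name_of(i)
      li <- if (fixed_lw) NULL else lw_name_of(i)
      if (fixed_lw && ai %in% rownames(fit$cov)) {
        se_int[i] <- pi * lw[i] / 2 * sqrt(max(0, fit$cov[ai, ai]))
      } else if (!is.null(li) && all(c(ai, li) %in% rownames(fit$cov))) {
        grad <- c(pi * lw[i] / 2, pi * amp[i] / 2)
        v <- fit$cov[c(ai, li), c(ai, li)]
        se_int[i] <- sqrt(max(0, drop(t(grad) %*% v %*% grad)))
      }
    }
  }
  at_bound <- lw <= lw_bounds_hz[1] + 1e-6 | lw >= lw_bounds_hz[2] - 1e-6
  comp <- data.frame(label = labels, offset_hz = offsets_hz,
                     amplitude = unname(amp), fwhm_hz = unname(lw),
                     integral = unname(integral), se_integral = se_int,
                     at_lw_bound = unname(at_bound),
                     stringsAsFactors = FALSE)
  structure(list(components = comp,
                 total_integral = sum(integral),
                 shift_hz = unname(est[["shift"]]),
                 phase = if (fit_phase) unname(est[["phase"]]) else 0,
                 noise_sigma = sigma, gof = gof,
                 converged = isTRUE(fit$converged),
                 anchor_ppm = anchor_ppm,
                 window = list(ppm = win$ppm, intensity = y, fitted = y - resid)),
            class = "multiplet_fit")
}

## box-constrained Levenberg-Marquardt on the residual function
fit_multiplet_lm <- function(x_hz, y, model_fn, start, lower, upper) {
  resid_fn <- function(par) {
    y - model_fn(stats::setNames(par, names(start)))
  }
  out <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 400,
                                                            ftol = 1e-12)),
    error = function(e) e)
  if (inherits(out, "error")) return(out)
  cov <- tryCatch({
    dof <- length(y) - length(start)
    s2 <- sum(out$fvec^2) / max(1, dof)
    v <- s2 * solve(out$hessian)
    rownames(v) <- colnames(v) <- names(start)
    v
  }, error = function(e) NULL)
  list(par = stats::setNames(out$par, names(start)),
       converged = out$info %in% 1:4, cov = cov)
}

#' @export
print.multiplet_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<multiplet_fit> anchor %.2f ppm, %d component(s)\n",
              x$anchor_ppm, nrow(x$components)))
  print(format(x$components, digits = digits), row.names = FALSE)
  cat(sprintf("  total integral %.4g; shift %.2f Hz; residual RMS / noise = %.2f\n",
              x$total_integral, x$shift_hz, x$gof))
  if (any(x$components$at_lw_bound)) {
    cat("  note: linewidth at constraint boundary for:",
        paste(x$components$label[x$components$at_lw_bound], collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.multiplet_fit <- function(x, ...) {
  graphics::plot(x$window$ppm, x$window$intensity, type = "l",
                 xlim = rev(range(x$window$ppm)),
                 xlab = "chemical shift (ppm)", ylab = "intensity", ...)
  graphics::lines(x$window$ppm, x$window$fitted, col = 2)
  invisible(x)
}

#' Fit the citrate C2/C4 region of a 13C spectrum
#'
#' The combined C2/C4 resonance near 46.5 ppm is modeled as a singlet
#' (uncoupled C2/C4, the C2-C4 coupling being smaller than the linewidth and
#' neglected) plus a symmetric doublet at +/-19 Hz from the one-bond C2-C3
#' coupling (J = 38 Hz). Linewidths are constrained to \[4, 20\] Hz and all
#' lines share one phase.
#'
#' @param spec a 13C [spectrum_1d()] covering the 44-49 ppm window.
#' @param anchor_ppm anchor chemical shift (default 46.5).
#' @param ... passed to [fit_multiplet()].
#' @return a `multiplet_fit` whose `group_totals` attribute carries the C2/4
#'   total (singlet + doublet).
#' @export
fit_citrate_c24_region <- function(spec, anchor_ppm = 46.5, ...) {
  fit <- fit_multiplet(spec, anchor_ppm,
                       offsets_hz = c(-J_C2C3_HZ / 2, 0, J_C2C3_HZ / 2),
                       labels = c("doublet_low", "singlet", "doublet_high"),
                       amplitude_groups = c(1, 2, 1), ...)
  fit$group_totals <- list(c24_total = fit$total_integral,
                           singlet = fit$components$integral[2],
                           doublet = fit$components$integral[1] +
                             fit$components$integral[3])
  fit
}

#' Fit the citrate C3 region of a 13C spectrum
#'
#' The C3 resonance near 76.2 ppm is modeled as a central line plus four
#' outer lines fixed at -38, -19, +19 and +38 Hz (doubly and singly
#' C2/C4-coupled C3), with linewidths constrained to \[4, 20\] Hz and a
#' shared phase.
#'
#' @param spec a 13C [spectrum_1d()] covering the C3 window.
#' @param anchor_ppm anchor chemical shift (default 76.2).
#' @param ... passed to [fit_multiplet()].
#' @return a `multiplet_fit` with a `group_totals` attribute (`c3_total`).
#' @export
fit_citrate_c3_region <- function(spec, anchor_ppm = 76.2, ...) {
  fit <- fit_multiplet(spec, anchor_ppm,
                       offsets_hz = c(-J_C2C3_HZ, -J_C2C3_HZ / 2, 0,
                                      J_C2C3_HZ / 2, J_C2C3_HZ),
                       labels = c("outer_m38", "outer_m19", "center",
                                  "outer_p19", "outer_p38"),
                       amplitude_groups = c(1, 2, 3, 2, 1),
                       window_hz = 150, ...)
  fit$group_totals <- list(c3_total = fit$total_integral,
                           center = fit$components$integral[3],
                           outer = fit$total_integral - fit$components$integral[3])
  fit
}

#' Fit a single Lorentzian resonance
#'
#' Convenience wrapper for singlet resonances (citrate carboxyl C1/5 and C6
#' lines, the 13C TSP reference, 13C lactate C3, ...).
#'
#' @inheritParams fit_multiplet
#' @param label component label.
#' @return a `multiplet_fit`.
#' @export
fit_singlet <- function(spec, anchor_ppm, label = "singlet", window_hz = 120,
                        ...) {
  fit_multiplet(spec, anchor_ppm, offsets_hz = 0, labels = label,
                window_hz = window_hz, ...)
}

#' Fit the lactate/alanine methyl region of a 1H spectrum
#'
#' Models the lactate methyl doublet at 1.33 ppm (3J_HH about 6.9 Hz), its
#' 13C satellite doublets at +/- 1J_CH/2 (about +/- 63.5 Hz) whose integral
#' fraction measures the fractional 13C enrichment of lactate C3 (and hence
#' of the pyruvate pool), and -- because the upfield satellite doublet
#' overlaps it -- the alanine methyl doublet at 1.48 ppm, in one joint fit.
#'
#' @param spec a 1H [spectrum_1d()].
#' @param anchor_ppm lactate doublet center (default 1.33).
#' @param alanine_ppm alanine doublet center (default 1.48); `NA` omits the
#'   alanine lines from the model.
#' @param j_hh_hz proton-proton coupling of the lactate doublet (Hz).
#' @param j_ch_hz one-bond carbon-proton coupling (Hz).
#' @param j_ala_hz proton-proton coupling of the alanine doublet (Hz).
#' @param lw_bounds_hz linewidth bounds for the 1H lines.
#' @param ... passed to [fit_multiplet()].
#' @return a `multiplet_fit` with `group_totals` components `main`
#'   (unlabeled lactate doublet), `satellite`, and `alanine`.
#' @export
fit_lactate_region <- function(spec, anchor_ppm = 1.33, alanine_ppm = 1.48,
                               j_hh_hz = 6.9, j_ch_hz = 127, j_ala_hz = 7.2,
                               lw_bounds_hz = c(0.5, 6), ...) {
  off_main <- c(-j_hh_hz / 2, j_hh_hz / 2)
  off_sat <- c(-j_ch_hz / 2 - j_hh_hz / 2, -j_ch_hz / 2 + j_hh_hz / 2,
               j_ch_hz / 2 - j_hh_hz / 2, j_ch_hz / 2 + j_hh_hz / 2)
  offsets <- c(off_sat[1:2], off_main, off_sat[3:4])
  labels <- c("sat_low_a", "sat_low_b", "main_low", "main_high",
              "sat_high_a", "sat_high_b")
  groups <- c(1, 1, 2, 2, 1, 1)
  with_ala <- !is.na(alanine_ppm)
  if (with_ala) {
    off_ala <- (alanine_ppm - anchor_ppm) * spec$frequency_mhz +
      c(-j_ala_hz / 2, j_ala_hz / 2)
    offsets <- c(offsets, off_ala)
    labels <- c(labels, "ala_low", "ala_high")
    groups <- c(groups, 3, 3)
  }
  fit <- fit_multiplet(spec, anchor_ppm, offsets_hz = offsets,
                       labels = labels, amplitude_groups = groups,
                       window_hz = 110, lw_bounds_hz = lw_bounds_hz,
                       lw_start_hz = 1.5, ...)
  ints <- fit$components$integral
  fit$group_totals <- list(main = ints[3] + ints[4],
                           satellite = ints[1] + ints[2] + ints[5] + ints[6],
                           alanine = if (with_ala) ints[7] + ints[8] else NA_real_)
  fit$total_integral <- fit$group_totals$main + fit$group_totals$satellite
  fit
}

#' Fit the TSP reference singlet of a 1H spectrum
#'
#' @param spec a 1H [spectrum_1d()].
#' @param ... passed to [fit_multiplet()].
#' @return a `multiplet_fit`.
#' @export
fit_tsp_proton <- function(spec, ...) {
  fit_singlet(spec, anchor_ppm = 0, label = "TSP", window_hz = 30,
              lw_bounds_hz = c(0.5, 6), lw_start_hz = 1.5, ...)
}

#' Fit the citrate proton quartet of a 1H spectrum
#'
#' The citrate methylene protons form an AB quartet (lines near 2.71, 2.68,
#' 2.57 and 2.54 ppm); the total integral corresponds to citrate's four
#' protons.
#'
#' @param spec a 1H [spectrum_1d()].
#' @param anchor_ppm quartet center (default 2.625).
#' @param ... passed to [fit_multiplet()].
#' @return a `multiplet_fit`; `total_integral` is the citrate 1H integral.
#' @export
fit_citrate_proton <- function(spec, anchor_ppm = 2.625, ...) {
  mhz <- spec$frequency_mhz
  offsets <- (c(2.71, 2.68, 2.57, 2.54) - anchor_ppm) * mhz
  fit_multiplet(spec, anchor_ppm, offsets_hz = offsets,
                labels = c("ab1", "ab2", "ab3", "ab4"), window_hz = 80,
                lw_bounds_hz = c(0.5, 6), lw_start_hz = 1.5, ...)
}

#' Fit the alanine methyl doublet of a 1H spectrum
#'
#' The alanine doublet at 1.48 ppm overlaps the upfield 13C satellite of
#' lactate, so it is fitted jointly with the lactate region (see
#' [fit_lactate_region()]); the returned fit reports the alanine doublet
#' integral as `total_integral`.
#'
#' @param spec a 1H [spectrum_1d()].
#' @param anchor_ppm alanine doublet center (default 1.48).
#' @param ... passed to [fit_lactate_region()].
#' @return a `multiplet_fit`; `total_integral` is the alanine methyl
#'   integral.
#' @export
fit_alanine_proton <- function(spec, anchor_ppm = 1.48, ...) {
  fit <- fit_lactate_region(spec, alanine_ppm = anchor_ppm, ...)
  fit$total_integral <- fit$group_totals$alanine
  fit
}
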