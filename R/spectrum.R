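#' 1D NMR spectrum container
#'
#' A frequency-domain spectrum: a strictly monotone ppm axis with matching
#' intensities, the nucleus, the spectrometer frequency for that nucleus
#' (which doubles as the Hz-per-ppm conversion), and the chemical-shift
#' reference (TSP at 0 ppm for 1H, TSP at -2.0 ppm for 13C).
#'
#' @param ppm strictly monotone numeric vector of chemical shifts (ppm).
#' @param intensity numeric vector of the same length.
#' @param nucleus `"1H"` or `"13C"`.
#' @param frequency_mhz spectrometer frequency in MHz for this nucleus;
#'   defaults to a 500 MHz instrument (500.13 for 1H, 125.76 for 13C).
#' @param reference chemical-shift reference; defaults to the TSP convention
#'   for the nucleus.
#' @return an object of class `spectrum_1d`.
#' @export
spectrum_1d <- function(ppm, intensity, nucleus = c("13C", "1H"),
                        frequency_mhz = NULL, reference = NULL) {
  nucleus <- match.arg(nucleus)
  stopifnot(is.numeric(ppm), is.numeric(intensity))
  if (length(ppm) != length(intensity)) {
    stop("ppm axis and intensity must have equal length", call. = FALSE)
  }
  if (length(ppm) < 2L) stop("a spectrum needs at least two points", call. = FALSE)
  dppm <- diff(ppm)
  if (!(all(dppm > 0) || all(dppm < 0))) {
    stop("ppm axis must be strictly monotone", call. = FALSE)
  }
  if (is.null(frequency_mhz)) {
    frequency_mhz <- if (nucleus == "1H") 500.13 else 125.76
  }
  stopifnot(is.numeric(frequency_mhz), frequency_mhz > 0)
  default_ref <- if (nucleus == "1H") "TSP_1H_0ppm" else "TSP_13C_minus2ppm"
  if (is.null(reference)) reference <- default_ref
  if (!identical(reference, default_ref)) {
    stop("reference '", reference, "' inconsistent with nucleus ", nucleus,
         " (expected ", default_ref, ")", call. = FALSE)
  }
  structure(list(ppm = as.numeric(ppm), intensity = as.numeric(intensity),
                 nucleus = nucleus, frequency_mhz = frequency_mhz,
                 reference = reference),
            class = "spectrum_1d")
}

#' @export
print.spectrum_1d <- function(x, ...) {
  cat(sprintf("<spectrum_1d> %s, %d points, %.2f..%.2f ppm at %.2f MHz (%s)\n",
              x$nucleus, length(x$ppm), min(x$ppm), max(x$ppm),
              x$frequency_mhz, x$reference))
  invisible(x)
}

#' @export
plot.spectrum_1d <- function(x, xlim = NULL, ...) {
  if (is.null(xlim)) xlim <- rev(range(x$ppm))  # NMR convention: ppm decreasing
  graphics::plot(x$ppm, x$intensity, type = "l", xlim = xlim,
                 xlab = paste0(x$nucleus, " chemical shift (ppm)"),
                 ylab = "intensity", ...)
  invisible(x)
}

## extract the points of a window (ppm_lo, ppm_hi); errors when the window is
## not covered by the spectrum
spectrum_window <- function(spec, ppm_range) {
  stopifnot(inherits(spec, "spectrum_1d"), length(ppm_range) == 2L)
  ppm_range <- sort(ppm_range)
  if (ppm_range[1] < min(spec$ppm) || ppm_range[2] > max(spec$ppm)) {
    stop(sprintf("spectral window %.2f..%.2f ppm not covered by the spectrum (%.2f..%.2f)",
                 ppm_range[1], ppm_range[2], min(spec$ppm), max(spec$ppm)),
         call. = FALSE)
  }
  keep <- spec$ppm >= ppm_range[1] & spec$ppm <= ppm_range[2]
  list(ppm = spec$ppm[keep], intensity = spec$intensity[keep])
}

## Noise sigma for a fit window, as the smaller of two estimates:
## (1) sd of the 20% of points with smallest |intensity| (signal-free under
##     the flat-zero-baseline assumption), rescaled for the truncation of
##     the noise distribution the selection induces (|Z| < a with
##     P(|Z| < a) = fraction);
## (2) a robust first-difference estimate mad(diff)/sqrt(2), insensitive to
##     smooth signal tails that contaminate (1).
## Each overestimates in the regime where the other is reliable, so the
## minimum is taken.
estimate_noise_sigma <- function(intensity, fraction = 0.2) {
  n <- max(5L, floor(length(intensity) * fraction))
  n <- min(n, length(intensity))
  quiet <- intensity[order(abs(intensity))[seq_len(n)]]
  a <- stats::qnorm(0.5 + fraction / 2)
  correction <- sqrt(1 - 2 * a * stats::dnorm(a) / fraction)
  s_quiet <- stats::sd(quiet) / correction
  s_diff <- stats::mad(diff(intensity)) / sqrt(2)
  min(s_quiet, s_diff) + 1e-300
}

#' Read a 1D spectrum from a two-column tabular file
#'
#' Accepts whitespace- or comma-separated (ppm, intensity) files, with or
#' without a header line.
#'
#' @param path file path.
#' @inheritParams spectrum_1d
#' @return a [spectrum_1d()].
#' @export
read_spectrum_table <- function(path, nucleus = c("13C", "1H"),
                                frequency_mhz = NULL, reference = NULL) {
  nucleus <- match.arg(nucleus)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  header <- grepl("[A-Za-z]", first)
  tab <- utils::read.table(path, header = header, sep = sep,
                           strip.white = TRUE)
  if (ncol(tab) < 2L) stop("expected two columns (ppm, intensity)", call. = FALSE)
  spectrum_1d(tab[[1]], tab[[2]], nucleus = nucleus,
              frequency_mhz = frequency_mhz, reference = reference)
}

#' Write a 1D spectrum as a two-column tabular file
#'
#' @param spec a [spectrum_1d()].
#' @param path output file path; comma-separated with a `ppm,intensity`
#'   header.
#' @export
write_spectrum_table <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum_1d"))
  utils::write.table(data.frame(ppm = spec$ppm, intensity = spec$intensity),
                     path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write spectrum metadata as a YAML sidecar
#'
#' @param meta named list of metadata (nucleus, frequency, reference,
#'   ground-truth parameters, ...).
#' @param path output file path.
#' @export
write_metadata_yaml <- function(meta, path) {
  yaml::write_yaml(meta, path)
  invisible(path)
}

#' Read a YAML metadata sidecar
#'
#' @param path file path.
#' @return a named list.
#' @export
read_metadata_yaml <- function(path) {
  yaml::read_yaml(path)
}
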