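## Minimal JCAMP-DX 1D support: fixed-point (AFFN) XYDATA=(X++(Y..Y)) tables
## only. Compressed ordinate forms (SQZ/DIF/DUP/PAC) are out of scope and are
## rejected with a clear error.

#' Read a 1D spectrum from a JCAMP-DX file
#'
#' Supports JCAMP-DX files whose data block is an AFFN (plain-number)
#' `##XYDATA=(X++(Y..Y))` table, as written by [write_spectrum_jcamp()].
#' `XFACTOR`/`YFACTOR` scaling is applied; the x axis is interpreted via
#' `XUNITS` (PPM, or HZ converted using `.OBSERVE FREQUENCY`).
#'
#' @param path file path.
#' @param nucleus `"13C"` or `"1H"`; when the file carries
#'   `##.OBSERVE NUCLEUS`, that value wins.
#' @return a [spectrum_1d()].
#' @export
read_spectrum_jcamp <- function(path, nucleus = c("13C", "1H")) {
  nucleus <- match.arg(nucleus)
  lines <- readLines(path, warn = FALSE)
  ldr <- function(label) {
    hit <- grep(paste0("^##", label, "="), lines, ignore.case = TRUE, value = TRUE)
    if (length(hit) == 0L) return(NULL)
    trimws(sub("^##[^=]*=", "", hit[1]))
  }
  obs_nuc <- ldr("\\.OBSERVE NUCLEUS")
  if (!is.null(obs_nuc)) {
    nucleus <- if (grepl("13C", obs_nuc)) "13C" else if (grepl("1H", obs_nuc)) "1H" else nucleus
  }
  freq <- suppressWarnings(as.numeric(ldr("\\.OBSERVE FREQUENCY")))
  xfactor <- suppressWarnings(as.numeric(ldr("XFACTOR")))
  yfactor <- suppressWarnings(as.numeric(ldr("YFACTOR")))
  if (is.na(xfactor) || is.null(ldr("XFACTOR"))) xfactor <- 1
  if (is.na(yfactor) || is.null(ldr("YFACTOR"))) yfactor <- 1
  xunits <- toupper(ldr("XUNITS") %||% "PPM")
  start <- grep("^##XYDATA=", lines, ignore.case = TRUE)
  if (length(start) == 0L) stop("no ##XYDATA block found in ", path, call. = FALSE)
  form <- toupper(gsub("\\s", "", sub("^##XYDATA=", "", lines[start[1]],
                                      ignore.case = TRUE)))
  if (form != "(X++(Y..Y))") {
    stop("unsupported XYDATA form '", form, "'; only (X++(Y..Y)) is supported",
         call. = FALSE)
  }
  body_end <- grep("^##", lines[-seq_len(start[1])])[1]
  body <- if (is.na(body_end)) lines[-seq_len(start[1])] else
    lines[start[1] + seq_len(body_end - 1L)]
  body <- body[nzchar(trimws(body))]
  if (any(grepl("[A-DF-Za-df-z%@]", gsub("[eE][+-]?[0-9]+", "", body)))) {
    stop("compressed JCAMP ordinate forms (SQZ/DIF/...) are not supported; ",
         "only AFFN numeric tables", call. = FALSE)
  }
  xs <- list(); ys <- list()
  for (ln in body) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "[,[:space:]]+")[[1]]))
    if (anyNA(vals) || length(vals) < 2L) {
      stop("malformed XYDATA line: ", ln, call. = FALSE)
    }
    x0 <- vals[1] * xfactor
    yv <- vals[-1] * yfactor
    xs[[length(xs) + 1L]] <- x0
    ys[[length(ys) + 1L]] <- yv
  }
  ## reconstruct per-point x from line-start x values and NPOINTS spacing
  npoints <- suppressWarnings(as.numeric(ldr("NPOINTS")))
  firstx <- suppressWarnings(as.numeric(ldr("FIRSTX"))) * 1
  lastx <- suppressWarnings(as.numeric(ldr("LASTX"))) * 1
  y <- unlist(ys)
  if (!is.na(npoints) && !is.na(firstx) && !is.na(lastx) && npoints >= 2) {
    if (length(y) != npoints) {
      stop(sprintf("NPOINTS (%d) does not match the %d ordinates read",
                   as.integer(npoints), length(y)), call. = FALSE)
    }
    x <- seq(firstx, lastx, length.out = npoints)
  } else {
    ## fall back to uniform spacing inferred from consecutive line starts
    nper <- lengths(ys)
    starts <- unlist(xs)
    if (length(starts) < 2L) stop("cannot infer x spacing", call. = FALSE)
    dx <- (starts[2] - starts[1]) / nper[1]
    x <- starts[1] + dx * (seq_along(y) - 1L)
  }
  if (xunits == "HZ") {
    if (is.na(freq)) stop("XUNITS=HZ requires ##.OBSERVE FREQUENCY", call. = FALSE)
    x <- x / freq
  } else if (xunits != "PPM") {
    stop("unsupported XUNITS '", xunits, "'", call. = FALSE)
  }
  spectrum_1d(x, y, nucleus = nucleus,
              frequency_mhz = if (is.na(freq)) NULL else freq)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a 1D spectrum as a JCAMP-DX file
#'
#' Emits a JCAMP-DX 4.24 file with an AFFN `##XYDATA=(X++(Y..Y))` table
#' (ppm axis, no ordinate compression), readable by
#' [read_spectrum_jcamp()] and by common NMR software.
#'
#' @param spec a [spectrum_1d()].
#' @param path output file path.
#' @param title title record.
#' @export
write_spectrum_jcamp <- function(spec, path, title = "citrateflux spectrum") {
  stopifnot(inherits(spec, "spectrum_1d"))
  n <- length(spec$ppm)
  per_line <- 6L
  header <- c(
    paste0("##TITLE=", title),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=NMR SPECTRUM",
    paste0("##.OBSERVE NUCLEUS=^", spec$nucleus),
    paste0("##.OBSERVE FREQUENCY=", format(spec$frequency_mhz, digits = 8)),
    "##XUNITS=PPM",
    "##YUNITS=ARBITRARY UNITS",
    "##XFACTOR=1",
    "##YFACTOR=1",
    paste0("##FIRSTX=", format(spec$ppm[1], digits = 12)),
    paste0("##LASTX=", format(spec$ppm[n], digits = 12)),
    paste0("##NPOINTS=", n),
    paste0("##FIRSTY=", format(spec$intensity[1], digits = 8)),
    "##XYDATA=(X++(Y..Y))"
  )
  idx <- split(seq_len(n), ceiling(seq_len(n) / per_line))
  body <- vapply(idx, function(i) {
    paste(c(format(spec$ppm[i[1]], digits = 12),
            format(spec$intensity[i], digits = 8)), collapse = " ")
  }, character(1))
  writeLines(c(header, body, "##END="), path)
  invisible(path)
}
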