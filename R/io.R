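## Plain-text spectra and report I/O. One CSV dialect: samples as rows,
## header row "sample_id,concentration,<wavenumber>...", UTF-8, point
## decimal, empty concentration for unknowns. Values are serialised with 17
## significant digits so that read(write(x)) reproduces x exactly.

fmtNum <- function(x) {
  out <- formatC(x, format = "g", digits = 17)
  gsub(" ", "", out)
}

#' Write a SpectraSet to the package's CSV dialect
#'
#' @param x a [SpectraSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @seealso [readSpectra()]
#' @export
writeSpectra <- function(x, path) {
  stopifnot(methods::is(x, "SpectraSet"))
  X <- intensityMatrix(x)
  conc <- concentrations(x)
  concTxt <- ifelse(is.na(conc), "", fmtNum(conc))
  header <- paste(c("sample_id", "concentration", fmtNum(wavenumbers(x))),
                  collapse = ",")
  rows <- vapply(seq_len(nrow(X)), function(i)
    paste(c(sampleIds(x)[i], concTxt[i], fmtNum(X[i, ])), collapse = ","),
    character(1))
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read a SpectraSet from the package's CSV dialect
#'
#' Parse failures (ragged rows, a non-increasing or duplicated wavenumber
#' header, non-numeric intensities) raise errors naming the offending line.
#'
#' @param path input file written by [writeSpectra()] (or conforming to the
#'   dialect).
#' @return a [SpectraSet-class]; missing concentrations become `NA`.
#' @export
readSpectra <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L) stop("spectra file needs a header and >= 1 sample")
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  if (length(header) < 3L || header[1L] != "sample_id" ||
      header[2L] != "concentration")
    stop("line 1: header must start with 'sample_id,concentration'")
  wn <- suppressWarnings(as.numeric(header[-(1:2)]))
  if (anyNA(wn)) stop("line 1: non-numeric wavenumber in header")
  if (anyDuplicated(wn)) stop("line 1: duplicated wavenumber column")
  if (any(diff(wn) <= 0)) stop("line 1: wavenumbers must be strictly increasing")
  p <- length(wn)
  n <- length(lines) - 1L
  X <- matrix(NA_real_, n, p)
  conc <- numeric(n)
  ids <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i + 1L], ",", fixed = TRUE)[[1L]]
    # a trailing empty field is dropped by strsplit; not possible here since
    # intensity columns come last, so a short row is genuinely ragged
    if (length(f) != p + 2L)
      stop(sprintf("line %d: expected %d fields, found %d",
                   i + 1L, p + 2L, length(f)))
    ids[i] <- f[1L]
    conc[i] <- if (identical(f[2L], "")) NA_real_ else {
      v <- suppressWarnings(as.numeric(f[2L]))
      if (is.na(v)) stop(sprintf("line %d: non-numeric concentration", i + 1L))
      v
    }
    v <- suppressWarnings(as.numeric(f[-(1:2)]))
    if (anyNA(v)) stop(sprintf("line %d: non-numeric intensity", i + 1L))
    X[i, ] <- v
  }
  SpectraSet(X, wn, concentrations = conc, sampleIds = ids)
}

reportColumns <- c("method", "nComponents", "nSelected",
                   "selectedWavelengths", "rC", "rmsec", "rP", "rmsep", "rpd")

#' Write a model-comparison report
#'
#' One row per calibration model with the columns `method`, `nComponents`,
#' `nSelected`, `selectedWavelengths` (cluster representatives, 1/cm,
#' semicolon-separated), `rC`, `rmsec`, `rP`, `rmsep`, `rpd`, in that fixed
#' order — the layout of a variable-selection model-comparison table.
#'
#' @param report data.frame as produced by [runPipeline()].
#' @param path output file.
#' @param format `"csv"` or `"txt"` (aligned, human-readable).
#' @return `path`, invisibly.
#' @export
writeModelReport <- function(report, path, format = c("csv", "txt")) {
  format <- match.arg(format)
  if (!is.data.frame(report) || nrow(report) == 0L)
    stop("report must be a non-empty data.frame")
  if (!all(reportColumns %in% names(report)))
    stop("report is missing columns: ",
         paste(setdiff(reportColumns, names(report)), collapse = ", "))
  report <- report[, reportColumns]
  if (format == "csv") {
    utils::write.csv(report, path, row.names = FALSE, quote = TRUE)
  } else {
    num <- vapply(report, is.numeric, logical(1))
    txt <- report
    txt[num] <- lapply(report[num], function(z) formatC(z, digits = 4,
                                                        format = "fg"))
    txt <- rbind(stats::setNames(as.data.frame(as.list(reportColumns)),
                                 reportColumns), txt)
    widths <- vapply(txt, function(col) max(nchar(as.character(col))),
                     integer(1))
    lines <- apply(txt, 1L, function(r)
      paste(mapply(formatC, r, width = widths, MoreArgs = list(flag = "-")),
            collapse = "  "))
    writeLines(trimws(lines, "right"), path, useBytes = TRUE)
  }
  invisible(path)
}
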