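#' Fit a multiplicative scatter correction model
#'
#' The MSC reference is the column-wise mean spectrum of the calibration
#' set. Prediction-set spectra are later corrected against this calibration
#' reference, so no information leaks from prediction samples.
#'
#' @param calibration a [SpectraSet-class] with at least two spectra.
#' @return an [MSCModel-class].
#' @examples
#' s <- generateDataset(generatorConfig(nPoints = 120L, replicates = 2L))
#' m <- mscFit(s)
#' @export
mscFit <- function(calibration) {
  stopifnot(methods::is(calibration, "SpectraSet"))
  if (nSpectra(calibration) < 2L)
    stop("MSC needs at least two calibration spectra; ",
         "with one the reference would equal the spectrum itself")
  X <- intensityMatrix(calibration)
  methods::new("MSCModel", reference = colMeans(X),
               wavenumbers = wavenumbers(calibration))
}

#' Apply multiplicative scatter correction
#'
#' Each spectrum `x` is regressed on the reference `m` over the full grid,
#' `x ~ a + b m`, and replaced by `(x - a) / b`. Correcting the reference
#' itself (or any spectrum of the form `a + b m`) returns the reference.
#' A spectrum whose fitted slope is numerically zero cannot be corrected;
#' its row is returned as `NA` with a warning.
#'
#' @param model an [MSCModel-class] from [mscFit()].
#' @param x a [SpectraSet-class] on the same wavenumber grid.
#' @return a corrected [SpectraSet-class]; the fitted per-sample offsets and
#'   gains are stored in `metadata(x)$msc` for diagnostics.
#' @export
mscCorrect <- function(model, x) {
  stopifnot(methods::is(model, "MSCModel"), methods::is(x, "SpectraSet"))
  wn <- wavenumbers(x)
  if (length(wn) != length(model@wavenumbers) ||
      any(abs(wn - model@wavenumbers) > 1e-8))
    stop("wavenumber grid of 'x' does not match the MSC reference")
  X <- intensityMatrix(x)
  ref <- model@reference
  refC <- ref - mean(ref)
  denom <- sum(refC^2)
  if (denom < 1e-12) stop("MSC reference has no variance")
  b <- as.vector(X %*% refC) / denom  # centred cross-product; sum(refC) == 0
  a <- unname(rowMeans(X)) - b * mean(ref)
  bad <- abs(b) < 1e-12
  corr <- (X - a) / b
  if (any(bad)) {
    warning(sum(bad), " spectrum/spectra with near-zero MSC slope; ",
            "correction refused (rows set to NA)")
    corr[bad, ] <- NA_real_
  }
  out <- SpectraSet(corr, wn, concentrations = concentrations(x),
                    sampleIds = sampleIds(x))
  S4Vectors::metadata(out) <- S4Vectors::metadata(x)
  S4Vectors::metadata(out)$msc <- list(offset = a, gain = b)
  out
}
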