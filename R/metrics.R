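#' Root-mean-square error
#'
#' @param yTrue,yPred numeric vectors of equal, non-zero length.
#' @return `sqrt(mean((yTrue - yPred)^2))` in the units of `yTrue` (mg/L for
#'   concentration models).
#' @examples
#' rmse(c(0, 0), c(3, 4))  # sqrt(12.5)
#' @export
rmse <- function(yTrue, yPred) {
  if (length(yTrue) == 0L) stop("rmse of empty vectors is undefined")
  if (length(yTrue) != length(yPred)) stop("lengths differ")
  sqrt(mean((yTrue - yPred)^2))
}

#' Pearson correlation between reference and predicted values
#'
#' @param yTrue,yPred numeric vectors; both must be non-constant.
#' @return the product-moment correlation.
#' @export
pearsonR <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred)) stop("lengths differ")
  if (stats::var(yTrue) < 1e-24 || stats::var(yPred) < 1e-24)
    stop("correlation undefined for a constant vector")
  stats::cor(yTrue, yPred)
}

#' Ratio of prediction to deviation (RPD)
#'
#' The sample standard deviation (n-1 denominator) of the prediction-set
#' reference values divided by RMSEP. Models with RPD above 2 are
#' conventionally considered usable for quantitative prediction, above 3
#' good quantitative models.
#'
#' @param yTrue prediction-set reference values (non-constant).
#' @param yPred predictions.
#' @return a positive number, `+Inf` (with a warning) when RMSEP is zero.
#' @export
rpd <- function(yTrue, yPred) {
  sdev <- stats::sd(yTrue)
  if (!is.finite(sdev) || sdev < 1e-24)
    stop("prediction-set reference values are constant; RPD undefined")
  err <- rmse(yTrue, yPred)
  if (err == 0) {
    warning("RMSEP is zero; RPD reported as +Inf")
    return(Inf)
  }
  sdev / err
}

#' Spike-recovery statistics
#'
#' Per spiked level: mean and sd of the predictions, the per-sample
#' standard-addition recovery range `100 * predicted / added` (%), the
#' relative standard deviation `100 * sd / mean` (%), and the per-sample
#' relative error range `100 * (predicted - added) / added` (%). A level of
#' zero (blank) is reported descriptively only: recovery and relative error
#' are undefined there and returned as `NA`.
#'
#' @param added numeric spike level per sample (mg/L or mg/kg).
#' @param predicted numeric model predictions, same length.
#' @return a data.frame with one row per level: `level`, `n`, `meanPred`,
#'   `sdPred`, `recoveryMin`, `recoveryMax`, `rsd`, `relErrMin`, `relErrMax`.
#' @examples
#' recoveryStats(rep(1, 3), c(0.9, 1.0, 1.1))
#' @export
recoveryStats <- function(added, predicted) {
  if (length(added) != length(predicted)) stop("lengths differ")
  levels <- sort(unique(added))
  rows <- lapply(levels, function(lv) {
    p <- predicted[added == lv]
    if (length(p) < 2L)
      stop("need >= 2 replicates per level for RSD (level ", lv, ")")
    m <- mean(p)
    blank <- lv == 0
    data.frame(
      level = lv, n = length(p), meanPred = m, sdPred = stats::sd(p),
      recoveryMin = if (blank) NA_real_ else 100 * min(p) / lv,
      recoveryMax = if (blank) NA_real_ else 100 * max(p) / lv,
      rsd = if (abs(m) < 1e-24) NA_real_ else 100 * stats::sd(p) / m,
      relErrMin = if (blank) NA_real_ else 100 * min(p - lv) / lv,
      relErrMax = if (blank) NA_real_ else 100 * max(p - lv) / lv)
  })
  do.call(rbind, rows)
}

#' @describeIn peakIntensity baseline-corrected band intensity of one
#'   spectrum: the maximum intensity inside `center +/- window` minus the
#'   linear baseline interpolated between the window endpoints, evaluated at
#'   the position of the maximum.
#' @param wavenumbers numeric grid matching the spectrum.
#' @param center band position (1/cm).
#' @param window half-width of the search window (1/cm); must cover at
#'   least one grid step and lie inside the grid.
#' @export
setMethod("peakIntensity", "numeric",
  function(x, wavenumbers, center, window = 10, ...) {
    assertNumericVector(wavenumbers, "wavenumbers")
    if (length(x) != length(wavenumbers))
      stop("spectrum and wavenumber grid lengths differ")
    step <- mean(diff(wavenumbers))
    if (window < step) stop("window must span at least one grid step")
    lo <- center - window
    hi <- center + window
    if (lo < min(wavenumbers) || hi > max(wavenumbers))
      stop("window extends outside the wavenumber grid")
    inw <- which(wavenumbers >= lo & wavenumbers <= hi)
    i0 <- inw[1L]
    i1 <- inw[length(inw)]
    imax <- inw[which.max(x[inw])]
    frac <- (wavenumbers[imax] - wavenumbers[i0]) /
      (wavenumbers[i1] - wavenumbers[i0])
    baseline <- x[i0] + frac * (x[i1] - x[i0])
    x[imax] - baseline
  })

#' @describeIn peakIntensity per-sample band intensities of a `SpectraSet`.
#' @export
setMethod("peakIntensity", "SpectraSet",
  function(x, center, window = 10, ...) {
    X <- intensityMatrix(x)
    wn <- wavenumbers(x)
    out <- apply(X, 1L, peakIntensity, wavenumbers = wn, center = center,
                 window = window)
    stats::setNames(out, sampleIds(x))
  })
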