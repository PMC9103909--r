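#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame metadata "metadata<-"
#' @importFrom stats coef cor lm predict rnorm runif sd var setNames
#' @importFrom utils head modifyList
#' @importFrom Rcpp sourceCpp
#' @useDynLib SERSelect, .registration = TRUE
NULL

#' Container for a set of spectra with reference concentrations
#'
#' `SpectraSet` extends [SummarizedExperiment::SummarizedExperiment] with one
#' `"intensity"` assay laid out as wavenumbers (rows) by samples (columns).
#' The wavenumber axis lives in `rowData(x)$wavenumber` and must be strictly
#' increasing; per-sample reference concentrations (mg/L, `NA` for unknowns)
#' live in `colData(x)$concentration`.
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment].
#' @seealso [SpectraSet()], [wavenumbers()], [concentrations()],
#'   [intensityMatrix()]
#' @export
setClass("SpectraSet", contains = "SummarizedExperiment")

setValidity("SpectraSet", function(object) {
  msg <- character()
  wn <- SummarizedExperiment::rowData(object)$wavenumber
  if (is.null(wn))
    msg <- c(msg, "rowData must contain a 'wavenumber' column")
  else {
    if (!is.numeric(wn) || anyNA(wn))
      msg <- c(msg, "wavenumbers must be numeric and non-missing")
    else if (length(wn) > 1L && any(diff(wn) <= 0))
      msg <- c(msg, "wavenumbers must be strictly increasing")
  }
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  if (is.null(SummarizedExperiment::colData(object)$concentration))
    msg <- c(msg, "colData must contain a 'concentration' column")
  if (length(msg)) msg else TRUE
})

#' Synthetic SERS dataset generator configuration
#'
#' Holds the full experimental design and noise model of the synthetic
#' generator: the wavenumber grid, the concentration series with its
#' replicate count, the analyte band library, the intensity-concentration
#' response law, and the scatter / baseline / noise magnitudes. See
#' [generatorConfig()] for the defaults and their rationale.
#'
#' @slot gridMin,gridMax numeric, grid range in 1/cm.
#' @slot nPoints integer, number of grid points.
#' @slot concentrations numeric, calibration levels in mg/L.
#' @slot replicates integer, spectra per level.
#' @slot peaks data.frame with columns `center`, `width`, `amplitude`,
#'   `assignment` (one row per band; width is the HWHM in 1/cm).
#' @slot displacement data.frame (same columns), the bands of the surface
#'   species the analyte displaces on adsorption; zero rows disable the
#'   displacement term.
#' @slot shape character, band profile: `"lorentzian"` or `"gaussian"`.
#' @slot response character, `"linear"` or `"langmuir"`.
#' @slot cSat numeric, Langmuir saturation constant in mg/L.
#' @slot backgroundScale numeric, multiplier of the fixed smooth
#'   substrate/instrument background.
#' @slot backgroundJitterSd numeric, relative s.d. of the per-spectrum
#'   random rescaling of each background component (substrate/matrix
#'   heterogeneity).
#' @slot etalonSd numeric, s.d. (intensity units) of the per-spectrum
#'   amplitudes of the fixed fringe components (broad undulating background
#'   residuals, e.g. etaloning / matrix wiggle).
#' @slot baselineDegree integer, degree of the per-spectrum random baseline
#'   polynomial.
#' @slot baselineScale numeric, s.d. of its coefficients (intensity units).
#' @slot signalJitterSd numeric, relative s.d. of the per-spectrum analyte
#'   signal amplitude (SERS enhancement variability between replicates).
#' @slot scatterGainSd numeric, s.d. of the per-spectrum multiplicative gain
#'   (around 1).
#' @slot scatterOffsetSd numeric, s.d. of the per-spectrum additive offset.
#' @slot noiseSd numeric, s.d. of iid additive noise per point.
#' @slot seed integer RNG seed; the generator is a pure function of the
#'   configuration.
#' @export
setClass("GeneratorConfig",
  representation(
    gridMin = "numeric", gridMax = "numeric", nPoints = "integer",
    concentrations = "numeric", replicates = "integer",
    peaks = "data.frame", displacement = "data.frame",
    shape = "character",
    response = "character", cSat = "numeric",
    backgroundScale = "numeric", backgroundJitterSd = "numeric",
    etalonSd = "numeric", signalJitterSd = "numeric",
    baselineDegree = "integer", baselineScale = "numeric",
    scatterGainSd = "numeric", scatterOffsetSd = "numeric",
    noiseSd = "numeric", seed = "integer"))

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  if (object@nPoints < 2L) msg <- c(msg, "nPoints must be >= 2")
  if (object@gridMax <= object@gridMin) msg <- c(msg, "gridMax must exceed gridMin")
  cc <- object@concentrations
  if (any(cc <= 0)) msg <- c(msg, "concentrations must be strictly positive")
  if (anyDuplicated(cc)) msg <- c(msg, "concentrations must be distinct")
  if (object@replicates < 1L) msg <- c(msg, "replicates must be >= 1")
  pk <- object@peaks
  need <- c("center", "width", "amplitude")
  if (!all(need %in% names(pk)))
    msg <- c(msg, "peaks needs columns center, width, amplitude")
  else if (nrow(pk)) {
    if (any(pk$width <= 0)) msg <- c(msg, "peak widths must be positive")
    if (any(pk$amplitude <= 0)) msg <- c(msg, "peak amplitudes must be positive")
    if (any(pk$center < object@gridMin | pk$center > object@gridMax))
      msg <- c(msg, "peak centers must lie within the grid range")
  }
  dp <- object@displacement
  if (!all(need %in% names(dp)))
    msg <- c(msg, "displacement needs columns center, width, amplitude")
  else if (nrow(dp)) {
    if (any(dp$width <= 0) || any(dp$amplitude <= 0))
      msg <- c(msg, "displacement widths and amplitudes must be positive")
    if (any(dp$center < object@gridMin | dp$center > object@gridMax))
      msg <- c(msg, "displacement centers must lie within the grid range")
  }
  if (!object@shape %in% c("lorentzian", "gaussian"))
    msg <- c(msg, "shape must be 'lorentzian' or 'gaussian'")
  if (!object@response %in% c("linear", "langmuir"))
    msg <- c(msg, "response must be 'linear' or 'langmuir'")
  if (object@cSat <= 0) msg <- c(msg, "cSat must be positive")
  if (object@scatterGainSd < 0 || object@scatterGainSd >= 1)
    msg <- c(msg, "scatterGainSd must lie in [0, 1) so gains stay positive")
  if (object@scatterOffsetSd < 0 || object@noiseSd < 0 ||
      object@baselineScale < 0 || object@backgroundJitterSd < 0 ||
      object@etalonSd < 0 || object@signalJitterSd < 0)
    msg <- c(msg, "noise/scatter/baseline scales must be non-negative")
  if (object@baselineDegree < 0L) msg <- c(msg, "baselineDegree must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Multiplicative scatter correction model
#'
#' @slot reference numeric, the reference spectrum (column means of the
#'   calibration intensities).
#' @slot wavenumbers numeric, grid the reference was computed on.
#' @export
setClass("MSCModel",
  representation(reference = "numeric", wavenumbers = "numeric"))

setValidity("MSCModel", function(object) {
  if (length(object@reference) != length(object@wavenumbers))
    "reference and wavenumbers must have equal length" else TRUE
})

#' PLS1 regression model
#'
#' Fitted by [plsFit()] via NIPALS with X-deflation. `coefficients` maps a
#' raw (uncentred) spectrum row to a prediction together with `intercept`;
#' `coefPath` holds the coefficient vectors of every truncation
#' k = 1..nComponents.
#'
#' @slot xMeans,yMean centring vectors.
#' @slot weights,loadings,scores,yLoadings the NIPALS structure (one column /
#'   element per latent variable).
#' @slot coefficients,intercept raw-scale regression vector at `nComponents`.
#' @slot coefPath matrix of coefficients for each truncation.
#' @slot nComponents integer, latent variables retained.
#' @export
setClass("PLSModel",
  representation(
    xMeans = "numeric", yMean = "numeric",
    weights = "matrix", loadings = "matrix", scores = "matrix",
    yLoadings = "numeric",
    coefficients = "numeric", intercept = "numeric", coefPath = "matrix",
    nComponents = "integer"))

setValidity("PLSModel", function(object) {
  msg <- character()
  if (length(object@coefficients) != length(object@xMeans))
    msg <- c(msg, "coefficient length must match xMeans length")
  if (object@nComponents < 1L) msg <- c(msg, "nComponents must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Result of a wavelength-selection run
#'
#' @slot method character label (`"boss"`, `"ga"`, `"lasso"`, `"ivissa"`).
#' @slot indices integer, selected column indices into the wavenumber grid
#'   (unique, sorted).
#' @slot wavenumbers numeric, the corresponding wavenumbers.
#' @slot rmsecvTrace numeric, per-iteration RMSECV.
#' @slot nVarTrace integer, per-iteration retained-variable count.
#' @slot weights numeric, final per-variable weights where the method
#'   defines them (length p, zero elsewhere), else length 0.
#' @slot seed integer seed the run used.
#' @export
setClass("SelectionResult",
  representation(
    method = "character", indices = "integer", wavenumbers = "numeric",
    rmsecvTrace = "numeric", nVarTrace = "integer",
    weights = "numeric", seed = "integer"))

setValidity("SelectionResult", function(object) {
  msg <- character()
  idx <- object@indices
  if (length(idx) == 0L) msg <- c(msg, "selection must be non-empty")
  if (is.unsorted(idx, strictly = TRUE)) msg <- c(msg, "indices must be sorted and unique")
  if (length(idx) && any(idx < 1L)) msg <- c(msg, "indices must be positive")
  if (length(object@wavenumbers) != length(idx))
    msg <- c(msg, "wavenumbers must parallel indices")
  if (length(object@rmsecvTrace) != length(object@nVarTrace))
    msg <- c(msg, "trace lengths must agree")
  if (length(msg)) msg else TRUE
})

#' Rank-stratified calibration/prediction split
#'
#' @slot calibration,prediction integer sample indices (disjoint, covering
#'   all samples).
#' @slot seed integer seed.
#' @export
setClass("SplitResult",
  representation(calibration = "integer", prediction = "integer",
                 seed = "integer"))

setValidity("SplitResult", function(object) {
  both <- c(object@calibration, object@prediction)
  if (anyDuplicated(both)) "calibration and prediction must be disjoint" else TRUE
})
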