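#' Construct a SpectraSet
#'
#' @param intensities numeric matrix, samples x wavenumbers.
#' @param wavenumbers numeric, strictly increasing axis in 1/cm.
#' @param concentrations numeric, reference concentrations in mg/L (`NA` for
#'   unknowns). Recycled `NA` if omitted.
#' @param sampleIds character sample labels; defaults to `s001, s002, ...`.
#'
#' @return a [SpectraSet-class] object.
#' @examples
#' s <- SpectraSet(matrix(rnorm(20), 4), seq(400, 500, length.out = 5),
#'                 concentrations = c(1, 2, 5, 10))
#' nSpectra(s)
#' @export
SpectraSet <- function(intensities, wavenumbers,
                       concentrations = rep(NA_real_, nrow(intensities)),
                       sampleIds = NULL) {
  intensities <- as.matrix(intensities)
  if (ncol(intensities) != length(wavenumbers))
    stop("ncol(intensities) must equal length(wavenumbers)")
  n <- nrow(intensities)
  if (length(concentrations) != n)
    stop("length(concentrations) must equal nrow(intensities)")
  if (is.null(sampleIds)) sampleIds <- sprintf("s%03d", seq_len(n))
  if (length(sampleIds) != n)
    stop("length(sampleIds) must equal nrow(intensities)")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = t(unname(intensities))),
    rowData = S4Vectors::DataFrame(wavenumber = as.numeric(wavenumbers)),
    colData = S4Vectors::DataFrame(
      sample_id = as.character(sampleIds),
      concentration = as.numeric(concentrations),
      row.names = make.unique(as.character(sampleIds))))
  methods::new("SpectraSet", se)
}

#' @rdname SpectraSet
#' @aliases wavenumbers,SpectraSet-method
#' @export
setMethod("wavenumbers", "SpectraSet", function(x)
  SummarizedExperiment::rowData(x)$wavenumber)

#' @rdname SpectraSet
#' @export
setMethod("concentrations", "SpectraSet", function(x)
  SummarizedExperiment::colData(x)$concentration)

#' @rdname SpectraSet
#' @export
setReplaceMethod("concentrations", "SpectraSet", function(x, value) {
  SummarizedExperiment::colData(x)$concentration <- as.numeric(value)
  methods::validObject(x)
  x
})

#' @rdname SpectraSet
#' @export
setMethod("sampleIds", "SpectraSet", function(x)
  SummarizedExperiment::colData(x)$sample_id)

#' @rdname SpectraSet
#' @export
setMethod("intensityMatrix", "SpectraSet", function(x) {
  m <- t(SummarizedExperiment::assay(x, "intensity"))
  dimnames(m) <- list(sampleIds(x), NULL)
  m
})

#' @rdname SpectraSet
#' @export
setMethod("nSpectra", "SpectraSet", function(x) ncol(x))

setMethod("show", "SpectraSet", function(object) {
  wn <- wavenumbers(object)
  conc <- concentrations(object)
  cat(sprintf("SpectraSet: %d spectra x %d wavenumbers (%.1f-%.1f 1/cm)\n",
              ncol(object), nrow(object), min(wn), max(wn)))
  known <- conc[!is.na(conc)]
  if (length(known))
    cat(sprintf("  concentrations: %d known, %d levels, %.3g-%.3g mg/L\n",
                length(known), length(unique(known)), min(known), max(known)))
  else cat("  concentrations: all unknown\n")
  invisible(object)
})

setMethod("show", "MSCModel", function(object) {
  cat(sprintf("MSCModel: reference spectrum on %d points (%.1f-%.1f 1/cm)\n",
              length(object@reference), min(object@wavenumbers),
              max(object@wavenumbers)))
  invisible(object)
})

setMethod("show", "PLSModel", function(object) {
  cat(sprintf("PLSModel: %d latent variable(s), %d wavelength variables\n",
              object@nComponents, length(object@coefficients)))
  invisible(object)
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult [%s]: %d variables selected (%d iterations)\n",
              object@method, length(object@indices),
              length(object@rmsecvTrace)))
  if (length(object@rmsecvTrace))
    cat(sprintf("  best RMSECV %.4g\n", min(object@rmsecvTrace)))
  invisible(object)
})

setMethod("show", "SplitResult", function(object) {
  cat(sprintf("SplitResult: %d calibration / %d prediction samples\n",
              length(object@calibration), length(object@prediction)))
  invisible(object)
})

setMethod("show", "GeneratorConfig", function(object) {
  cat(sprintf(paste0(
    "GeneratorConfig: %d levels x %d replicates on %d points ",
    "(%.0f-%.0f 1/cm)\n  %d %s band(s), %s response, seed %d\n"),
    length(object@concentrations), object@replicates, object@nPoints,
    object@gridMin, object@gridMax, nrow(object@peaks), object@shape,
    object@response, object@seed))
  invisible(object)
})

#' Accessors for fitted models
#'
#' @param object a `PLSModel`.
#' @param ... ignored.
#' @return `coef` returns the raw-scale regression coefficient vector.
#' @export
setMethod("coef", "PLSModel", function(object, ...) object@coefficients)

#' @rdname coef-PLSModel-method
#' @param x a `SelectionResult`.
#' @export
selectedIndices <- function(x) {
  stopifnot(methods::is(x, "SelectionResult"))
  x@indices
}

#' @rdname coef-PLSModel-method
#' @export
selectedWavenumbers <- function(x) {
  stopifnot(methods::is(x, "SelectionResult"))
  x@wavenumbers
}
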