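#' @rdname SpectraSet
#' @param x a `SpectraSet`.
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @rdname SpectraSet
#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))

#' @rdname SpectraSet
#' @param value replacement value.
#' @export
setGeneric("concentrations<-", function(x, value) standardGeneric("concentrations<-"))

#' @rdname SpectraSet
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname SpectraSet
#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))

#' @rdname SpectraSet
#' @export
setGeneric("nSpectra", function(x) standardGeneric("nSpectra"))

#' Baseline-corrected peak intensity
#'
#' @param x a numeric spectrum or a `SpectraSet`.
#' @param ... passed to methods.
#' @export
setGeneric("peakIntensity", function(x, ...) standardGeneric("peakIntensity"))
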