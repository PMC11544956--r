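#' @rdname SpectrumSet
#' @param x,object a `SpectrumSet` (or other object with a method).
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname SpectrumSet
#' @export
setGeneric("spectra", function(x) standardGeneric("spectra"))

#' @rdname SpectrumSet
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @rdname SpectrumSet
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname SpectrumSet
#' @export
setGeneric("analysisDay", function(x) standardGeneric("analysisDay"))

#' @rdname snv
#' @export
setGeneric("snv", function(x) standardGeneric("snv"))

#' @rdname sgDerivative
#' @export
setGeneric("sgDerivative",
    function(x, order = 1L, window = 5L, polyOrder = 2L)
        standardGeneric("sgDerivative"))

#' @rdname pairCenter
#' @export
setGeneric("pairCenter", function(x) standardGeneric("pairCenter"))

#' @rdname vipScores
#' @export
setGeneric("vipScores", function(object) standardGeneric("vipScores"))

#' @rdname CVScheme
#' @export
setGeneric("cvGroups", function(x) standardGeneric("cvGroups"))

#' @rdname BEResult
#' @export
setGeneric("beTrace", function(object) standardGeneric("beTrace"))

#' @rdname BEResult
#' @export
setGeneric("selectedWavelengths",
    function(object) standardGeneric("selectedWavelengths"))

#' @rdname BEResult
#' @export
setGeneric("finalModel", function(object) standardGeneric("finalModel"))
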