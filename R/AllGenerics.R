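#' @rdname arms
#' @export
setGeneric("arms", function(x) standardGeneric("arms"))

#' @rdname geneLengths
#' @export
setGeneric("geneLengths", function(x) standardGeneric("geneLengths"))

#' @rdname simulationTruth
#' @export
setGeneric("simulationTruth", function(x) standardGeneric("simulationTruth"))

#' @rdname treatmentArms
#' @export
setGeneric("treatmentArms", function(x) standardGeneric("treatmentArms"))

#' @rdname contrastArms
#' @export
setGeneric("contrastArms", function(x) standardGeneric("contrastArms"))
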