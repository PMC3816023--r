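#' @rdname FusionPanel-class
#' @param x a \code{FusionPanel}, \code{IntensityGrid} or \code{SampleReport}
#' @export
setGeneric("primers", function(x) standardGeneric("primers"))

#' @rdname FusionPanel-class
#' @export
setGeneric("probes", function(x) standardGeneric("probes"))

#' @rdname FusionPanel-class
#' @export
setGeneric("arrayLayout", function(x) standardGeneric("arrayLayout"))

#' @rdname FusionPanel-class
#' @export
setGeneric("fusionRules", function(x) standardGeneric("fusionRules"))

#' @rdname FusionPanel-class
#' @export
setGeneric("fusionIds", function(x) standardGeneric("fusionIds"))

#' @rdname IntensityGrid-class
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname IntensityGrid-class
#' @export
setGeneric("spots", function(x) standardGeneric("spots"))

#' @rdname SampleReport-class
#' @export
setGeneric("qcPass", function(x) standardGeneric("qcPass"))

#' @rdname SampleReport-class
#' @export
setGeneric("trueProbes", function(x) standardGeneric("trueProbes"))

#' @rdname SampleReport-class
#' @export
setGeneric("fusionCalls", function(x) standardGeneric("fusionCalls"))

#' @rdname SampleReport-class
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))
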