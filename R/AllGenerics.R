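#' @name cytodyn-generics
#' @title Generics for cytodyn data containers
#' @description Accessor generics for the package's S4 classes.
#' @param x,object a cytodyn object.
#' @param ... further arguments for methods.
NULL

#' @rdname cytodyn-generics
#' @export
setGeneric("mediatorNames", function(x) standardGeneric("mediatorNames"))

#' @rdname cytodyn-generics
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))

#' @rdname cytodyn-generics
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))

#' @rdname cytodyn-generics
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname cytodyn-generics
#' @export
setGeneric("longFormat", function(x, ...) standardGeneric("longFormat"))

#' @rdname cytodyn-generics
#' @export
setGeneric("edges", function(x, ...) standardGeneric("edges"))

#' @rdname cytodyn-generics
#' @export
setGeneric("networkDensity", function(x, ...) standardGeneric("networkDensity"))

#' @rdname cytodyn-generics
#' @export
setGeneric("matchedPairs", function(x) standardGeneric("matchedPairs"))

#' @rdname cytodyn-generics
#' @export
setGeneric("unmatchedIds", function(x) standardGeneric("unmatchedIds"))

#' @rdname cytodyn-generics
#' @export
setGeneric("edgeProbabilities", function(x) standardGeneric("edgeProbabilities"))

#' @rdname cytodyn-generics
#' @export
setGeneric("bestParents", function(x) standardGeneric("bestParents"))

#' @rdname cytodyn-generics
#' @export
setGeneric("feedbackNodes", function(x, ...) standardGeneric("feedbackNodes"))

#' @rdname cytodyn-generics
#' @export
setGeneric("centralNodes", function(x, ...) standardGeneric("centralNodes"))

#' @rdname cytodyn-generics
#' @export
setGeneric("consensusEdges", function(x, ...) standardGeneric("consensusEdges"))
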