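#' Extract multiplicity sufficient statistics
#'
#' @param object a \linkS4class{CountsTable}.
#' @param ... passed to methods.
#' @return a \linkS4class{Multiplicities} object.
#' @export
setGeneric("multiplicities", function(object, ...) standardGeneric("multiplicities"))

#' Sample a contingency table from a ground-truth model
#'
#' Draws n i.i.d. (x, y) pairs from the model and tallies them into a
#' \linkS4class{CountsTable}.
#'
#' @param model a \linkS4class{JointModel} or \linkS4class{ParityModel}.
#' @param n number of samples.
#' @param seed optional integer seed for reproducibility.
#' @param ... passed to methods.
#' @return a \linkS4class{CountsTable}.
#' @export
setGeneric("sampleCounts", function(model, n, seed = NULL, ...) standardGeneric("sampleCounts"))

#' Exact mutual information of a known model
#'
#' @param model a \linkS4class{JointModel} or \linkS4class{ParityModel}.
#' @param ... passed to methods.
#' @return mutual information in nats.
#' @export
setGeneric("trueInformation", function(model, ...) standardGeneric("trueInformation"))

#' Exact entropies of a known model
#'
#' @param model a \linkS4class{JointModel} or \linkS4class{ParityModel}.
#' @param ... passed to methods.
#' @return named numeric vector with HX, HY, HYgX, HXY and I, in nats.
#' @export
setGeneric("modelEntropies", function(model, ...) standardGeneric("modelEntropies"))

#' @rdname countsAccessors
#' @export
setGeneric("countsMatrix", function(object) standardGeneric("countsMatrix"))
#' @rdname countsAccessors
#' @export
setGeneric("xIds", function(object) standardGeneric("xIds"))
#' @rdname countsAccessors
#' @export
setGeneric("yIds", function(object) standardGeneric("yIds"))
#' @rdname countsAccessors
#' @export
setGeneric("sampleTotal", function(object) standardGeneric("sampleTotal"))
#' @rdname countsAccessors
#' @export
setGeneric("xCounts", function(object) standardGeneric("xCounts"))
#' @rdname countsAccessors
#' @export
setGeneric("yCounts", function(object) standardGeneric("yCounts"))
#' @rdname countsAccessors
#' @export
setGeneric("xFrequencies", function(object) standardGeneric("xFrequencies"))
#' @rdname countsAccessors
#' @export
setGeneric("yFrequencies", function(object) standardGeneric("yFrequencies"))

#' @rdname multAccessors
#' @export
setGeneric("coincidenceCount", function(object) standardGeneric("coincidenceCount"))
#' @rdname multAccessors
#' @export
setGeneric("f11", function(object) standardGeneric("f11"))
#' @rdname multAccessors
#' @export
setGeneric("classKey", function(object) standardGeneric("classKey"))
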