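#' @rdname SeroAssignment-class
#' @param object a \code{SeroAssignment}
#' @export
setGeneric("seroLabel", function(object) standardGeneric("seroLabel"))

#' @rdname SeroAssignment-class
#' @export
setGeneric("epitopeCall", function(object) standardGeneric("epitopeCall"))

#' @rdname SeroAssignment-class
#' @export
setGeneric("rationale", function(object) standardGeneric("rationale"))

#' @rdname SeroAssignment-class
#' @export
setGeneric("offendingPositions",
           function(object) standardGeneric("offendingPositions"))

#' @rdname MotifProfile-class
#' @param object a \code{MotifProfile}
#' @export
setGeneric("profileMatrix", function(object) standardGeneric("profileMatrix"))

#' @rdname ClassificationReport-class
#' @param object a \code{ClassificationReport}
#' @export
setGeneric("reportRecords", function(object) standardGeneric("reportRecords"))

#' @rdname ClassificationReport-class
#' @export
setGeneric("reportSummary", function(object) standardGeneric("reportSummary"))

#' @rdname PositionPattern-class
#' @param object a \code{PositionPattern}
#' @export
setGeneric("patternPositions",
           function(object) standardGeneric("patternPositions"))

#' @rdname PositionPattern-class
#' @export
setGeneric("uniqueFor", function(object) standardGeneric("uniqueFor"))

#' @rdname PositionPattern-class
#' @export
setGeneric("residuesByLabel",
           function(object) standardGeneric("residuesByLabel"))
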