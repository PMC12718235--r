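#' @rdname TrackSet-class
#' @param x,object A \code{TrackSet}.
#' @export
setGeneric("detections", function(x) standardGeneric("detections"))

#' @rdname TrackSet-class
#' @export
setGeneric("nTracks", function(x) standardGeneric("nTracks"))

#' @rdname TrackSet-class
#' @export
setGeneric("trackIds", function(x) standardGeneric("trackIds"))

#' @rdname TrackSet-class
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname ModelRanking-class
#' @param x A \code{ModelRanking}.
#' @export
setGeneric("rankingTable", function(x) standardGeneric("rankingTable"))

#' @rdname ModelRanking-class
#' @param i Rank position (1 = best).
#' @export
setGeneric("topFit", function(x, i = 1L) standardGeneric("topFit"))

#' @rdname IntersectionSet-class
#' @param x An \code{IntersectionSet}.
#' @export
setGeneric("roots", function(x) standardGeneric("roots"))

#' @rdname RegimeSplit-class
#' @param x A \code{RegimeSplit}.
#' @export
setGeneric("slowFraction", function(x) standardGeneric("slowFraction"))

#' @rdname RegimeSplit-class
#' @export
setGeneric("regimeSummary", function(x) standardGeneric("regimeSummary"))
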