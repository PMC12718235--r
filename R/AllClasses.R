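#' @import methods
NULL

#' TrackSet: frame-wise tracking trajectories
#'
#' Container for frame-wise single-cell tracking data: one row per detected
#' cell per frame, grouped into trajectories by track identifier. Positions
#' are planar coordinates in micrometres; \code{t} is the acquisition time in
#' seconds. Detections are stored sorted by track id and frame.
#'
#' Structural validity (required columns, numeric finite coordinates,
#' positive frame interval) is enforced at construction. Content-level
#' problems a tracking export may legitimately contain — duplicated frames
#' within a track, non-monotone timestamps — are *reported*, not rejected:
#' see \code{\link{validateTrackSet}}.
#'
#' @slot detections \code{data.frame} with columns \code{track_id}
#'   (character), \code{frame} (integer, >= 0), \code{x}, \code{y}
#'   (micrometres), \code{t} (seconds).
#' @slot frameInterval Nominal time between consecutive frames in seconds
#'   (default 0.024, i.e. the high-speed acquisition interval this pipeline
#'   was designed around).
#' @slot source Provenance string (file path or simulator description).
#' @slot metadata Free-form list (e.g. I/O report, ground-truth linkage for
#'   simulated data).
#'
#' @seealso \code{\link{readTracks}}, \code{\link{instantaneousSpeeds}}
#' @export
setClass("TrackSet",
  representation(
    detections    = "data.frame",
    frameInterval = "numeric",
    source        = "character",
    metadata      = "list"
  ),
  prototype(
    detections = data.frame(track_id = character(), frame = integer(),
                            x = numeric(), y = numeric(), t = numeric()),
    frameInterval = 0.024, source = "", metadata = list()
  )
)

setValidity("TrackSet", function(object) {
  msgs <- character()
  d <- object@detections
  need <- c("track_id", "frame", "x", "y", "t")
  miss <- setdiff(need, names(d))
  if (length(miss))
    return(sprintf("detections lacks column(s): %s",
                   paste(miss, collapse = ", ")))
  if (nrow(d)) {
    if (!is.numeric(d$frame) || any(d$frame < 0 | d$frame != floor(d$frame)))
      msgs <- c(msgs, "frame must be a nonnegative integer index")
    if (!all(is.finite(d$x)) || !all(is.finite(d$y)))
      msgs <- c(msgs, "x and y must be finite")
    if (!is.numeric(d$t) || anyNA(d$t))
      msgs <- c(msgs, "t must be numeric and non-missing")
  }
  if (length(object@frameInterval) != 1L || !is.finite(object@frameInterval) ||
      object@frameInterval <= 0)
    msgs <- c(msgs, "frameInterval must be a single positive number")
  if (length(msgs)) msgs else TRUE
})

#' FilterReport: bookkeeping of trajectory and speed-sample exclusions
#'
#' Records, stage by stage, how many trajectories were removed by the
#' minimum-duration and minimum-path-length rules and how many individual
#' speed samples the upper speed cutoff excluded.
#' \code{cutoffExcludedPercent} is
#' \eqn{100 \times} removed-by-cutoff / samples-before-cutoff (0 when the
#' denominator is 0); the denominator is the number of speed samples
#' computed on trajectories that survived the trajectory-level filters.
#'
#' @export
setClass("FilterReport",
  representation(
    nTracksIn                = "integer",
    nTracksRemovedDuration   = "integer",
    nTracksRemovedLength     = "integer",
    nSpeedSamplesBeforeCutoff = "integer",
    nSamplesRemovedByCutoff  = "integer",
    cutoffExcludedPercent    = "numeric"
  )
)

#' DistSpec: a candidate distribution family on a truncated support
#'
#' Describes one candidate model for the instantaneous-speed distribution:
#' either a single continuous family truncated and renormalised to the
#' support interval, or a two-component mixture of such a family with a
#' uniform background spanning the full support. Supported families:
#' lognormal, cauchy, normal, gamma, weibull, exponential, uniform.
#'
#' @slot family Component family name.
#' @slot mixture Logical; if \code{TRUE} the model is
#'   \eqn{w f_{trunc}(x) + (1-w)/(hi-lo)}.
#' @slot support Numeric length-2 \code{c(lo, hi)}; densities are 0 outside.
#'   \code{hi} may be \code{Inf} for untruncated single families (used e.g.
#'   for closed-form intersection checks).
#' @slot nParams Number of free parameters (mixture weight counts; the fixed
#'   uniform bounds do not).
#' @export
setClass("DistSpec",
  representation(family = "character", mixture = "logical",
                 support = "numeric", nParams = "integer")
)

setValidity("DistSpec", function(object) {
  fams <- c("lognormal", "cauchy", "normal", "gamma", "weibull",
            "exponential", "uniform")
  if (!(object@family %in% fams))
    return(sprintf("unknown family '%s'", object@family))
  if (object@family == "uniform" && object@mixture)
    return("a uniform+uniform mixture is not identifiable")
  s <- object@support
  if (length(s) != 2L || !(s[1] >= 0) || !(s[2] > s[1]))
    return("support must be c(lo, hi) with 0 <= lo < hi")
  if (object@mixture && !is.finite(s[2]))
    return("mixture models need a finite support (uniform background)")
  TRUE
})

#' FitResult: a fitted speed-distribution model
#'
#' Result of \code{\link{fitMLE}}: the model specification, the estimated
#' parameter vector (component parameters plus the mixture weight \code{w}
#' when applicable), the maximised log-likelihood, and optimisation
#' diagnostics. \code{\link{speedPdf}}, \code{\link{speedCdf}} and
#' \code{\link{sampleSpeeds}} evaluate and sample the fitted model.
#'
#' A mixture whose weight is estimated on the boundary (\code{w} = 0 or 1)
#' is flagged \code{boundary = TRUE} and carries the nested single-family
#' fit in \code{nested}.
#'
#' @export
setClass("FitResult",
  representation(
    spec          = "DistSpec",
    params        = "numeric",
    logLik        = "numeric",
    n             = "integer",
    converged     = "logical",
    nRestartsUsed = "integer",
    boundary      = "logical",
    nested        = "ANY"
  ),
  prototype(boundary = FALSE, nested = NULL, nRestartsUsed = 0L,
            converged = TRUE, n = 0L, logLik = NA_real_)
)

setValidity("FitResult", function(object) {
  p <- object@params
  need <- familyParamNames(object@spec@family)
  if (object@spec@mixture) need <- c(need, "w")
  miss <- setdiff(need, names(p))
  if (length(miss))
    return(sprintf("params lacks: %s", paste(miss, collapse = ", ")))
  if (object@spec@mixture && (p[["w"]] < 0 || p[["w"]] > 1))
    return("mixture weight w must lie in [0, 1]")
  scalePar <- intersect(names(p), c("sdlog", "scale", "sd", "shape", "rate"))
  if (length(scalePar) && any(p[scalePar] <= 0))
    return("scale/shape parameters must be positive")
  TRUE
})

#' ModelRanking: candidate fits ordered by an information criterion
#'
#' Table of fitted candidate models with log-likelihood, AIC, BIC and HQC,
#' sorted by the chosen criterion (ascending for information criteria,
#' descending for log-likelihood). At most \code{topN} rows are kept
#' (default 10, the conventional "top ten best fits" report size).
#'
#' @slot table \code{data.frame} with one row per retained fit.
#' @slot fits List of \code{FitResult}, parallel to \code{table}.
#' @slot criterion Sorting criterion used.
#' @export
setClass("ModelRanking",
  representation(table = "data.frame", fits = "list", criterion = "character")
)

#' IntersectionSet: roots of the difference of two fitted PDFs
#'
#' Speeds at which two fitted probability density curves cross, found by a
#' sign scan on a regular grid followed by bisection refinement. Tangential
#' contacts (no sign change) are not reported.
#'
#' @export
setClass("IntersectionSet",
  representation(roots = "numeric", interval = "numeric",
                 gridPoints = "integer")
)

#' RegimeSplit: slow/fast partition of speed samples at a threshold
#'
#' Partition of each population's pooled speed measurements into a slow
#' regime (speed < threshold) and a fast regime (speed >= threshold), with
#' per-regime counts, means, standard deviations, and the slow fraction in
#' percent.
#'
#' @export
setClass("RegimeSplit",
  representation(threshold = "numeric", slow = "list", fast = "list",
                 summary = "data.frame")
)

#' HyphalNetwork: simulated branching mycelial network geometry
#'
#' Planar polyline segments produced by a seeded branching random walk from
#' an origin (the inoculated drop) toward a target; side branches attach to
#' the trunk, so the network is connected by construction. Used as the
#' substrate along which simulated bacterial agents move.
#'
#' @slot segments List of 2-column coordinate matrices (micrometres).
#' @slot adjacency \code{data.frame(segment, parent, parentVertex)};
#'   \code{parent = 0} marks the trunk.
#' @slot box Numeric length-2 bounding box (micrometres).
#' @export
setClass("HyphalNetwork",
  representation(segments = "list", adjacency = "data.frame", box = "numeric")
)

setValidity("HyphalNetwork", function(object) {
  if (!length(object@segments)) return("network has no segments")
  a <- object@adjacency
  if (nrow(a) != length(object@segments))
    return("adjacency must have one row per segment")
  if (any(a$parent >= a$segment))
    return("each segment's parent must precede it (connected, acyclic)")
  for (s in object@segments) {
    if (any(s[, 1] < 0 | s[, 1] > object@box[1] |
            s[, 2] < 0 | s[, 2] > object@box[2]))
      return("segment coordinates outside the bounding box")
  }
  TRUE
})
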