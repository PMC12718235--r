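#' Construct a TrackSet from a detections table
#'
#' @param detections \code{data.frame} with columns \code{track_id},
#'   \code{frame}, \code{x}, \code{y} and optionally \code{t}; when \code{t}
#'   is absent it is reconstructed as \code{frame * frameInterval}.
#' @param frameInterval Time between consecutive frames in seconds.
#' @param source Provenance string.
#' @param metadata Optional list of ancillary information.
#' @return A \code{\link{TrackSet-class}} object with detections sorted by
#'   track id and frame.
#' @examples
#' ts <- TrackSet(data.frame(track_id = "A", frame = 0:1,
#'                           x = c(0, 3), y = c(0, 4)))
#' nTracks(ts)
#' @export
TrackSet <- function(detections, frameInterval = 0.024, source = "",
                     metadata = list()) {
  d <- as.data.frame(detections)
  need <- c("track_id", "frame", "x", "y")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stopf("detections table lacks column(s): %s", paste(miss, collapse = ", "))
  d$track_id <- as.character(d$track_id)
  d$frame <- as.integer(d$frame)
  if (!"t" %in% names(d)) d$t <- d$frame * frameInterval
  d <- d[, c("track_id", "frame", "x", "y", "t")]
  # radix sort: stable C-locale ordering regardless of the session locale
  if (nrow(d)) d <- d[order(d$track_id, d$frame, method = "radix"), ,
                      drop = FALSE]
  rownames(d) <- NULL
  new("TrackSet", detections = d, frameInterval = frameInterval,
      source = source, metadata = metadata)
}

#' @rdname TrackSet-class
#' @export
setMethod("detections", "TrackSet", function(x) x@detections)

#' @rdname TrackSet-class
#' @export
setMethod("nTracks", "TrackSet",
          function(x) length(unique(x@detections$track_id)))

#' @rdname TrackSet-class
#' @export
setMethod("trackIds", "TrackSet", function(x) unique(x@detections$track_id))

#' @rdname TrackSet-class
#' @export
setMethod("frameInterval", "TrackSet", function(x) x@frameInterval)

setMethod("show", "TrackSet", function(object) {
  d <- object@detections
  cat(sprintf("TrackSet: %d trajectories, %d detections\n",
              length(unique(d$track_id)), nrow(d)))
  cat(sprintf("  frame interval: %g s", object@frameInterval))
  if (nzchar(object@source)) cat(sprintf("  source: %s", object@source))
  cat("\n")
  if (nrow(d))
    cat(sprintf("  time span: %.3f–%.3f s;  x: %.1f–%.1f µm;  y: %.1f–%.1f µm\n",
                min(d$t), max(d$t), min(d$x), max(d$x), min(d$y), max(d$y)))
})

#' Report content-level problems in a TrackSet
#'
#' Tracking exports can contain duplicated frames within a track (double
#' detections) or timestamps that do not increase with the frame index.
#' These do not prevent constructing a \code{TrackSet}; this function lists
#' them so a user can decide whether to repair or drop the affected tracks.
#'
#' @param tracks A \code{TrackSet}.
#' @return A list with \code{nTracks}, \code{nDetections}, and
#'   \code{violations}, a \code{data.frame(track_id, type, detail)} with one
#'   row per violation (\code{type} is \code{"duplicate_frame"} or
#'   \code{"nonmonotone_time"}); empty for a valid set.
#' @export
validateTrackSet <- function(tracks) {
  stopifnot(is(tracks, "TrackSet"))
  d <- detections(tracks)
  out <- list(nTracks = length(unique(d$track_id)), nDetections = nrow(d))
  vio <- data.frame(track_id = character(), type = character(),
                    detail = character(), stringsAsFactors = FALSE)
  if (nrow(d)) {
    for (id in unique(d$track_id)) {
      di <- d[d$track_id == id, , drop = FALSE]
      dup <- unique(di$frame[duplicated(di$frame)])
      for (f in dup)
        vio <- rbind(vio, data.frame(track_id = id, type = "duplicate_frame",
                                     detail = sprintf("frame %d", f)))
      # compare t across strictly increasing frames only
      di <- di[!duplicated(di$frame), , drop = FALSE]
      if (nrow(di) > 1) {
        bad <- which(diff(di$t) < 0)
        for (i in bad)
          vio <- rbind(vio, data.frame(
            track_id = id, type = "nonmonotone_time",
            detail = sprintf("t decreases between frames %d and %d",
                             di$frame[i], di$frame[i + 1])))
      }
    }
  }
  out$violations <- vio
  out$nDuplicateFrame <- sum(vio$type == "duplicate_frame")
  out$nNonmonotoneTime <- sum(vio$type == "nonmonotone_time")
  out
}
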