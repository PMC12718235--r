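#' Instantaneous speeds from consecutive-frame displacements
#'
#' The instantaneous speed of a tracked cell is the Euclidean distance
#' between its coordinates in two *consecutive* frames divided by the time
#' difference between the frames. Detection pairs spanning a frame gap
#' (frame difference > 1) yield no sample: the cell's path in between is
#' unobserved.
#'
#' @param tracks A \code{\link{TrackSet-class}}.
#' @return \code{data.frame} with one row per speed sample: \code{speed}
#'   (µm/s), \code{track_id}, \code{frame_i}, \code{frame_j} (the frame
#'   pair), \code{dt} (s).
#' @examples
#' ts <- TrackSet(data.frame(track_id = "A", frame = 0:1,
#'                           x = c(0, 3), y = c(0, 4)), frameInterval = 0.024)
#' instantaneousSpeeds(ts)$speed  # 5 µm / 0.024 s
#' @export
instantaneousSpeeds <- function(tracks) {
  stopifnot(is(tracks, "TrackSet"))
  d <- detections(tracks)
  empty <- data.frame(speed = numeric(), track_id = character(),
                      frame_i = integer(), frame_j = integer(),
                      dt = numeric(), stringsAsFactors = FALSE)
  if (nrow(d) < 2) return(empty)
  # detections are sorted by (track_id, frame) at construction
  sameTrack <- d$track_id[-1] == d$track_id[-nrow(d)]
  dFrame <- diff(d$frame)
  dt <- diff(d$t)
  pair <- which(sameTrack & dFrame == 1L)
  if (!length(pair)) return(empty)
  badDt <- pair[dt[pair] <= 0]
  if (length(badDt))
    stopf("non-positive time step in track '%s' between frames %d and %d",
          d$track_id[badDt[1]], d$frame[badDt[1]], d$frame[badDt[1] + 1])
  disp <- sqrt(diff(d$x)^2 + diff(d$y)^2)
  data.frame(speed = disp[pair] / dt[pair],
             track_id = d$track_id[pair],
             frame_i = d$frame[pair], frame_j = d$frame[pair + 1],
             dt = dt[pair], stringsAsFactors = FALSE)
}

#' Path length of a trajectory
#'
#' Sum of Euclidean displacements between successive detections, including
#' across frame gaps (path length is a whole-trajectory property, unlike
#' speed). A single-detection track has path length 0.
#'
#' @param traj \code{data.frame} of detections for one track (columns
#'   \code{x}, \code{y}, sorted by frame), or a one-track \code{TrackSet}.
#' @return Path length in µm.
#' @export
trajectoryPathLength <- function(traj) {
  if (is(traj, "TrackSet")) {
    d <- detections(traj)
    if (length(unique(d$track_id)) > 1)
      stopf("trajectoryPathLength expects a single trajectory")
    traj <- d
  }
  if (nrow(traj) < 1) stopf("trajectory has no detections")
  if (nrow(traj) == 1) return(0)
  sum(sqrt(diff(traj$x)^2 + diff(traj$y)^2))
}

#' Filter configuration for speed analysis
#'
#' The three exclusion rules applied before any distribution analysis:
#' trajectories shorter than \code{minDuration} seconds are excluded (cells
#' crossing the focal plane only transiently), trajectories whose path
#' length is below \code{minPathLength} µm are excluded (positional
#' rearrangements inside microcolonies, not dispersal), and individual
#' speed samples above \code{vMax} µm/s are excluded (tracking artifacts).
#' Exclusions use strict inequalities; boundary values are retained.
#'
#' @param vMax Upper speed cutoff, µm/s (default 100).
#' @param minPathLength Minimum trajectory path length, µm (default 5).
#' @param minDuration Minimum trajectory duration, s (default 0.25).
#' @return A validated list of class \code{"FilterConfig"}.
#' @export
filterConfig <- function(vMax = 100, minPathLength = 5, minDuration = 0.25) {
  stopifnot(vMax > 0, minPathLength > 0, minDuration > 0)
  structure(list(vMax = vMax, minPathLength = minPathLength,
                 minDuration = minDuration), class = "FilterConfig")
}

#' Apply trajectory- and sample-level exclusion rules
#'
#' Pipeline order: (1) drop trajectories with duration
#' \code{t_last - t_first < minDuration}; (2) drop trajectories with path
#' length \code{< minPathLength}; (3) compute instantaneous speeds on the
#' survivors; (4) drop individual samples with \code{speed > vMax}. Counts
#' at every stage go into the \code{\link{FilterReport-class}}; the
#' cutoff-excluded percentage uses the post-trajectory-filter sample count
#' as denominator.
#'
#' @param tracks A \code{\link{TrackSet-class}}.
#' @param cfg A \code{\link{filterConfig}}.
#' @return \code{list(samples, report)}: retained speed samples (as from
#'   \code{\link{instantaneousSpeeds}}) and the \code{FilterReport}.
#' @export
applyFilters <- function(tracks, cfg = filterConfig()) {
  stopifnot(is(tracks, "TrackSet"), inherits(cfg, "FilterConfig"))
  d <- detections(tracks)
  ids <- unique(d$track_id)
  nIn <- length(ids)

  if (nIn == 0) {
    rep <- new("FilterReport", nTracksIn = 0L, nTracksRemovedDuration = 0L,
               nTracksRemovedLength = 0L, nSpeedSamplesBeforeCutoff = 0L,
               nSamplesRemovedByCutoff = 0L, cutoffExcludedPercent = 0)
    return(list(samples = instantaneousSpeeds(tracks), report = rep))
  }

  dur <- vapply(split(d$t, d$track_id), function(t) max(t) - min(t), 0)
  shortDur <- names(dur)[dur < cfg$minDuration]
  d1 <- d[!(d$track_id %in% shortDur), , drop = FALSE]

  plen <- vapply(split(seq_len(nrow(d1)), d1$track_id), function(i) {
    trajectoryPathLength(d1[i, , drop = FALSE])
  }, 0)
  shortLen <- names(plen)[plen < cfg$minPathLength]
  d2 <- d1[!(d1$track_id %in% shortLen), , drop = FALSE]

  surv <- TrackSet(d2, frameInterval = frameInterval(tracks),
                   source = tracks@source)
  s <- instantaneousSpeeds(surv)
  nBefore <- nrow(s)
  keep <- s$speed <= cfg$vMax
  nRemoved <- sum(!keep)
  rep <- new("FilterReport",
             nTracksIn = nIn,
             nTracksRemovedDuration = length(shortDur),
             nTracksRemovedLength = length(shortLen),
             nSpeedSamplesBeforeCutoff = as.integer(nBefore),
             nSamplesRemovedByCutoff = as.integer(nRemoved),
             cutoffExcludedPercent =
               if (nBefore == 0) 0 else 100 * nRemoved / nBefore)
  list(samples = s[keep, , drop = FALSE], report = rep)
}

setMethod("show", "FilterReport", function(object) {
  cat("FilterReport\n")
  cat(sprintf("  tracks in: %d (removed: %d by duration, %d by path length)\n",
              object@nTracksIn, object@nTracksRemovedDuration,
              object@nTracksRemovedLength))
  cat(sprintf("  speed samples: %d, of which %d (%.3f%%) above the cutoff\n",
              object@nSpeedSamplesBeforeCutoff,
              object@nSamplesRemovedByCutoff, object@cutoffExcludedPercent))
})

#' Convert a FilterReport to a list (e.g. for JSON serialisation)
#' @param report A \code{FilterReport}.
#' @export
filterReportAsList <- function(report) {
  stopifnot(is(report, "FilterReport"))
  list(nTracksIn = report@nTracksIn,
       nTracksRemovedDuration = report@nTracksRemovedDuration,
       nTracksRemovedLength = report@nTracksRemovedLength,
       nSpeedSamplesBeforeCutoff = report@nSpeedSamplesBeforeCutoff,
       nSamplesRemovedByCutoff = report@nSamplesRemovedByCutoff,
       cutoffExcludedPercent = report@cutoffExcludedPercent)
}

#' Summary statistics of speed samples
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator).
#' Empty input yields an explicit empty summary (n = 0, NA mean and sd);
#' a single sample has a defined mean but no sd.
#'
#' @param samples Numeric vector of speeds, or a samples \code{data.frame}
#'   from \code{\link{instantaneousSpeeds}}.
#' @return \code{list(n, mean, sd, label)} where \code{label} is the
#'   two-decimal \code{"mean ± sd"} rendering.
#' @export
summarizeSpeeds <- function(samples) {
  v <- if (is.data.frame(samples)) samples$speed else samples
  stopifnot(is.numeric(v) || length(v) == 0)
  n <- length(v)
  m <- if (n >= 1) mean(v) else NA_real_
  s <- if (n >= 2) stats::sd(v) else NA_real_
  list(n = n, mean = m, sd = s, label = formatMeanSd(m, s))
}
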