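# Strain-profile presets and the paper-like dataset generator. The presets
# are design targets, not measured constants: roughly two thirds of the
# *filtered* speed measurements below ~5 µm/s, a heavy tail reaching
# ~100 µm/s, a true pre-cutoff maximum of 115 µm/s, microcolony jitter, and
# focal-plane track fragmentation. See the methods vignette for the
# calibration rationale.

strainProfiles <- function() {
  list(
    UWC1 = list(
      proportions = c(microcolony = 0.12, slow = 0.56, fast = 0.32),
      slowLaw = list(meanlog = log(2.00), sdlog = 0.62),
      fastLaw = list(family = "cauchy", location = 6, scale = 14)
    ),
    KT2440 = list(
      proportions = c(microcolony = 0.12, slow = 0.69, fast = 0.19),
      slowLaw = list(meanlog = log(2.15), sdlog = 0.75),
      fastLaw = list(family = "lognormal", meanlog = 3.0, sdlog = 0.9)
    )
  )
}

profileAgentConfig <- function(profile, nAgents) {
  pr <- strainProfiles()[[profile]]
  agentConfig(nAgents = nAgents, proportions = pr$proportions,
              slowLaw = pr$slowLaw, fastLaw = pr$fastLaw,
              vTrueMax = 115, switchRate = 1.0, jitterSd = 0.006)
}

# Trim a single track's detections so that roughly `deficit` filtered speed
# samples remain, while keeping the track long enough to survive the
# duration and path-length filters.
trimTrack <- function(di, deficit, cfg) {
  n <- nrow(di)
  if (n < 3) return(di)
  consec <- c(FALSE, diff(di$frame) == 1L)
  cumSamples <- cumsum(consec)
  m <- match(deficit, cumSamples)
  if (is.na(m)) return(di)
  while (m < n) {
    sub <- di[seq_len(m), , drop = FALSE]
    if ((max(sub$t) - min(sub$t)) >= cfg$minDuration &&
        trajectoryPathLength(sub) >= cfg$minPathLength) break
    m <- m + 1L
  }
  di[seq_len(m), , drop = FALSE]
}

#' Generate a paper-like tracked dataset for one strain profile
#'
#' Simulates bacteria on a seeded hyphal network under one of two strain
#' profiles and the default imaging model, then assembles whole observed
#' tracks (in deterministic order, trimming the last one) until the
#' *filtered* dataset holds approximately \code{nTargetSamples} speed
#' measurements. \code{"UWC1"} uses a Cauchy-tailed fast-state law,
#' \code{"KT2440"} a lognormal-tailed one; both share a lognormal slow
#' state, a microcolony fraction, localisation noise and focal-plane
#' dropout, so the filtered speed distribution is majority-slow with a
#' heavy tail reaching ~100 µm/s.
#'
#' @param profile \code{"UWC1"} or \code{"KT2440"}.
#' @param nTargetSamples Target number of retained speed samples (>= 1000).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @param filter The \code{\link{filterConfig}} the target count refers to.
#' @return List with \code{tracks} (a \code{\link{TrackSet-class}} whose
#'   metadata carries the ground-truth linkage) and \code{profile}.
#' @export
paperLikeDataset <- function(profile = c("UWC1", "KT2440"),
                             nTargetSamples = 6000, seed = 1,
                             filter = filterConfig()) {
  profile <- match.arg(profile)
  stopifnot(nTargetSamples >= 1000)
  durationS <- 4
  nFrames <- round(durationS / 0.024)
  # rough yield per agent: frames x visible x mobile x filter survival
  perAgent <- nFrames * 0.45
  net <- generateNetwork(childSeed(seed, 1L), nBranches = 8, stepUm = 5,
                         boxUm = c(400, 300))
  om <- observationModel()
  collected <- list()
  got <- 0L
  batch <- 0L
  while (got < nTargetSamples && batch < 30L) {
    batch <- batch + 1L
    remaining <- nTargetSamples - got
    nAgents <- max(5L, ceiling(remaining / perAgent * 1.3))
    cfg <- profileAgentConfig(profile, nAgents)
    paths <- simulateAgents(net, cfg, durationS,
                            seed = childSeed(seed, 10L + batch))
    ts <- observeTracks(paths, om, seed = childSeed(seed, 100L + batch))
    d <- detections(ts)
    if (!nrow(d)) next
    d$track_id <- sprintf("b%d_%s", batch, d$track_id)
    # take whole tracks in simulation order (agent, then fragment) until the
    # filtered yield is reached; numeric ordering is locale-independent
    ids <- unique(d$track_id)
    nums <- regmatches(ids, gregexpr("[0-9]+", ids))
    key <- do.call(rbind, lapply(nums, function(v)
      as.integer(v[seq_len(3)])))
    ids <- ids[order(key[, 1], key[, 2], key[, 3])]
    for (id in ids) {
      di <- d[d$track_id == id, , drop = FALSE]
      one <- applyFilters(TrackSet(di, frameInterval = om$frameInterval),
                          filter)
      k <- nrow(one$samples)
      if (k == 0) { collected[[id]] <- di; next }  # filtered out anyway
      if (got + k > nTargetSamples) {
        di <- trimTrack(di, nTargetSamples - got, filter)
        one <- applyFilters(TrackSet(di, frameInterval = om$frameInterval),
                            filter)
        k <- nrow(one$samples)
      }
      collected[[id]] <- di
      got <- got + k
      if (got >= nTargetSamples) break
    }
  }
  d <- do.call(rbind, collected)
  rownames(d) <- NULL
  tracks <- TrackSet(d, frameInterval = om$frameInterval,
                     source = sprintf("paperLikeDataset(%s, seed %d)",
                                      profile, seed),
                     metadata = list(profile = profile, seed = seed,
                                     targetSamples = nTargetSamples))
  list(tracks = tracks, profile = profile)
}

#' Write simulated datasets to disk
#'
#' Emits one minimal-dialect CSV per requested profile plus a JSON sidecar
#' with the generation parameters (profile, seed, target sample count).
#'
#' @param dir Output directory (created if needed).
#' @param profiles Character vector of strain profiles.
#' @param nTargetSamples Target retained samples per profile.
#' @param seed Integer seed.
#' @return Invisibly, the written CSV paths.
#' @export
simulateToFiles <- function(dir, profiles = c("UWC1", "KT2440"),
                            nTargetSamples = 6000, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (i in seq_along(profiles)) {
    pr <- profiles[i]
    ds <- paperLikeDataset(pr, nTargetSamples, seed = childSeed(seed, i))
    csv <- file.path(dir, sprintf("%s_sim_seed%d.csv", tolower(pr), seed))
    writeTracks(ds$tracks, csv, dialect = "minimal")
    sidecar <- file.path(dir, sprintf("%s_sim_seed%d_truth.json",
                                      tolower(pr), seed))
    jsonlite::write_json(
      list(profile = pr, seed = seed, nTargetSamples = nTargetSamples,
           nTracks = nTracks(ds$tracks),
           frameInterval = frameInterval(ds$tracks)),
      sidecar, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, csv)
  }
  invisible(paths)
}
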