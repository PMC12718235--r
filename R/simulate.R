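# Agent-based simulation of bacteria on a hyphal network, plus an imaging
# observation model (frame sampling, localisation noise, focal-plane
# dropout with track relabeling).

#' Agent behaviour configuration
#'
#' Agents occupy one of three behavioural states: \code{microcolony}
#' (jitter around a fixed anchor; positional rearrangement, not dispersal),
#' \code{slow} (dispersal at lognormally distributed per-step speeds) and
#' \code{fast} (dispersal at speeds drawn from a heavy-tailed law, capped
#' at \code{vTrueMax}). State switching is Markovian: with total rate
#' \code{switchRate} per second an agent re-draws its state from
#' \code{proportions}, which therefore is also the stationary state
#' distribution.
#'
#' @param nAgents Number of agents.
#' @param proportions Named numeric \code{c(microcolony=, slow=, fast=)}
#'   summing to 1: initial and stationary state probabilities.
#' @param slowLaw \code{list(meanlog, sdlog)} of the slow-state lognormal
#'   speed law (µm/s).
#' @param fastLaw \code{list(family = "cauchy"|"lognormal"|"constant",
#'   ...)}: \code{location}/\code{scale} for cauchy, \code{meanlog}/
#'   \code{sdlog} for lognormal, \code{value} for constant. Draws are
#'   truncated to (0, \code{vTrueMax}].
#' @param vTrueMax True maximum instantaneous speed, µm/s (default 115,
#'   the observed pre-cutoff maximum this generator emulates).
#' @param switchRate Total state-switching rate, per second.
#' @param jitterSd Microcolony jitter standard deviation, µm.
#' @return Validated list of class \code{"AgentConfig"}.
#' @export
agentConfig <- function(nAgents,
                        proportions = c(microcolony = 0.2, slow = 0.5,
                                        fast = 0.3),
                        slowLaw = list(meanlog = log(1.9), sdlog = 0.65),
                        fastLaw = list(family = "cauchy", location = 14,
                                       scale = 25),
                        vTrueMax = 115, switchRate = 0.05, jitterSd = 0.05) {
  stopifnot(nAgents >= 0, vTrueMax > 0, switchRate >= 0, jitterSd >= 0)
  proportions <- proportions[c("microcolony", "slow", "fast")]
  if (anyNA(proportions) || abs(sum(proportions) - 1) > 1e-9)
    stopf("proportions must be named (microcolony, slow, fast) and sum to 1")
  stopifnot(slowLaw$sdlog >= 0)
  if (!fastLaw$family %in% c("cauchy", "lognormal", "constant"))
    stopf("unsupported fast-law family '%s'", fastLaw$family)
  structure(list(nAgents = as.integer(nAgents), proportions = proportions,
                 slowLaw = slowLaw, fastLaw = fastLaw, vTrueMax = vTrueMax,
                 switchRate = switchRate, jitterSd = jitterSd),
            class = "AgentConfig")
}

#' Imaging observation model
#'
#' @param frameInterval Seconds between recorded frames (default 0.024).
#' @param noiseSd Isotropic Gaussian localisation noise sd, µm.
#' @param dropoutProb Per-frame probability that a visible agent leaves the
#'   focal plane.
#' @param meanOffTime Mean invisible time before reappearing, s.
#' @param relabel If \code{TRUE} (default), an agent reappearing after
#'   dropout gets a new track id: cells cannot be re-identified once they
#'   leave the focal plane.
#' @return Validated list of class \code{"ObservationModel"}.
#' @export
observationModel <- function(frameInterval = 0.024, noiseSd = 0.008,
                             dropoutProb = 0.006, meanOffTime = 0.5,
                             relabel = TRUE) {
  stopifnot(frameInterval > 0, noiseSd >= 0,
            dropoutProb >= 0, dropoutProb <= 1, meanOffTime > 0)
  structure(list(frameInterval = frameInterval, noiseSd = noiseSd,
                 dropoutProb = dropoutProb, meanOffTime = meanOffTime,
                 relabel = relabel), class = "ObservationModel")
}

drawStateSpeed <- function(state, cfg, n = 1) {
  if (state == 2L) {  # slow
    v <- stats::rlnorm(n, cfg$slowLaw$meanlog, cfg$slowLaw$sdlog)
    return(pmin(v, cfg$vTrueMax))
  }
  if (state == 3L) {  # fast
    fl <- cfg$fastLaw
    v <- switch(fl$family,
      constant  = rep(fl$value, n),
      cauchy    = {  # inverse-cdf draw truncated to (0, vTrueMax]
        lo <- stats::pcauchy(0, fl$location, fl$scale)
        hi <- stats::pcauchy(cfg$vTrueMax, fl$location, fl$scale)
        stats::qcauchy(lo + stats::runif(n) * (hi - lo), fl$location, fl$scale)
      },
      lognormal = {
        hi <- stats::plnorm(cfg$vTrueMax, fl$meanlog, fl$sdlog)
        stats::qlnorm(stats::runif(n) * hi, fl$meanlog, fl$sdlog)
      })
    return(v)
  }
  rep(0, n)  # microcolony: no directed movement (jitter handled separately)
}

#' Simulate agents moving on a hyphal network
#'
#' Each mobile agent is assigned a route (origin-to-leaf polyline) and a
#' position along its arc length; per time step it draws a speed from its
#' current state's law and advances along the route (reflecting at the
#' ends, with a small per-step turnaround probability). Microcolony agents
#' jitter isotropically around a fixed anchor on the network. States switch
#' Markovianly (see \code{\link{agentConfig}}). Ground-truth positions,
#' state labels and per-step speeds are all retained.
#'
#' @param net A \code{\link{HyphalNetwork-class}}.
#' @param cfg An \code{\link{agentConfig}}.
#' @param durationS Simulated time, s.
#' @param seed Integer seed; the simulation is deterministic given it.
#' @param dt Simulation time step, s (default 0.024: one camera frame).
#' @return List of class \code{"AgentPaths"}: \code{positions} (list of
#'   (nSteps+1) x 2 matrices), \code{states} (list of integer vectors,
#'   1 = microcolony, 2 = slow, 3 = fast), \code{speeds} (list of true
#'   per-step speeds), \code{dt}, \code{cfg}.
#' @export
simulateAgents <- function(net, cfg, durationS, seed, dt = 0.024) {
  stopifnot(is(net, "HyphalNetwork"), inherits(cfg, "AgentConfig"),
            durationS > 0, dt > 0)
  if (!length(net@segments)) stopf("empty network")
  nSteps <- max(1L, as.integer(round(durationS / dt)))
  routes <- networkRoutes(net)
  params <- lapply(routes, routeParam)
  withSeed(seed, {
    nA <- cfg$nAgents
    positions <- vector("list", nA)
    states <- vector("list", nA)
    speeds <- vector("list", nA)
    pSwitch <- min(cfg$switchRate * dt, 1)
    for (a in seq_len(nA)) {
      ri <- sample.int(length(routes), 1)
      rp <- params[[ri]]
      s <- stats::runif(1, 0, rp$total)
      dir <- sample(c(-1, 1), 1)
      anchor <- rp$at(s)
      st <- sample.int(3L, 1, prob = cfg$proportions)
      pos <- matrix(NA_real_, nSteps + 1, 2)
      stv <- integer(nSteps + 1)
      spd <- numeric(nSteps)
      pos[1, ] <- if (st == 1L)
        anchor + stats::rnorm(2, 0, cfg$jitterSd) else rp$at(s)
      stv[1] <- st
      for (i in seq_len(nSteps)) {
        if (stats::runif(1) < pSwitch)
          st <- sample.int(3L, 1, prob = cfg$proportions)
        if (st == 1L) {
          newPos <- anchor + stats::rnorm(2, 0, cfg$jitterSd)
        } else {
          v <- drawStateSpeed(st, cfg)
          if (stats::runif(1) < 0.01) dir <- -dir
          s2 <- s + dir * v * dt
          if (s2 < 0) { s2 <- -s2; dir <- 1 }
          if (s2 > rp$total) { s2 <- 2 * rp$total - s2; dir <- -1 }
          s2 <- min(max(s2, 0), rp$total)
          s <- s2
          newPos <- rp$at(s)
          anchor <- newPos  # becoming sessile anchors at the current spot
        }
        spd[i] <- sqrt(sum((newPos - pos[i, ])^2)) / dt
        pos[i + 1, ] <- newPos
        stv[i + 1] <- st
      }
      positions[[a]] <- pos
      states[[a]] <- stv
      speeds[[a]] <- spd
    }
    structure(list(positions = positions, states = states, speeds = speeds,
                   dt = dt, cfg = cfg, nSteps = nSteps),
              class = "AgentPaths")
  })
}

#' Observe simulated agents through the imaging model
#'
#' Samples agent positions every \code{frameInterval} (a multiple of the
#' simulation step), adds isotropic Gaussian localisation noise, and applies
#' focal-plane dropout: a visible agent becomes invisible with
#' \code{dropoutProb} per frame and reappears after a geometric off-time
#' with the configured mean. With \code{relabel = TRUE} every reappearance
#' starts a new track, mirroring the impossibility of re-identifying cells.
#' The ground-truth linkage (track id to agent and dominant state) is kept
#' in \code{metadata(tracks)$linkage}.
#'
#' @param paths An \code{"AgentPaths"} object from
#'   \code{\link{simulateAgents}}.
#' @param om An \code{\link{observationModel}}.
#' @param seed Integer seed.
#' @return A \code{\link{TrackSet-class}}.
#' @export
observeTracks <- function(paths, om = observationModel(), seed = NULL) {
  stopifnot(inherits(paths, "AgentPaths"), inherits(om, "ObservationModel"))
  stride <- om$frameInterval / paths$dt
  if (abs(stride - round(stride)) > 1e-9)
    stopf("frameInterval (%g s) must be an integer multiple of the simulation step (%g s)",
          om$frameInterval, paths$dt)
  stride <- as.integer(round(stride))
  frames <- seq(1L, paths$nSteps + 1L, by = stride)
  dt <- om$frameInterval
  pOn <- min(dt / om$meanOffTime, 1)
  withSeed(seed, {
    rows <- vector("list", length(paths$positions))
    linkage <- vector("list", length(paths$positions))
    for (a in seq_along(paths$positions)) {
      pos <- paths$positions[[a]][frames, , drop = FALSE]
      stv <- paths$states[[a]][frames]
      nF <- length(frames)
      visible <- logical(nF)
      vis <- TRUE
      for (i in seq_len(nF)) {
        visible[i] <- vis
        vis <- if (vis) stats::runif(1) >= om$dropoutProb
               else stats::runif(1) < pOn
      }
      if (!any(visible)) next
      runId <- cumsum(c(visible[1], diff(visible) == 1))  # run index
      obsIdx <- which(visible)
      trackOf <- if (om$relabel)
        sprintf("a%d_r%d", a, runId[obsIdx]) else sprintf("a%d", a)
      noise <- matrix(stats::rnorm(2 * length(obsIdx), 0, om$noiseSd),
                      ncol = 2)
      rows[[a]] <- data.frame(
        track_id = trackOf,
        frame = obsIdx - 1L,
        x = pos[obsIdx, 1] + noise[, 1],
        y = pos[obsIdx, 2] + noise[, 2],
        t = (obsIdx - 1L) * dt,
        stringsAsFactors = FALSE)
      linkage[[a]] <- data.frame(
        track_id = unique(trackOf), agent = a,
        stringsAsFactors = FALSE)
    }
    d <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    if (is.null(d))
      d <- data.frame(track_id = character(), frame = integer(),
                      x = numeric(), y = numeric(), t = numeric())
    TrackSet(d, frameInterval = dt, source = "simulateAgents",
             metadata = list(
               linkage = do.call(rbind, linkage[!vapply(linkage, is.null, TRUE)]),
               truth = list(states = paths$states, speeds = paths$speeds,
                            dt = paths$dt)))
  })
}
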