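#' Generate a branching hyphal network
#'
#' Seeded branching random walk emulating a mycelial network that connects
#' an inoculated drop (the origin, left edge) with a target drop (right
#' edge): a trunk grows from origin toward the target with angular noise;
#' side branches attach at random trunk vertices and grow outward with
#' their own angular noise. All coordinates stay inside the bounding box;
#' the network is connected by construction (every branch attaches to the
#' trunk).
#'
#' @param seed Integer seed (mandatory: geometry must be reproducible).
#' @param nBranches Total number of leaf tips, >= 1 (trunk tip plus
#'   \code{nBranches - 1} side branches).
#' @param stepUm Step length of the growth walk, µm.
#' @param boxUm Bounding box \code{c(width, height)}, µm.
#' @return A \code{\link{HyphalNetwork-class}}.
#' @export
generateNetwork <- function(seed, nBranches = 8, stepUm = 5,
                            boxUm = c(400, 300)) {
  stopifnot(nBranches >= 1, stepUm > 0, length(boxUm) == 2)
  if (3 * stepUm > min(boxUm))
    stopf("bounding box %g x %g µm too small for step %g µm",
          boxUm[1], boxUm[2], stepUm)
  withSeed(seed, {
    clamp <- function(p) c(min(max(p[1], 0), boxUm[1]),
                           min(max(p[2], 0), boxUm[2]))
    grow <- function(start, heading0, nSteps, toward = NULL) {
      pts <- matrix(NA_real_, nSteps + 1, 2)
      pts[1, ] <- start
      h <- heading0
      for (i in seq_len(nSteps)) {
        if (!is.null(toward)) {
          aim <- atan2(toward[2] - pts[i, 2], toward[1] - pts[i, 1])
          h <- aim + stats::rnorm(1, 0, 0.25)
        } else {
          h <- h + stats::rnorm(1, 0, 0.2)
        }
        pts[i + 1, ] <- clamp(pts[i, ] + stepUm * c(cos(h), sin(h)))
      }
      pts
    }
    origin <- c(stepUm, boxUm[2] / 2)
    target <- c(boxUm[1] - stepUm, boxUm[2] / 2)
    nTrunk <- ceiling(sqrt(sum((target - origin)^2)) / stepUm) + 2
    trunk <- grow(origin, 0, nTrunk, toward = target)
    segments <- list(trunk)
    adjacency <- data.frame(segment = 1L, parent = 0L, parentVertex = 1L)
    if (nBranches > 1) {
      for (b in seq_len(nBranches - 1)) {
        v <- sample(2:(nTrunk - 1), 1)
        side <- sample(c(-1, 1), 1)
        h0 <- side * stats::runif(1, 0.5, 1.2)
        len <- max(3L, as.integer(round(nTrunk * stats::runif(1, 0.3, 0.6))))
        br <- grow(trunk[v, ], h0, len)
        segments[[length(segments) + 1L]] <- br
        adjacency <- rbind(adjacency, data.frame(
          segment = length(segments), parent = 1L, parentVertex = v))
      }
    }
    new("HyphalNetwork", segments = segments, adjacency = adjacency,
        box = as.numeric(boxUm))
  })
}

setMethod("show", "HyphalNetwork", function(object) {
  cat(sprintf("HyphalNetwork: %d segment(s) in a %g x %g µm box\n",
              length(object@segments), object@box[1], object@box[2]))
})

#' Leaf tips of a hyphal network
#'
#' End points of every segment (each segment terminates in a leaf: branches
#' attach at interior vertices of their parent).
#'
#' @param net A \code{\link{HyphalNetwork-class}}.
#' @return Matrix of tip coordinates, one row per leaf.
#' @export
leafTips <- function(net) {
  stopifnot(is(net, "HyphalNetwork"))
  do.call(rbind, lapply(net@segments, function(s) s[nrow(s), , drop = FALSE]))
}

# Routes from the origin to each leaf: polyline = trunk up to the branch
# attachment vertex, then the branch. Used as 1D rails for agent movement.
networkRoutes <- function(net) {
  segs <- net@segments
  adj <- net@adjacency
  lapply(seq_along(segs), function(i) {
    if (adj$parent[i] == 0L) return(segs[[i]])
    parent <- segs[[adj$parent[i]]]
    rbind(parent[seq_len(adj$parentVertex[i]), , drop = FALSE],
          segs[[i]][-1, , drop = FALSE])
  })
}

# Arc-length parameterisation of a polyline: cumulative lengths plus an
# interpolator arc -> (x, y).
routeParam <- function(poly) {
  seglen <- sqrt(rowSums(diff(poly)^2))
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  list(total = total, at = function(s) {
    s <- min(max(s, 0), total)
    i <- findInterval(s, cum, rightmost.closed = TRUE)
    i <- min(i, length(seglen))
    f <- if (seglen[i] > 0) (s - cum[i]) / seglen[i] else 0
    poly[i, ] + f * (poly[i + 1, ] - poly[i, ])
  })
}
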