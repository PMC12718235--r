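# Regime analysis: intersections of fitted probability density curves,
# slow/fast splits at a threshold speed, and sub-range refits.

#' Intersections of two fitted probability density curves
#'
#' Scans \code{pdf_a - pdf_b} on a regular grid over \code{interval}, then
#' refines every sign change by bisection (\code{uniroot}) to an absolute
#' x-tolerance below 1e-6 µm/s. Tangential contacts (the curves touch
#' without crossing) produce no sign change and are not reported; an
#' interval with no sign change yields an empty set, not an error.
#'
#' @param fitA,fitB \code{\link{FitResult-class}} objects (converged).
#' @param interval \code{c(lo, hi)} search interval, µm/s.
#' @param gridPoints Grid resolution (default 10000).
#' @return An \code{\link{IntersectionSet-class}} with sorted roots.
#' @examples
#' a <- asFitResult(distSpec("lognormal", support = c(0, Inf)),
#'                  c(meanlog = 0, sdlog = 1))
#' b <- asFitResult(distSpec("lognormal", support = c(0, Inf)),
#'                  c(meanlog = 1, sdlog = 1))
#' roots(pdfIntersections(a, b, c(0.1, 10)))  # exp(0.5)
#' @export
pdfIntersections <- function(fitA, fitB, interval, gridPoints = 10000) {
  stopifnot(is(fitA, "FitResult"), is(fitB, "FitResult"))
  if (!fitA@converged || !fitB@converged)
    stopf("both fits must have converged")
  stopifnot(length(interval) == 2, interval[1] < interval[2])
  g <- seq(interval[1], interval[2], length.out = gridPoints)
  d <- function(x) speedPdf(fitA, x) - speedPdf(fitB, x)
  dg <- d(g)
  sg <- sign(dg)
  # a strict sign change between consecutive non-zero grid values
  idx <- which(sg[-length(sg)] * sg[-1] < 0)
  rts <- vapply(idx, function(i) {
    stats::uniroot(d, lower = g[i], upper = g[i + 1], tol = 1e-10)$root
  }, 0)
  # grid points that are exact zeros flanked by opposite signs
  zero <- which(sg == 0 & dg == 0)
  zero <- zero[zero > 1 & zero < length(g)]
  zero <- zero[sg[zero - 1] * sg[zero + 1] < 0]
  rts <- sort(unique(c(rts, g[zero])))
  new("IntersectionSet", roots = rts, interval = as.numeric(interval),
      gridPoints = as.integer(gridPoints))
}

#' @rdname IntersectionSet-class
#' @export
setMethod("roots", "IntersectionSet", function(x) x@roots)

setMethod("show", "IntersectionSet", function(object) {
  cat(sprintf("IntersectionSet on (%g, %g): %d root(s)%s\n",
              object@interval[1], object@interval[2], length(object@roots),
              if (length(object@roots))
                paste0(" at ", paste(sprintf("%.4f", object@roots),
                                     collapse = ", "), " µm/s")
              else ""))
})

#' Split speed samples into slow and fast regimes
#'
#' Slow regime: \code{speed < threshold}; fast regime:
#' \code{speed >= threshold} (the boundary convention is fixed; ties at the
#' threshold have measure zero for continuous speeds). Per population and
#' regime the count, mean and sample sd are computed, along with the slow
#' fraction in percent.
#'
#' @param samplesByPopulation Named list: population -> numeric speeds.
#' @param threshold Split speed, µm/s.
#' @return A \code{\link{RegimeSplit-class}}.
#' @export
splitAt <- function(samplesByPopulation, threshold) {
  stopifnot(is.list(samplesByPopulation), length(samplesByPopulation) >= 1,
            is.finite(threshold))
  if (is.null(names(samplesByPopulation)))
    names(samplesByPopulation) <- paste0("pop", seq_along(samplesByPopulation))
  slow <- lapply(samplesByPopulation, function(v) v[v < threshold])
  fast <- lapply(samplesByPopulation, function(v) v[v >= threshold])
  rows <- list()
  for (popn in names(samplesByPopulation)) {
    n <- length(samplesByPopulation[[popn]])
    for (regime in c("slow", "fast")) {
      v <- if (regime == "slow") slow[[popn]] else fast[[popn]]
      s <- summarizeSpeeds(v)
      rows[[length(rows) + 1L]] <- data.frame(
        population = popn, regime = regime, n = s$n,
        mean = s$mean, sd = s$sd, label = s$label,
        fraction = if (n == 0) NA_real_ else 100 * s$n / n,
        stringsAsFactors = FALSE)
    }
  }
  new("RegimeSplit", threshold = threshold, slow = slow, fast = fast,
      summary = do.call(rbind, rows))
}

#' @rdname RegimeSplit-class
#' @export
setMethod("slowFraction", "RegimeSplit", function(x) {
  s <- x@summary[x@summary$regime == "slow", ]
  stats::setNames(s$fraction, s$population)
})

#' @rdname RegimeSplit-class
#' @export
setMethod("regimeSummary", "RegimeSplit", function(x) x@summary)

setMethod("show", "RegimeSplit", function(object) {
  cat(sprintf("RegimeSplit at %.4g µm/s\n", object@threshold))
  print(object@summary, row.names = FALSE, digits = 4)
})

#' Refit candidate models on slow and fast sub-ranges
#'
#' Robustness check for the mixed character of a speed distribution: the
#' pooled samples are split at \code{cut} (default 60 µm/s), each subset is
#' refitted over its own truncated support ((0, cut] for the slow subset,
#' [cut, vMax] for the fast one), and the resulting rankings are inspected
#' for whether the top three fits of each subset are still mixtures.
#'
#' @param samples Numeric speeds.
#' @param cut Sub-split speed, µm/s (default 60).
#' @param vMax Upper support bound.
#' @param pool Optional custom spec pool *generator* inputs are not needed:
#'   the default pool is rebuilt on each sub-support.
#' @param seed Optional integer seed.
#' @param nRestarts Restarts per fit.
#' @param criterion Ranking criterion.
#' @return List with \code{slow} and \code{fast} (\code{ModelRanking} or
#'   \code{NULL} when a subset is too small to fit, in which case the
#'   corresponding \code{*Flagged} entry is \code{TRUE}) and
#'   \code{mixtureDominated}: are the top-3 of every fitted subset all
#'   mixtures?
#' @export
subrangeRefit <- function(samples, cut = 60, vMax = 100, pool = NULL,
                          seed = NULL, nRestarts = 20,
                          criterion = "BIC") {
  stopifnot(is.numeric(samples), cut > 0, cut < vMax)
  lowSub <- samples[samples < cut]
  highSub <- samples[samples >= cut]
  fitSub <- function(v, sup, k) {
    if (length(v) < 10) return(NULL)
    p <- if (is.null(pool)) defaultSpecPool(sup[2], lo = sup[1]) else pool
    tryCatch(rankModels(v, pool = p, criterion = criterion,
                        seed = childSeed(seed, k), nRestarts = nRestarts),
             error = function(e) NULL)
  }
  rkSlow <- fitSub(lowSub, c(0, cut), 1L)
  rkFast <- fitSub(highSub, c(cut, vMax), 2L)
  top3Mixed <- function(rk) {
    if (is.null(rk)) return(NA)
    tb <- rankingTable(rk)
    all(tb$mixture[seq_len(min(3, nrow(tb)))])
  }
  ms <- top3Mixed(rkSlow); mf <- top3Mixed(rkFast)
  list(slow = rkSlow, fast = rkFast,
       slowFlagged = is.null(rkSlow), fastFlagged = is.null(rkFast),
       slowTop3Mixture = ms, fastTop3Mixture = mf,
       mixtureDominated = isTRUE(ms) && isTRUE(mf))
}
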