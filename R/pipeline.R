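# End-to-end orchestration: read -> filter -> pool -> fit & rank ->
# intersect -> split -> compare, with a serialisable run report.

#' Run the full dispersal-speed analysis pipeline
#'
#' For each population (a named list entry holding one or more
#' \code{TrackSet}s or CSV file paths): apply the exclusion filters per
#' file, pool the retained speed samples, and rank the candidate
#' distribution pool. With exactly two populations, the two best fits'
#' probability density curves are intersected inside \code{bracket}; the
#' smallest root is the slow/fast threshold (all roots are kept in the
#' report), the pooled samples are split there, per-file and combined
#' regime summaries are computed, the full distributions are compared with
#' the Kolmogorov-Smirnov test and the per-regime speeds with
#' Kruskal-Wallis tests, and each population is refitted on the slow/fast
#' sub-ranges at \code{subCut} as a robustness check.
#'
#' @param populations Named list; each element is a \code{TrackSet}, a list
#'   of \code{TrackSet}s, or a character vector of CSV paths.
#' @param filter A \code{\link{filterConfig}}.
#' @param criterion Ranking criterion (default \code{"BIC"}).
#' @param bracket Interval in which the regime threshold is sought
#'   (default \code{c(1, 10)} µm/s, the zoomed-in low-speed view).
#' @param subCut Sub-split speed for the robustness refit (default 60 µm/s);
#'   \code{NA} skips it.
#' @param seed Integer seed for the (seeded) fitting restarts.
#' @param nRestarts Restarts per fit.
#' @param dialect,calibration Passed to \code{\link{readTracks}} for file
#'   inputs.
#' @param frameInterval Frame interval for file inputs, s.
#' @return A list of class \code{"RunReport"}.
#' @export
runSpeedPipeline <- function(populations, filter = filterConfig(),
                             criterion = "BIC", bracket = c(1, 10),
                             subCut = 60, seed = 1, nRestarts = 20,
                             dialect = "minimal", calibration = 1,
                             frameInterval = 0.024) {
  stopifnot(is.list(populations), length(populations) >= 1,
            !is.null(names(populations)))
  asTrackSets <- function(el) {
    if (is(el, "TrackSet")) return(list(el))
    if (is.character(el))
      return(lapply(el, readTracks, dialect = dialect,
                    calibration = calibration,
                    frameInterval = frameInterval))
    if (is.list(el) && all(vapply(el, is, TRUE, "TrackSet"))) return(el)
    stopf("each population must be TrackSet(s) or file path(s)")
  }

  perPop <- list()
  for (popn in names(populations)) {
    sets <- asTrackSets(populations[[popn]])
    files <- lapply(seq_along(sets), function(i) {
      fl <- applyFilters(sets[[i]], filter)
      src <- sets[[i]]@source
      list(name = if (nzchar(src)) src else sprintf("%s_%d", popn, i),
           samples = fl$samples, report = fl$report,
           summary = summarizeSpeeds(fl$samples))
    })
    pooledDf <- do.call(rbind, lapply(files, `[[`, "samples"))
    pooled <- pooledDf$speed
    nZero <- sum(pooled <= 0)
    if (nZero) pooled <- pooled[pooled > 0]  # zero-displacement samples
    perPop[[popn]] <- list(files = files, pooled = pooled,
                           nZeroDropped = nZero,
                           summary = summarizeSpeeds(pooled))
  }

  empty <- names(perPop)[vapply(perPop, function(p) length(p$pooled) == 0, TRUE)]
  report <- list(populations = perPop, filter = unclass(filter),
                 criterion = criterion, bracket = bracket, subCut = subCut,
                 seed = seed, nRestarts = nRestarts,
                 version = as.character(utils::packageVersion("hyphalTracks")),
                 emptyPopulations = empty)
  class(report) <- "RunReport"
  if (length(empty)) {
    warnf("population(s) with zero retained samples: %s",
          paste(empty, collapse = ", "))
    report$status <- "empty-population"
    return(report)
  }

  rankings <- list()
  for (i in seq_along(perPop)) {
    popn <- names(perPop)[i]
    rankings[[popn]] <- rankModels(perPop[[popn]]$pooled,
                                   criterion = criterion,
                                   seed = childSeed(seed, i),
                                   nRestarts = nRestarts,
                                   vMax = filter$vMax)
  }
  report$rankings <- rankings

  if (length(perPop) == 2) {
    bestA <- topFit(rankings[[1]])
    bestB <- topFit(rankings[[2]])
    isect <- pdfIntersections(bestA, bestB, bracket)
    report$intersections <- isect
    if (length(roots(isect))) {
      threshold <- min(roots(isect))
      report$threshold <- threshold
      samplesByPop <- lapply(perPop, `[[`, "pooled")
      report$regimes <- splitAt(samplesByPop, threshold)
      # per-file regime summaries for the rendered summary table
      for (popn in names(perPop)) {
        for (j in seq_along(perPop[[popn]]$files)) {
          v <- perPop[[popn]]$files[[j]]$samples$speed
          report$populations[[popn]]$files[[j]]$slowSummary <-
            summarizeSpeeds(v[v < threshold])
          report$populations[[popn]]$files[[j]]$fastSummary <-
            summarizeSpeeds(v[v >= threshold])
        }
      }
      slowGroups <- report$regimes@slow
      fastGroups <- report$regimes@fast
      report$tests <- list(
        ksFull = ksTwoSample(samplesByPop[[1]], samplesByPop[[2]],
                             method = "asymptotic"),
        kwSlow = if (all(lengths(slowGroups) >= 1))
          kruskalWallisTest(slowGroups) else NULL,
        kwFast = if (all(lengths(fastGroups) >= 1))
          kruskalWallisTest(fastGroups) else NULL)
    } else {
      warnf("no PDF intersection inside the bracket (%g, %g)",
            bracket[1], bracket[2])
      report$threshold <- NA_real_
    }
    if (is.finite(subCut)) {
      report$subrange <- lapply(seq_along(perPop), function(i) {
        subrangeRefit(perPop[[i]]$pooled, cut = subCut, vMax = filter$vMax,
                      seed = childSeed(seed, 100L + i),
                      nRestarts = nRestarts)
      })
      names(report$subrange) <- names(perPop)
    }
  } else if (length(perPop) != 2) {
    warnf("between-population sections need exactly 2 populations (got %d)",
          length(perPop))
  }
  report$status <- "ok"
  report
}

#' Per-file and combined summary table of a pipeline run
#'
#' One row per input file plus a combined row per population: number of
#' independent speed measurements, slow-regime and fast-regime
#' \code{"mean ± sd"} (two decimals). Combined rows are recomputed from the
#' pooled samples, not averaged from per-file rows. Empty regimes render as
#' \code{"—"}.
#'
#' @param report A \code{"RunReport"} from \code{\link{runSpeedPipeline}}.
#' @return A \code{data.frame}.
#' @export
reportTable <- function(report) {
  stopifnot(inherits(report, "RunReport"))
  rows <- list()
  thr <- report$threshold
  for (popn in names(report$populations)) {
    pop <- report$populations[[popn]]
    for (f in pop$files) {
      slow <- if (!is.null(f$slowSummary)) f$slowSummary$label else "—"
      fast <- if (!is.null(f$fastSummary)) f$fastSummary$label else "—"
      rows[[length(rows) + 1L]] <- data.frame(
        population = popn, file = basename(f$name), n = f$summary$n,
        slow = slow, fast = fast, stringsAsFactors = FALSE)
    }
    v <- pop$pooled
    slow <- if (is.null(thr) || !is.finite(thr)) "—" else
      summarizeSpeeds(v[v < thr])$label
    fast <- if (is.null(thr) || !is.finite(thr)) "—" else
      summarizeSpeeds(v[v >= thr])$label
    rows[[length(rows) + 1L]] <- data.frame(
      population = popn, file = sprintf("Combined data for %s", popn),
      n = length(v), slow = slow, fast = fast, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Serialise a run report to JSON
#'
#' Writes the machine-readable parts of the report (filter settings and
#' reports, summaries, rankings, threshold, regime table, test results,
#' config, package version) as JSON. Two runs with identical inputs and
#' config produce byte-identical files.
#'
#' @param report A \code{"RunReport"}.
#' @param path Output JSON path.
#' @export
writeRunReport <- function(report, path) {
  stopifnot(inherits(report, "RunReport"))
  ser <- list(
    version = report$version, status = report$status,
    filter = report$filter, criterion = report$criterion,
    bracket = report$bracket, subCut = report$subCut, seed = report$seed,
    threshold = report$threshold,
    populations = lapply(report$populations, function(pop) list(
      n = pop$summary$n, mean = pop$summary$mean, sd = pop$summary$sd,
      nZeroDropped = pop$nZeroDropped,
      files = lapply(pop$files, function(f) list(
        name = f$name, n = f$summary$n,
        filterReport = filterReportAsList(f$report))))),
    rankings = lapply(report$rankings, function(r)
      rankingTable(r)[, c("rank", "family", "mixture", "params", "logL",
                          "AIC", "BIC", "HQC")]),
    intersectionRoots = if (!is.null(report$intersections))
      roots(report$intersections) else NULL,
    regimes = if (!is.null(report$regimes))
      regimeSummary(report$regimes) else NULL,
    tests = if (!is.null(report$tests)) lapply(
      Filter(Negate(is.null), report$tests), function(tst) list(
        statistic = unname(tst$statistic), p = tst$p.value,
        method = tst$method)) else NULL)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @export
print.RunReport <- function(x, ...) {
  cat("hyphalTracks run report\n")
  cat(sprintf("  status: %s; criterion: %s; seed: %d\n",
              x$status, x$criterion, x$seed))
  if (!is.null(x$threshold) && is.finite(x$threshold))
    cat(sprintf("  slow/fast threshold: %.4f µm/s (roots: %s)\n",
                x$threshold,
                paste(sprintf("%.4f", roots(x$intersections)),
                      collapse = ", ")))
  for (popn in names(x$rankings)) {
    tb <- rankingTable(x$rankings[[popn]])
    cat(sprintf("  %s: best fit %s%s (BIC %.1f), n = %d\n", popn,
                tb$family[1], if (tb$mixture[1]) "+uniform" else "",
                tb$BIC[1], x$populations[[popn]]$summary$n))
  }
  if (!is.null(x$regimes)) print(regimeSummary(x$regimes), row.names = FALSE,
                                 digits = 4)
  invisible(x)
}
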