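# Maximum-likelihood fitting of truncated families and uniform-background
# mixtures, with multi-start bounded optimisation on transformed parameters,
# plus information-criterion model ranking.

# unconstrained transform <-> natural parameters ---------------------------

thetaFromParams <- function(spec, p) {
  th <- switch(spec@family,
    lognormal   = c(p[["meanlog"]], log(p[["sdlog"]])),
    cauchy      = c(p[["location"]], log(p[["scale"]])),
    normal      = c(p[["mean"]], log(p[["sd"]])),
    gamma       = c(log(p[["shape"]]), log(p[["rate"]])),
    weibull     = c(log(p[["shape"]]), log(p[["scale"]])),
    exponential = log(p[["rate"]]))
  if (spec@mixture)
    th <- c(th, stats::qlogis(min(max(p[["w"]], 1e-4), 1 - 1e-4)))
  th
}

paramsFromTheta <- function(spec, th) {
  p <- switch(spec@family,
    lognormal   = c(meanlog = th[1], sdlog = exp(th[2])),
    cauchy      = c(location = th[1], scale = exp(th[2])),
    normal      = c(mean = th[1], sd = exp(th[2])),
    gamma       = c(shape = exp(th[1]), rate = exp(th[2])),
    weibull     = c(shape = exp(th[1]), scale = exp(th[2])),
    exponential = c(rate = exp(th[1])))
  if (spec@mixture) p <- c(p, w = stats::plogis(th[length(th)]))
  p
}

# moment-style starting values restricted to the support
initParams <- function(family, x, support) {
  m <- mean(x); v <- stats::var(x)
  lo <- support[1]
  switch(family,
    lognormal   = c(meanlog = mean(log(x)), sdlog = max(stats::sd(log(x)), 1e-3)),
    cauchy      = c(location = stats::median(x),
                    scale = max(stats::IQR(x) / 2, 1e-3)),
    normal      = c(mean = m, sd = max(sqrt(v), 1e-3)),
    gamma       = c(shape = max(m^2 / max(v, 1e-12), 1e-3),
                    rate = max(m / max(v, 1e-12), 1e-6)),
    weibull     = {
      cv <- sqrt(v) / m
      sh <- max(cv^(-1.086), 0.1)
      c(shape = sh, scale = max(m / gamma(1 + 1 / sh), 1e-3))
    },
    exponential = c(rate = 1 / max(m - lo, 1e-6)))
}

mixtureNll <- function(spec, x) {
  sup <- spec@support
  bg <- 1 / (sup[2] - sup[1])
  family <- spec@family
  function(th) {
    if (any(!is.finite(th))) return(Inf)
    p <- paramsFromTheta(spec, th)
    Z <- tryCatch(truncMass(family, p, sup), error = function(e) NA_real_)
    if (!is.finite(Z) || Z < 1e-12) return(Inf)
    f <- baseDens(family, x, p) / Z
    dens <- if (spec@mixture) p[["w"]] * f + (1 - p[["w"]]) * bg else f
    if (any(!is.finite(dens)) || any(dens <= 0)) return(Inf)
    -sum(log(dens))
  }
}

#' Fit a candidate model to speed samples by maximum likelihood
#'
#' Direct numerical maximisation of the truncated (mixture) log-likelihood
#' on an unconstrained parameter transform (log scales, logit weight), with
#' multiple restarts: a deterministic moment-based start, for mixtures a
#' peak-subset start and a start at the nested single-family solution, and
#' seeded random perturbations. The best restart is returned. For mixtures
#' the boundary weights \eqn{w = 0} (pure uniform) and \eqn{w = 1} (pure
#' component) are evaluated exactly; if one of them attains the highest
#' likelihood the fit is flagged \code{boundary} and the nested single-family
#' fit is attached. This guarantees that a mixture never scores a lower
#' log-likelihood than its nested single family on the same data.
#'
#' @param samples Numeric speeds, all inside the model's support; n >= 10.
#' @param spec A \code{\link{DistSpec-class}}.
#' @param nRestarts Number of optimisation starts (default 20). The first
#'   starts are deterministic; the remainder are seeded random
#'   perturbations, so results are reproducible given \code{seed}.
#' @param seed Optional integer seed.
#' @return A \code{\link{FitResult-class}}; if no restart converged the
#'   result carries \code{converged = FALSE} rather than raising an error.
#' @export
fitMLE <- function(samples, spec, nRestarts = 20, seed = NULL) {
  stopifnot(is(spec, "DistSpec"), is.numeric(samples))
  x <- as.numeric(samples)
  n <- length(x)
  if (n < 10) stopf("need at least 10 samples to fit (got %d)", n)
  if (!all(inSupport(x, spec@support)))
    stopf("%d sample(s) outside the support (%g, %g]",
          sum(!inSupport(x, spec@support)), spec@support[1], spec@support[2])
  sup <- spec@support

  if (spec@family == "uniform")
    return(new("FitResult", spec = spec, params = numeric(),
               logLik = -n * log(sup[2] - sup[1]), n = as.integer(n),
               converged = TRUE, nRestartsUsed = 0L))

  nll <- mixtureNll(spec, x)
  singleSpec <- distSpec(spec@family, mixture = FALSE, support = sup)

  starts <- list()
  base <- initParams(spec@family, x, sup)
  if (spec@mixture) {
    # slow-peak subset start: component on the lower bulk, w from its share
    bulk <- x[x <= stats::quantile(x, 0.7)]
    pkInit <- if (length(bulk) >= 10) initParams(spec@family, bulk, sup) else base
    starts <- list(c(base, w = 0.7), c(pkInit, w = 0.7), c(pkInit, w = 0.5))
  } else {
    starts <- list(base)
  }

  singleFit <- NULL
  if (spec@mixture) {
    singleFit <- fitMLE(x, singleSpec,
                        nRestarts = min(nRestarts, 5L),
                        seed = childSeed(seed, 777L))
    if (singleFit@converged)
      starts <- c(starts, list(c(singleFit@params, w = 0.98)))
  }

  thetaStarts <- lapply(starts, function(p) thetaFromParams(spec, p))
  nRandom <- max(0L, nRestarts - length(thetaStarts))
  if (nRandom > 0) {
    thetaStarts <- c(thetaStarts, withSeed(seed, {
      lapply(seq_len(nRandom), function(i) {
        th <- thetaStarts[[1]] + stats::rnorm(length(thetaStarts[[1]]), 0, 0.8)
        if (spec@mixture)
          th[length(th)] <- stats::qlogis(stats::runif(1, 0.05, 0.95))
        th
      })
    }))
  }

  best <- NULL; bestVal <- Inf; used <- 0L
  for (th0 in thetaStarts) {
    used <- used + 1L
    opt <- tryCatch(
      suppressWarnings(
        stats::optim(th0, nll, method = "BFGS",
                     control = list(maxit = 300, reltol = 1e-10))),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (opt$value < bestVal) { bestVal <- opt$value; best <- opt }
  }

  if (is.null(best)) {
    return(new("FitResult", spec = spec,
               params = if (spec@mixture) c(base, w = 0.5) else base,
               logLik = NA_real_, n = as.integer(n), converged = FALSE,
               nRestartsUsed = used))
  }

  params <- paramsFromTheta(spec, best$par)
  logLik <- -bestVal
  boundary <- FALSE
  nested <- NULL

  if (spec@mixture) {
    # exact boundary candidates: w = 1 (pure component), w = 0 (pure uniform)
    candidates <- list()
    if (!is.null(singleFit) && singleFit@converged)
      candidates$one <- list(params = c(singleFit@params, w = 1),
                             logLik = singleFit@logLik)
    candidates$zero <- list(params = c(base, w = 0),
                            logLik = -n * log(sup[2] - sup[1]))
    for (cand in candidates) {
      if (cand$logLik > logLik) {
        params <- cand$params
        logLik <- cand$logLik
        boundary <- TRUE
      }
    }
    if (!boundary && (params[["w"]] < 1e-4 || params[["w"]] > 1 - 1e-4))
      boundary <- TRUE
    if (boundary) nested <- singleFit
  }

  new("FitResult", spec = spec, params = params, logLik = logLik,
      n = as.integer(n), converged = TRUE, nRestartsUsed = used,
      boundary = boundary, nested = nested)
}

#' Log-likelihood and information criteria of a fit
#'
#' \code{AIC = 2k - 2 logL}, \code{BIC = k ln(n) - 2 logL},
#' \code{HQC = 2k ln(ln n) - 2 logL}, with \code{k} the number of free
#' parameters (the mixture weight counts; fixed uniform bounds do not).
#' Lower is better for all three.
#'
#' @param fit A converged \code{\link{FitResult-class}} with n >= 3
#'   (\code{ln ln n} is undefined below e).
#' @return Named numeric \code{c(logL, AIC, BIC, HQC)}.
#' @export
informationCriteria <- function(fit) {
  stopifnot(is(fit, "FitResult"))
  if (!fit@converged || !is.finite(fit@logLik))
    stopf("information criteria need a converged fit")
  n <- fit@n
  if (n < 3) stopf("n = %d too small: ln(ln n) undefined for n <= e", n)
  k <- fit@spec@nParams
  ll <- fit@logLik
  c(logL = ll, AIC = 2 * k - 2 * ll, BIC = k * log(n) - 2 * ll,
    HQC = 2 * k * log(log(n)) - 2 * ll)
}

#' Fit and rank a pool of candidate models
#'
#' Fits every spec in the pool to the same samples and sorts by the chosen
#' criterion (ascending for AIC/BIC/HQC, descending for log-likelihood).
#' Results are deterministic given \code{seed} and invariant to the order
#' of the samples.
#'
#' @param samples Numeric speeds.
#' @param pool List of \code{\link{DistSpec-class}} (default:
#'   \code{\link{defaultSpecPool}} on (0, vMax]).
#' @param criterion \code{"BIC"} (default), \code{"AIC"}, \code{"HQC"} or
#'   \code{"logL"}.
#' @param seed Optional integer seed.
#' @param nRestarts Restarts per fit (see \code{\link{fitMLE}}).
#' @param topN Keep at most this many rows (default 10).
#' @param vMax Support used for the default pool.
#' @return A \code{\link{ModelRanking-class}}.
#' @export
rankModels <- function(samples, pool = NULL,
                       criterion = c("BIC", "AIC", "HQC", "logL"),
                       seed = NULL, nRestarts = 20, topN = 10, vMax = 100) {
  criterion <- match.arg(criterion)
  if (is.null(pool)) pool <- defaultSpecPool(vMax)
  stopifnot(length(pool) >= 1)
  fits <- vector("list", length(pool))
  fails <- character()
  for (i in seq_along(pool)) {
    f <- tryCatch(fitMLE(samples, pool[[i]], nRestarts = nRestarts,
                         seed = childSeed(seed, i)),
                  error = function(e) e)
    if (inherits(f, "error") || !f@converged) {
      lbl <- sprintf("%s%s", pool[[i]]@family,
                     if (pool[[i]]@mixture) "+uniform" else "")
      msg <- if (inherits(f, "error")) conditionMessage(f) else "did not converge"
      fails <- c(fails, sprintf("%s: %s", lbl, msg))
      fits[[i]] <- NULL
    } else fits[[i]] <- f
  }
  ok <- !vapply(fits, is.null, TRUE)
  if (!any(ok))
    stopf("all candidate fits failed:\n  %s", paste(fails, collapse = "\n  "))
  fits <- fits[ok]

  rows <- lapply(fits, function(f) {
    ic <- informationCriteria(f)
    data.frame(
      family = f@spec@family, mixture = f@spec@mixture,
      nParams = f@spec@nParams,
      params = paste(sprintf("%s=%.4g", names(f@params), f@params),
                     collapse = "; "),
      logL = ic[["logL"]], AIC = ic[["AIC"]], BIC = ic[["BIC"]],
      HQC = ic[["HQC"]], converged = f@converged, boundary = f@boundary,
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ord <- if (criterion == "logL") order(-tab$logL) else order(tab[[criterion]])
  tab <- tab[ord, , drop = FALSE]
  fits <- fits[ord]
  keep <- seq_len(min(topN, nrow(tab)))
  tab <- tab[keep, , drop = FALSE]
  fits <- fits[keep]
  tab <- cbind(rank = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  new("ModelRanking", table = tab, fits = fits, criterion = criterion)
}

#' @rdname ModelRanking-class
#' @export
setMethod("rankingTable", "ModelRanking", function(x) x@table)

#' @rdname ModelRanking-class
#' @export
setMethod("topFit", "ModelRanking", function(x, i = 1L) x@fits[[i]])

setMethod("show", "ModelRanking", function(object) {
  cat(sprintf("ModelRanking (%d fits, sorted by %s)\n",
              nrow(object@table), object@criterion))
  print(object@table[, c("rank", "family", "mixture", "logL", "AIC", "BIC",
                         "HQC")], row.names = FALSE, digits = 6)
})
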