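# Candidate distribution families, truncated to a speed support, plus
# two-component mixtures with a uniform background. Parameterisations follow
# the base R d/p/q functions.

familyParamNames <- function(family) {
  switch(family,
    lognormal   = c("meanlog", "sdlog"),
    cauchy      = c("location", "scale"),
    normal      = c("mean", "sd"),
    gamma       = c("shape", "rate"),
    weibull     = c("shape", "scale"),
    exponential = "rate",
    uniform     = character(),
    stopf("unknown family '%s'", family))
}

baseDens <- function(family, x, p, log = FALSE) {
  switch(family,
    lognormal   = stats::dlnorm(x, p[["meanlog"]], p[["sdlog"]], log = log),
    cauchy      = stats::dcauchy(x, p[["location"]], p[["scale"]], log = log),
    normal      = stats::dnorm(x, p[["mean"]], p[["sd"]], log = log),
    gamma       = stats::dgamma(x, shape = p[["shape"]], rate = p[["rate"]],
                                log = log),
    weibull     = stats::dweibull(x, p[["shape"]], p[["scale"]], log = log),
    exponential = stats::dexp(x, p[["rate"]], log = log),
    uniform     = stopf("uniform density is handled by its support"))
}

baseCdf <- function(family, q, p) {
  switch(family,
    lognormal   = stats::plnorm(q, p[["meanlog"]], p[["sdlog"]]),
    cauchy      = stats::pcauchy(q, p[["location"]], p[["scale"]]),
    normal      = stats::pnorm(q, p[["mean"]], p[["sd"]]),
    gamma       = stats::pgamma(q, shape = p[["shape"]], rate = p[["rate"]]),
    weibull     = stats::pweibull(q, p[["shape"]], p[["scale"]]),
    exponential = stats::pexp(q, p[["rate"]]),
    uniform     = stopf("uniform cdf is handled by its support"))
}

baseQuantile <- function(family, pr, p) {
  switch(family,
    lognormal   = stats::qlnorm(pr, p[["meanlog"]], p[["sdlog"]]),
    cauchy      = stats::qcauchy(pr, p[["location"]], p[["scale"]]),
    normal      = stats::qnorm(pr, p[["mean"]], p[["sd"]]),
    gamma       = stats::qgamma(pr, shape = p[["shape"]], rate = p[["rate"]]),
    weibull     = stats::qweibull(pr, p[["shape"]], p[["scale"]]),
    exponential = stats::qexp(pr, p[["rate"]]),
    uniform     = stopf("uniform quantile is handled by its support"))
}

# Probability mass of the untruncated family inside (lo, hi]
truncMass <- function(family, p, support) {
  hi <- if (is.finite(support[2])) baseCdf(family, support[2], p) else 1
  hi - baseCdf(family, support[1], p)
}

# x inside support? Half-open (lo, hi]; a positive lo (sub-range supports)
# is treated as closed at lo so threshold-valued samples stay in range.
inSupport <- function(x, support) {
  loOk <- if (support[1] > 0) x >= support[1] else x > support[1]
  loOk & x <= support[2]
}

#' Specify a candidate speed-distribution model
#'
#' @param family One of \code{"lognormal"}, \code{"cauchy"}, \code{"normal"},
#'   \code{"gamma"}, \code{"weibull"}, \code{"exponential"},
#'   \code{"uniform"}.
#' @param mixture If \code{TRUE}, a two-component mixture of the (truncated)
#'   family with a uniform background over the full support.
#' @param support \code{c(lo, hi)} in µm/s; component densities are
#'   truncated and renormalised to this interval; the uniform background has
#'   fixed bounds equal to it.
#' @return A \code{\link{DistSpec-class}}.
#' @examples
#' distSpec("lognormal", mixture = TRUE)          # lognormal + uniform
#' distSpec("cauchy", support = c(0, 100))        # truncated Cauchy
#' @export
distSpec <- function(family, mixture = FALSE, support = c(0, 100)) {
  k <- length(familyParamNames(family)) + as.integer(mixture)
  new("DistSpec", family = family, mixture = mixture,
      support = as.numeric(support), nParams = as.integer(k))
}

setMethod("show", "DistSpec", function(object) {
  cat(sprintf("DistSpec: %s%s on (%g, %g], %d free parameter(s)\n",
              object@family, if (object@mixture) " + uniform" else "",
              object@support[1], object@support[2], object@nParams))
})

#' Default candidate pool
#'
#' Seven single families (lognormal, cauchy, normal, gamma, weibull,
#' exponential, uniform — all truncated to the support) plus the six
#' mixtures of each non-uniform family with a uniform background. The two
#' mixtures reported as best fits for the two strains (lognormal+uniform
#' and cauchy+uniform) are always members.
#'
#' @param vMax Upper support bound, µm/s.
#' @param lo Lower support bound (default 0).
#' @return List of \code{\link{DistSpec-class}}.
#' @export
defaultSpecPool <- function(vMax = 100, lo = 0) {
  fams <- c("lognormal", "cauchy", "normal", "gamma", "weibull",
            "exponential")
  sup <- c(lo, vMax)
  c(lapply(c(fams, "uniform"), distSpec, mixture = FALSE, support = sup),
    lapply(fams, distSpec, mixture = TRUE, support = sup))
}

# Construct a FitResult directly from known parameters (no fitting). Used
# for evaluating/sampling reference models and for intersection tests.
#' Build a FitResult from explicit parameter values
#'
#' Wraps known parameters in a \code{\link{FitResult-class}} without any
#' estimation, e.g. to evaluate a reference curve or to sample synthetic
#' speeds from a specified model.
#'
#' @param spec A \code{\link{DistSpec-class}}.
#' @param params Named numeric vector; component parameters plus \code{w}
#'   for mixtures.
#' @param samples Optional data the log-likelihood should be evaluated on.
#' @return A \code{FitResult} (log-likelihood is \code{NA} unless
#'   \code{samples} given).
#' @export
asFitResult <- function(spec, params = numeric(), samples = NULL) {
  stopifnot(is(spec, "DistSpec"))
  fr <- new("FitResult", spec = spec, params = params,
            logLik = NA_real_, n = 0L, converged = TRUE,
            nRestartsUsed = 0L)
  if (!is.null(samples)) {
    fr@logLik <- sum(speedPdf(fr, samples, log = TRUE))
    fr@n <- length(samples)
  }
  fr
}

#' Evaluate the fitted probability density
#'
#' For a single family: the family density truncated and renormalised to
#' the support. For a mixture: \eqn{w f_{trunc}(x) + (1 - w)/(hi - lo)}.
#' Zero outside the support.
#'
#' @param fit A \code{\link{FitResult-class}}.
#' @param x Speeds (µm/s).
#' @param log Return log-density?
#' @return Densities (per µm/s), nonnegative everywhere.
#' @export
speedPdf <- function(fit, x, log = FALSE) {
  stopifnot(is(fit, "FitResult"))
  spec <- fit@spec
  p <- fit@params
  sup <- spec@support
  dens <- numeric(length(x))
  ok <- inSupport(x, sup)
  if (spec@family == "uniform") {
    dens[ok] <- 1 / (sup[2] - sup[1])
  } else {
    Z <- truncMass(spec@family, p, sup)
    comp <- numeric(length(x))
    if (Z > 0) comp[ok] <- baseDens(spec@family, x[ok], p) / Z
    if (spec@mixture) {
      w <- p[["w"]]
      dens[ok] <- w * comp[ok] + (1 - w) / (sup[2] - sup[1])
    } else dens <- comp
  }
  if (log) base::log(dens) else dens
}

#' Evaluate the fitted cumulative distribution function
#'
#' @inheritParams speedPdf
#' @param q Speeds (µm/s).
#' @return Probabilities; 0 below the support, 1 above it.
#' @export
speedCdf <- function(fit, q) {
  stopifnot(is(fit, "FitResult"))
  spec <- fit@spec
  p <- fit@params
  sup <- spec@support
  qc <- pmin(pmax(q, sup[1]), sup[2])
  unif <- (qc - sup[1]) / (sup[2] - sup[1])
  if (spec@family == "uniform") return(unif)
  Z <- truncMass(spec@family, p, sup)
  compc <- if (Z > 0)
    (baseCdf(spec@family, qc, p) - baseCdf(spec@family, sup[1], p)) / Z
  else unif * 0
  out <- if (spec@mixture) {
    w <- p[["w"]]
    w * compc + (1 - w) * unif
  } else compc
  pmin(pmax(out, 0), 1)
}

#' Sample speeds from a fitted model
#'
#' Inverse-CDF sampling of the truncated component; mixture membership by a
#' Bernoulli draw on the weight.
#'
#' @inheritParams speedPdf
#' @param n Number of draws.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return Numeric vector of speeds inside the support.
#' @export
sampleSpeeds <- function(fit, n, seed = NULL) {
  stopifnot(is(fit, "FitResult"), n >= 0)
  withSeed(seed, {
    spec <- fit@spec
    p <- fit@params
    sup <- spec@support
    rUnif <- function(m) stats::runif(m, sup[1], sup[2])
    if (spec@family == "uniform") return(rUnif(n))
    rComp <- function(m) {
      lo <- baseCdf(spec@family, sup[1], p)
      hi <- if (is.finite(sup[2])) baseCdf(spec@family, sup[2], p) else 1
      baseQuantile(spec@family, lo + stats::runif(m) * (hi - lo), p)
    }
    if (!spec@mixture) return(rComp(n))
    fromComp <- stats::runif(n) < p[["w"]]
    out <- numeric(n)
    out[fromComp] <- rComp(sum(fromComp))
    out[!fromComp] <- rUnif(sum(!fromComp))
    out
  })
}

setMethod("show", "FitResult", function(object) {
  s <- object@spec
  cat(sprintf("FitResult: %s%s on (%g, %g]\n", s@family,
              if (s@mixture) " + uniform" else "",
              s@support[1], s@support[2]))
  if (length(object@params))
    cat("  params:",
        paste(sprintf("%s = %.4g", names(object@params), object@params),
              collapse = ", "), "\n")
  cat(sprintf("  logLik = %.4f on n = %d%s%s\n", object@logLik, object@n,
              if (!object@converged) " [NOT CONVERGED]" else "",
              if (object@boundary) " [boundary weight]" else ""))
})
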