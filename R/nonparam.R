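# Two-sample Kolmogorov-Smirnov and Kruskal-Wallis tests, implemented on
# ECDFs and midranks directly so that exact/permutation reference modes are
# available for small samples. Base R's ks.test/kruskal.test serve as
# independent cross-checks in the test suite.

ksStatistic <- function(x, y) {
  nx <- length(x); ny <- length(y)
  w <- c(x, y)
  o <- order(w)
  # running ECDF difference; at ties only the value after the whole tied
  # block is a valid evaluation point
  z <- cumsum(ifelse(o <= nx, 1 / nx, -1 / ny))
  keep <- c(diff(w[o]) != 0, TRUE)
  max(abs(z[keep]))
}

# survival function of the Kolmogorov distribution
kolmogorovSF <- function(lambda) {
  if (lambda <= 0) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided test of whether two speed samples come from the same
#' distribution. The statistic is the supremum over pooled points of the
#' absolute ECDF difference. The default p-value uses the asymptotic
#' Kolmogorov distribution with effective sample size
#' \eqn{n_e = n_x n_y / (n_x + n_y)} and the standard small-sample
#' continuity adjustment \eqn{\lambda = (\sqrt{n_e} + 0.12 +
#' 0.11/\sqrt{n_e}) D}. For \eqn{n_x + n_y \le 16} an exact permutation
#' p-value (full enumeration of group assignments) is available and is the
#' default (\code{method = "auto"}).
#'
#' @param x,y Numeric samples (both nonempty).
#' @param method \code{"auto"}, \code{"asymptotic"} or \code{"exact"}.
#' @return An object of class \code{"htest"} with the statistic \code{D},
#'   the p-value, and the sample sizes.
#' @export
ksTwoSample <- function(x, y, method = c("auto", "asymptotic", "exact")) {
  method <- match.arg(method)
  if (!length(x) || !length(y)) stopf("both samples must be nonempty")
  nx <- length(x); ny <- length(y)
  D <- ksStatistic(x, y)
  if (method == "auto")
    method <- if (nx + ny <= 16) "exact" else "asymptotic"
  if (method == "exact") {
    if (nx + ny > 16)
      stopf("exact enumeration limited to n_x + n_y <= 16 (got %d)", nx + ny)
    pooled <- c(x, y)
    idx <- utils::combn(nx + ny, nx)
    Dperm <- apply(idx, 2, function(i) ksStatistic(pooled[i], pooled[-i]))
    p <- mean(Dperm >= D - 1e-12)
    note <- "exact (full enumeration)"
  } else {
    ne <- nx * ny / (nx + ny)
    lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
    p <- kolmogorovSF(lambda)
    note <- "asymptotic Kolmogorov distribution"
  }
  structure(list(statistic = c(D = D), p.value = p,
                 method = paste("Two-sample Kolmogorov-Smirnov test,", note),
                 alternative = "two-sided",
                 n = c(n_x = nx, n_y = ny),
                 data.name = paste(deparse1(substitute(x)), "and",
                                   deparse1(substitute(y)))),
            class = "htest")
}

kwStatistic <- function(groups) {
  N <- sum(lengths(groups))
  pooled <- unlist(groups, use.names = FALSE)
  r <- rank(pooled)  # midranks
  g <- rep(seq_along(groups), lengths(groups))
  Rbar <- tapply(r, g, mean)
  ni <- lengths(groups)
  H <- 12 / (N * (N + 1)) * sum(ni * (Rbar - (N + 1) / 2)^2)
  tie <- table(pooled)
  C <- 1 - sum(tie^3 - tie) / (N^3 - N)
  if (C <= 0) return(0)  # all values identical
  H / C
}

#' Kruskal-Wallis rank test with tie correction
#'
#' Compares the central tendency of two or more groups via midranks of the
#' pooled data: \eqn{H = \frac{12}{N(N+1)} \sum_i n_i (\bar R_i -
#' \frac{N+1}{2})^2} divided by the tie-correction factor
#' \eqn{1 - \sum (t^3 - t)/(N^3 - N)}. The default p-value is from the
#' chi-squared distribution with (number of groups - 1) degrees of freedom;
#' a seeded permutation p-value is available for small-sample checks. All
#' values identical across groups is reported as H = 0, p = 1, not an
#' error.
#'
#' @param groups List of numeric samples (>= 2 groups, total N >= 3).
#' @param method \code{"chisq"} (default) or \code{"permutation"}.
#' @param nPerm Number of permutations (default 10000).
#' @param seed Seed for the permutation mode.
#' @return An object of class \code{"htest"} with the statistic \code{H}.
#' @export
kruskalWallisTest <- function(groups, method = c("chisq", "permutation"),
                              nPerm = 10000, seed = NULL) {
  method <- match.arg(method)
  stopifnot(is.list(groups), length(groups) >= 2, all(lengths(groups) >= 1))
  N <- sum(lengths(groups))
  if (N < 3) stopf("need a total of at least 3 observations")
  H <- kwStatistic(groups)
  df <- length(groups) - 1
  if (H == 0) {
    p <- 1
    note <- "degenerate (no rank variation)"
  } else if (method == "chisq") {
    p <- stats::pchisq(H, df = df, lower.tail = FALSE)
    note <- sprintf("chi-squared approximation, df = %d", df)
  } else {
    pooled <- unlist(groups, use.names = FALSE)
    ni <- lengths(groups)
    p <- withSeed(seed, {
      hits <- 0L
      for (b in seq_len(nPerm)) {
        perm <- sample(pooled)
        gs <- split(perm, rep(seq_along(ni), ni))
        if (kwStatistic(gs) >= H - 1e-12) hits <- hits + 1L
      }
      (hits + 1) / (nPerm + 1)
    })
    note <- sprintf("permutation (%d resamples)", nPerm)
  }
  structure(list(statistic = c(H = H), p.value = p,
                 parameter = c(df = df),
                 method = paste("Kruskal-Wallis rank test,", note),
                 n = lengths(groups),
                 data.name = deparse1(substitute(groups))),
            class = "htest")
}
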