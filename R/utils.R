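# internal helpers shared across modules

# Run code under a temporary RNG state. seed = NULL leaves the RNG alone.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed that stays inside 32-bit integer range.
childSeed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1009 + k) %% 2147483647)
}

#' Format a mean and standard deviation as \code{"mean ± sd"}
#'
#' Two-decimal rendering used in per-video and combined summary tables.
#' An undefined mean renders as \code{"—"}; an undefined sd (n < 2) is
#' omitted.
#'
#' @param mean,sd Numeric scalars (may be \code{NA}).
#' @return A character scalar.
#' @export
formatMeanSd <- function(mean, sd) {
  if (is.na(mean)) return("—")
  if (is.na(sd)) return(sprintf("%.2f", mean))
  sprintf("%.2f ± %.2f", mean, sd)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
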