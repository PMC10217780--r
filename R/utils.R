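#' @importFrom stats median p.adjust quantile rbinom rpois runif sd t.test
#'   ks.test wilcox.test predict setNames
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-stage random seed from a global seed
#'
#' Deterministically maps a (seed, stage-name) pair to a 32-bit integer seed so
#' that pipeline stages can be re-run independently with identical results.
#' The derivation is a small polynomial rolling hash of the stage name folded
#' into the global seed modulo 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param stage character stage name (e.g. \code{"cohort"}, \code{"split"}).
#' @return a single integer suitable for \code{set.seed()}.
#' @export
#' @examples
#' stageSeed(1L, "cohort")
stageSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647  # 2^31 - 1
  h <- as.double(seed %% m)
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% m
  as.integer(h)
}

## internal: stop() with a consistent prefix
kgStop <- function(...) stop(..., call. = FALSE)

## internal: check a probability vector
assertProb <- function(v, tol = 1e-9, what = "vector") {
  if (any(v < -tol)) kgStop(what, " has negative entries")
  if (abs(sum(v) - 1) > tol) kgStop(what, " does not sum to 1 (sum = ", sum(v), ")")
  invisible(TRUE)
}
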