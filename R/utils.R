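#' @keywords internal
#' @importFrom stats rnorm runif quantile setNames
#' @importFrom utils read.csv write.csv
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Numerically stable softmax
#'
#' @param x numeric vector of scores.
#' @return vector of the same length on the probability simplex.
#' @keywords internal
softmax <- function(x) {
  if (any(!is.finite(x))) {
    stop("non-finite score at instance index ", which(!is.finite(x))[1L])
  }
  e <- exp(x - max(x))
  e / sum(e)
}

#' Derive a stage seed from a global seed
#'
#' Hashes the stage name onto a 31-bit integer and combines it with the
#' run seed so that each pipeline stage draws from an independent,
#' individually reproducible stream.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return integer seed in [0, 2^31).
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% 2147483647
  as.integer((abs(seed) + h) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}
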