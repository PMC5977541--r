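#' @import methods
#' @importFrom stats median quantile rnorm runif rpois pnorm fft dist
#'   setNames
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a deterministic 32-bit sub-seed from a base seed and indices
#'
#' Mixes the base seed with up to three indices through a multiplicative hash
#' so nested simulation loops (patient, patch, retry) get independent but
#' reproducible streams without consuming the global RNG.
#'
#' @param seed base integer seed.
#' @param ... further non-negative integers distinguishing the stream.
#' @return an integer in [0, 2^31 - 1].
#' @keywords internal
deriveSeed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed) %% 2147483647
  for (v in idx) {
    h <- (h * 48271 + as.double(v) * 2654435761 + 1) %% 2147483647
  }
  as.integer(h)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' Population standard deviation
#' @param x numeric vector.
#' @keywords internal
popSd <- function(x) {
  n <- length(x)
  if (n == 0) return(NaN)
  sqrt(sum((x - mean(x))^2) / n)
}

popSkewness <- function(x) {
  n <- length(x)
  s <- popSd(x)
  if (n < 2 || s == 0) return(0)
  mean((x - mean(x))^3) / s^3
}

popKurtosis <- function(x) {
  n <- length(x)
  s <- popSd(x)
  if (n < 2 || s == 0) return(0)
  mean((x - mean(x))^4) / s^4 - 3
}
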