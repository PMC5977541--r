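#' Four-number summary used throughout the architecture feature catalog
#'
#' Summarises a set of measurements (Voronoi cell areas, graph edge lengths,
#' neighbor counts, ...) by its mean, population standard deviation,
#' min/max ratio and the disorder statistic
#' \deqn{D = 1 - \frac{1}{1 + \sigma/\mu}}
#' which is 0 for perfectly regular sets and approaches 1 as the relative
#' variability grows.
#'
#' Conventions: population (not sample) standard deviation; if the maximum is
#' 0 with all values 0 the min/max ratio is defined as 1; if the mean is 0 the
#' disorder is defined as 0.
#'
#' @param values numeric vector, length >= 1.
#' @return named numeric vector \code{c(mean, std, minmax_ratio, disorder)}.
#' @examples
#' statSet(c(1, 3))   # mean 2, std 1, minmax 1/3, disorder 1/3
#' @export
statSet <- function(values) {
  if (length(values) == 0 || !is.numeric(values))
    stop("statSet() is undefined for an empty value set", call. = FALSE)
  m <- mean(values)
  s <- popSd(values)
  mx <- max(values)
  mn <- min(values)
  mmr <- if (mx == 0 && all(values == 0)) 1 else mn / mx
  dis <- if (m == 0) 0 else 1 - 1 / (1 + s / m)
  c(mean = m, std = s, minmax_ratio = mmr, disorder = dis)
}
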