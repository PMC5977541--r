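# Per-nucleus shape descriptors and their per-compartment aggregation.

shapeDescriptorDefs <- local({
  base <- c("Area Ratio", "Perimeter Ratio", "Distance Ratio",
            "Radial Standard Deviation", "Radial Variance", "Smoothness",
            "Length Width Ratio",
            paste("Invariant Moment", 1:7),
            "Fractal Dimension",
            paste("Fourier Descriptor", 1:10))
  keys <- c("area_ratio", "perimeter_ratio", "distance_ratio", "radial_std",
            "radial_var", "smoothness", "length_width_ratio",
            paste0("invariant_moment_", 1:7), "fractal_dimension",
            paste0("fourier_descriptor_", 1:10))
  data.frame(key = keys, label = base, stringsAsFactors = FALSE)
})

#' Principal-axis orientation of a nucleus
#'
#' Orientation of the major principal axis of the filled polygon, from its
#' central second area moments, reported in degrees on [0, 180) in image
#' coordinates (x right, y down; 0 = x-axis aligned).
#'
#' @param poly n x 2 vertex matrix of a simple polygon with positive area.
#' @return orientation angle in degrees, in [0, 180).
#' @export
nucleusOrientation <- function(poly) {
  mu <- polygonCentralMoments(poly)
  ang <- 0.5 * atan2(2 * mu[["mu11"]], mu[["mu20"]] - mu[["mu02"]])
  deg <- (ang * 180 / pi) %% 180
  if (deg >= 180) deg <- deg - 180
  deg
}

boxCountingDimension <- function(boundary, nScales = 5L) {
  ext <- max(diff(range(boundary[, 1])), diff(range(boundary[, 2])))
  if (ext <= 0) return(1)
  # densify so point spacing is below half the smallest box
  target <- 2^nScales * 5L
  dense <- resampleBoundary(boundary, max(160L, target))
  x0 <- min(dense[, 1]); y0 <- min(dense[, 2])
  counts <- integer(nScales)
  sizes <- ext / 2^seq_len(nScales)
  for (k in seq_len(nScales)) {
    s <- sizes[k]
    bx <- floor((dense[, 1] - x0) / s)
    by <- floor((dense[, 2] - y0) / s)
    counts[k] <- length(unique(bx * 1e6 + by))
  }
  lx <- log(1 / sizes)
  ly <- log(counts)
  sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
}

#' The 25 per-nucleus shape descriptors
#'
#' Computes, from one simple closed nucleus boundary polygon: area ratio
#' (area / area of the circumscribed circle of radius R_max), perimeter ratio
#' (perimeter / perimeter of the equal-area circle), distance ratio (mean
#' radial distance / R_max), the population SD and variance of the
#' centroid-to-boundary radial distances, smoothness (mean absolute deviation
#' of each radial distance from the mean of its two neighbors), length/width
#' ratio (square root of the principal second-moment ratio), Hu's seven
#' invariant moments, the box-counting fractal dimension of the boundary,
#' and the magnitudes of Fourier boundary harmonics 1-10 normalized by
#' harmonic 1. The boundary is first resampled to 128 points equally spaced
#' in arc length, so the descriptors do not depend on vertex density.
#'
#' @param poly n x 2 vertex matrix (>= 8 vertices) of a simple closed polygon.
#' @param checkSimple verify simplicity (error on self-intersection).
#' @return named numeric vector of length 25.
#' @export
shapeDescriptors <- function(poly, checkSimple = TRUE) {
  if (nrow(poly) < 8)
    stop("shape descriptors need a polygon with >= 8 vertices", call. = FALSE)
  if (checkSimple && !polygonIsSimple(poly))
    stop("self-intersecting polygon", call. = FALSE)
  A <- polygonArea(poly)
  if (A <= 0) stop("degenerate polygon: zero area", call. = FALSE)
  P <- polygonPerimeter(poly)
  bnd <- resampleBoundary(poly, 128L)
  cen <- polygonCentroid(poly)
  d <- sqrt((bnd[, 1] - cen[1])^2 + (bnd[, 2] - cen[2])^2)
  rmax <- max(d)
  req <- sqrt(A / pi)
  neighborMean <- (d[c(128L, 1:127)] + d[c(2:128, 1L)]) / 2
  mu <- polygonCentralMoments(poly)
  m00 <- mu[["mu00"]]
  covm <- matrix(c(mu[["mu20"]], mu[["mu11"]], mu[["mu11"]], mu[["mu02"]]),
                 2, 2) / m00
  ev <- eigen(covm, symmetric = TRUE, only.values = TRUE)$values
  lw <- if (ev[2] <= 0) Inf else sqrt(ev[1] / ev[2])
  hu <- huMoments(poly, mu = mu)
  z <- complex(real = bnd[, 1] - cen[1], imaginary = bnd[, 2] - cen[2])
  F <- fft(z)
  mag <- Mod(F[2:11])
  fd <- if (mag[1] > 0) mag / mag[1] else rep(0, 10)
  out <- c(
    A / (pi * rmax^2),
    P / (2 * pi * req),
    mean(d) / rmax,
    popSd(d),
    popSd(d)^2,
    mean(abs(d - neighborMean)),
    lw,
    hu,
    boxCountingDimension(bnd),
    fd
  )
  names(out) <- shapeDescriptorDefs$key
  out
}

shapeStatLabels <- c(mean = "Mean", std = "Standard Deviation",
                     median = "Median", minmax_ratio = "Min Max Ratio")

#' Catalog names of the 100 per-compartment shape features
#' @param prefix compartment prefix, e.g. \code{"EP"}.
#' @return character vector of length 100.
#' @keywords internal
shapeFeatureNames <- function(prefix = NULL) {
  nm <- as.vector(vapply(shapeDescriptorDefs$label, function(lab)
    paste0("Shape: ", shapeStatLabels, " ", lab), character(4)))
  if (!is.null(prefix)) nm <- paste0(prefix, ": ", nm)
  nm
}

#' Aggregate per-nucleus shape descriptors into 100 compartment features
#'
#' For each of the 25 descriptors, computes the mean, population standard
#' deviation, median and min/max ratio across the compartment's nuclei
#' (catalog order: the four statistics per descriptor, descriptors in
#' \code{shapeDescriptors} order).
#'
#' @param polys list of nucleus boundary polygons of one compartment.
#' @param minNuclei minimum nuclei required; below it an all-NaN vector is
#'   returned (the patch NaN policy).
#' @param prefix optional compartment prefix for the names.
#' @return named numeric vector of length 100.
#' @export
shapeVector <- function(polys, minNuclei = 5L, prefix = NULL) {
  nm <- shapeFeatureNames(prefix)
  if (length(polys) < minNuclei)
    return(setNames(rep(NaN, 100L), nm))
  rows <- t(vapply(polys, shapeDescriptors, numeric(25), checkSimple = FALSE))
  out <- as.vector(apply(rows, 2, function(v) {
    mx <- max(v); mn <- min(v)
    mmr <- if (mx == 0 && all(v == 0)) 1 else mn / mx
    c(mean(v), popSd(v), median(v), mmr)
  }))
  setNames(out, nm)
}
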