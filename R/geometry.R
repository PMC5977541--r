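# Planar polygon primitives shared by the shape and I/O code.
# Polygons are n x 2 matrices of (x, y) vertices in pixel units, implicitly
# closed (last vertex connects back to the first), 0-based image coordinates
# with x to the right and y down.

polygonArea <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2
}

polygonSignedArea <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

polygonPerimeter <- function(poly) {
  d <- poly - poly[c(2:nrow(poly), 1), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

#' Area centroid of a simple polygon (falls back to the vertex mean for
#' degenerate zero-area input).
#' @keywords internal
polygonCentroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(poly))
  cx <- sum((x + x2) * cr) / (6 * a)
  cy <- sum((y + y2) * cr) / (6 * a)
  c(cx, cy)
}

# Exact area moments M_pq of the filled polygon for p + q <= 3, via Green's
# theorem over the edge fan (the closed forms used by standard contour-moment
# implementations). Returns raw moments with positive orientation normalized.
polygonRawMoments <- function(poly) {
  x1 <- poly[, 1]; y1 <- poly[, 2]
  idx <- c(2:nrow(poly), 1)
  x2 <- poly[idx, 1]; y2 <- poly[idx, 2]
  a <- x1 * y2 - x2 * y1
  m <- c(
    m00 = sum(a) / 2,
    m10 = sum(a * (x1 + x2)) / 6,
    m01 = sum(a * (y1 + y2)) / 6,
    m20 = sum(a * (x1^2 + x1 * x2 + x2^2)) / 12,
    m11 = sum(a * (2 * x1 * y1 + x1 * y2 + x2 * y1 + 2 * x2 * y2)) / 24,
    m02 = sum(a * (y1^2 + y1 * y2 + y2^2)) / 12,
    m30 = sum(a * (x1^3 + x1^2 * x2 + x1 * x2^2 + x2^3)) / 20,
    m21 = sum(a * (x1^2 * (3 * y1 + y2) + 2 * x1 * x2 * (y1 + y2) +
                     x2^2 * (y1 + 3 * y2))) / 60,
    m12 = sum(a * (y1^2 * (3 * x1 + x2) + 2 * y1 * y2 * (x1 + x2) +
                     y2^2 * (x1 + 3 * x2))) / 60,
    m03 = sum(a * (y1^3 + y1^2 * y2 + y1 * y2^2 + y2^3)) / 20
  )
  if (m[["m00"]] < 0) m <- -m
  m
}

# Central moments mu_pq (p + q <= 3) of the filled polygon.
polygonCentralMoments <- function(poly) {
  m <- polygonRawMoments(poly)
  m00 <- m[["m00"]]
  if (m00 <= 0) stop("degenerate polygon: zero area", call. = FALSE)
  xc <- m[["m10"]] / m00
  yc <- m[["m01"]] / m00
  mu20 <- m[["m20"]] - xc * m[["m10"]]
  mu02 <- m[["m02"]] - yc * m[["m01"]]
  mu11 <- m[["m11"]] - xc * m[["m01"]]
  mu30 <- m[["m30"]] - 3 * xc * m[["m20"]] + 2 * xc^2 * m[["m10"]]
  mu03 <- m[["m03"]] - 3 * yc * m[["m02"]] + 2 * yc^2 * m[["m01"]]
  mu21 <- m[["m21"]] - 2 * xc * m[["m11"]] - yc * m[["m20"]] +
    2 * xc^2 * m[["m01"]]
  mu12 <- m[["m12"]] - 2 * yc * m[["m11"]] - xc * m[["m02"]] +
    2 * yc^2 * m[["m10"]]
  c(mu00 = m00, mu20 = mu20, mu11 = mu11, mu02 = mu02,
    mu30 = mu30, mu21 = mu21, mu12 = mu12, mu03 = mu03,
    xc = xc, yc = yc)
}

#' Hu's seven rotation/translation/scale-invariant moments of a filled polygon
#' @param poly n x 2 vertex matrix of a simple closed polygon.
#' @param mu optional precomputed \code{polygonCentralMoments(poly)}.
#' @return numeric vector of length 7.
#' @keywords internal
huMoments <- function(poly, mu = polygonCentralMoments(poly)) {
  m00 <- mu[["mu00"]]
  eta <- function(val, p, q) val / m00^((p + q) / 2 + 1)
  n20 <- eta(mu[["mu20"]], 2, 0); n02 <- eta(mu[["mu02"]], 0, 2)
  n11 <- eta(mu[["mu11"]], 1, 1)
  n30 <- eta(mu[["mu30"]], 3, 0); n03 <- eta(mu[["mu03"]], 0, 3)
  n21 <- eta(mu[["mu21"]], 2, 1); n12 <- eta(mu[["mu12"]], 1, 2)
  h1 <- n20 + n02
  h2 <- (n20 - n02)^2 + 4 * n11^2
  h3 <- (n30 - 3 * n12)^2 + (3 * n21 - n03)^2
  h4 <- (n30 + n12)^2 + (n21 + n03)^2
  h5 <- (n30 - 3 * n12) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
    (3 * n21 - n03) * (n21 + n03) *
    (3 * (n30 + n12)^2 - (n21 + n03)^2)
  h6 <- (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
    4 * n11 * (n30 + n12) * (n21 + n03)
  h7 <- (3 * n21 - n03) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
    (n30 - 3 * n12) * (n21 + n03) *
    (3 * (n30 + n12)^2 - (n21 + n03)^2)
  c(h1, h2, h3, h4, h5, h6, h7)
}

# Segment-intersection based simplicity test, vectorized over all
# non-adjacent edge pairs; shared endpoints of adjacent edges do not count.
polygonIsSimple <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  nxt <- c(2:n, 1)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- pr[, 1]; j <- pr[, 2]
  adj <- (j == i + 1) | (i == 1 & j == n)
  i <- i[!adj]; j <- j[!adj]
  if (!length(i)) return(TRUE)
  a1x <- poly[i, 1]; a1y <- poly[i, 2]
  a2x <- poly[nxt[i], 1]; a2y <- poly[nxt[i], 2]
  b1x <- poly[j, 1]; b1y <- poly[j, 2]
  b2x <- poly[nxt[j], 1]; b2y <- poly[nxt[j], 2]
  d1x <- a2x - a1x; d1y <- a2y - a1y
  d2x <- b2x - b1x; d2y <- b2y - b1y
  den <- d1x * d2y - d1y * d2x
  ok <- abs(den) > 1e-14  # parallel edges: treat as non-crossing
  t <- ((b1x - a1x) * d2y - (b1y - a1y) * d2x) / den
  u <- ((b1x - a1x) * d1y - (b1y - a1y) * d1x) / den
  cross <- ok & t > 1e-12 & t < 1 - 1e-12 & u > 1e-12 & u < 1 - 1e-12
  !any(cross, na.rm = TRUE)
}

# Vectorized even-odd (crossing number) point-in-polygon test.
pointsInPolygon <- function(px, py, poly) {
  n <- nrow(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xj <- c(x[n], x[-n]); yj <- c(y[n], y[-n])
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    cross <- ((y[i] > py) != (yj[i] > py)) &
      (px < (xj[i] - x[i]) * (py - y[i]) / (yj[i] - y[i]) + x[i])
    inside <- xor(inside, cross & !is.na(cross))
  }
  inside
}

# Pixel centers (0-based convention: pixel (i, j) has center (i, j)) covered
# by a polygon, restricted to its bounding box. Returns a 2-col matrix.
polygonPixelCenters <- function(poly) {
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  xs <- seq(floor(xr[1]), ceiling(xr[2]))
  ys <- seq(floor(yr[1]), ceiling(yr[2]))
  g <- expand.grid(x = xs, y = ys)
  keep <- pointsInPolygon(g$x, g$y, poly)
  cbind(g$x[keep], g$y[keep])
}

#' Resample a closed polygon boundary to m points equally spaced in arc length
#' @keywords internal
resampleBoundary <- function(poly, m = 128L) {
  closed <- rbind(poly, poly[1, , drop = FALSE])
  seg <- sqrt(rowSums((closed[-1, , drop = FALSE] -
                         closed[-nrow(closed), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) stop("degenerate polygon: zero perimeter", call. = FALSE)
  t <- seq(0, total, length.out = m + 1)[seq_len(m)]
  xi <- approx(cum, closed[, 1], xout = t, ties = "ordered")$y
  yi <- approx(cum, closed[, 2], xout = t, ties = "ordered")$y
  cbind(xi, yi)
}

rotatePoints <- function(pts, angleDeg, center = c(0, 0)) {
  th <- angleDeg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(sweep(pts, 2, center) %*% t(R), 2, center, `+`)
}

#' @importFrom stats approx
NULL
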