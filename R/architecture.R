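# The 116 per-compartment nuclear architecture features:
# Voronoi (12), Delaunay (8), MST (4), nearest-neighbor/density (27),
# cell cluster graph (39), orientation co-occurrence entropy (26).

nnRadii <- c(10, 20, 30, 40, 50)
nnKs <- c(3L, 5L, 7L)
corePxRadius <- 40

statSuffix <- c("Mean", "Standard Deviation", "Min Max Ratio", "Disorder")

voronoiFeatureNames <- function() {
  as.vector(vapply(c("Cell Area", "Cell Perimeter", "Cell Chord Length"),
                   function(q) paste0("Voronoi: ", statSuffix, " ", q),
                   character(4)))
}

delaunayFeatureNames <- function() {
  as.vector(vapply(c("Side Length", "Triangle Area"),
                   function(q) paste0("Delaunay: ", statSuffix, " ", q),
                   character(4)))
}

mstFeatureNames <- function() paste0("MST: ", statSuffix, " Edge Length")

nnFeatureNames <- function() {
  cnt <- as.vector(vapply(nnRadii, function(r) paste0(
    "Arch: ",
    c("Avg. Nearest Neighbors", "Standard Deviation Nearest Neighbors",
      "Disorder of Nearest Neighbors"),
    sprintf(" in a %d Pixel Radius", r)), character(3)))
  knn <- as.vector(vapply(nnKs, function(k) paste0(
    "Arch: ",
    c("Avg. Distance to", "Standard Deviation Distance to",
      "Disorder of Distance to"),
    sprintf(" %d Nearest Neighbors", k)), character(3)))
  c(cnt, knn, "Arch: Nuclear Density",
    "Arch: Avg. Distance to Nearest Neighbor",
    "Arch: Standard Deviation Distance to Nearest Neighbor")
}

ccgFeatureNames <- function() {
  c("CCG: Number of Nodes", "CCG: Number of Edges", "CCG: Graph Density",
    "CCG: Mean Degree", "CCG: Standard Deviation Degree",
    "CCG: Disorder Degree",
    "CCG: Mean Eccentricity", "CCG: Standard Deviation Eccentricity",
    "CCG: Diameter", "CCG: Radius",
    "CCG: Mean Eccentricity 90%", "CCG: Diameter 90%", "CCG: Radius 90%",
    "CCG: Average Path Length", "CCG: Standard Deviation Path Length",
    "CCG: Clustering Coefficient C", "CCG: Clustering Coefficient D",
    "CCG: Clustering Coefficient E",
    "CCG: Number of Connected Components", "CCG: Giant Component Ratio",
    "CCG: Mean Component Size", "CCG: Standard Deviation Component Size",
    "CCG: Number of Isolated Nodes", "CCG: Fraction of Isolated Nodes",
    "CCG: Number of End Nodes", "CCG: Fraction of End Nodes",
    "CCG: Number of Central Nodes", "CCG: Fraction of Central Nodes",
    "CCG: mean edge length", "CCG: standard deviation edge length",
    "CCG: min max ratio edge length", "CCG: disorder edge length",
    "CCG: skewness edge length", "CCG: kurtosis edge length",
    "CCG: Spectral Radius", "CCG: Second Largest Eigenvalue",
    "CCG: Graph Energy", "CCG: Number of Distinct Eigenvalues",
    "CCG: Eigen Exponent")
}

coreStatNames <- c("Contrast Energy", "Contrast Inverse Moment",
                   "Contrast Average", "Contrast Variance",
                   "Contrast Entropy", "Intensity Average",
                   "Intensity Variance", "Intensity Entropy", "Entropy",
                   "Energy", "Correlation", "Information Measure 1",
                   "Information Measure 2")

coreFeatureNames <- function() {
  c(paste0("COrE: CCG ", coreStatNames),
    paste0("COrE: 40px ", coreStatNames))
}

#' Catalog names of the 116 per-compartment architecture features
#' @param prefix optional compartment prefix, e.g. \code{"EP"}.
#' @return character vector of length 116.
#' @keywords internal
architectureFeatureNames <- function(prefix = NULL) {
  nm <- c(voronoiFeatureNames(), delaunayFeatureNames(), mstFeatureNames(),
          nnFeatureNames(), ccgFeatureNames(), coreFeatureNames())
  if (!is.null(prefix)) nm <- paste0(prefix, ": ", nm)
  nm
}

checkNonCollinear <- function(centroids) {
  if (nrow(centroids) < 3) return(FALSE)
  s <- svd(scale(centroids, scale = FALSE))$d
  s[2] > 1e-9 * max(s[1], 1)
}

# Indices of centroids kept after merging points closer than `tol` px
# (duplicate detections would otherwise create zero-length graph edges).
coincidentKeepIndex <- function(centroids, tol = 1e-6) {
  if (nrow(centroids) < 2) return(seq_len(nrow(centroids)))
  key <- paste(round(centroids[, 1] / tol), round(centroids[, 2] / tol))
  dup <- duplicated(key)
  if (any(dup)) message(sum(dup), " coincident centroid(s) merged")
  which(!dup)
}

mergeCoincident <- function(centroids, tol = 1e-6) {
  centroids[coincidentKeepIndex(centroids, tol), , drop = FALSE]
}

tessellate <- function(centroids, bounds) {
  deldir::deldir(centroids[, 1], centroids[, 2], rw = bounds,
                 suppressMsge = TRUE)
}

#' Voronoi diagram features (12)
#'
#' Statistics (\code{\link{statSet}}) of cell area, cell perimeter and cell
#' chord length (all vertex-pair distances per cell), computed over the
#' Voronoi cells that lie strictly inside the patch bounds; cells touching
#' or clipped by the boundary are dropped to avoid censored-area bias.
#'
#' @param centroids n x 2 matrix of nucleus centroids (n >= 5,
#'   non-collinear).
#' @param bounds patch rectangle \code{c(xmin, xmax, ymin, ymax)}.
#' @param dd optional precomputed \code{deldir} tessellation.
#' @return named numeric vector of length 12 (NaN when fewer than 5 interior
#'   cells are available).
#' @export
voronoiFeatures <- function(centroids, bounds, dd = NULL) {
  nm <- voronoiFeatureNames()
  if (!checkNonCollinear(centroids))
    stop("Voronoi diagram undefined: collinear or too few centroids",
         call. = FALSE)
  if (is.null(dd)) dd <- tessellate(centroids, bounds)
  tiles <- deldir::tile.list(dd)
  eps <- 1e-9
  interior <- vapply(tiles, function(tl) {
    !any(tl$bp) &&
      all(tl$x > bounds[1] + eps & tl$x < bounds[2] - eps &
            tl$y > bounds[3] + eps & tl$y < bounds[4] - eps)
  }, logical(1))
  tiles <- tiles[interior]
  if (length(tiles) < 5) return(setNames(rep(NaN, 12L), nm))
  areas <- vapply(tiles, function(tl) polygonArea(cbind(tl$x, tl$y)),
                  numeric(1))
  perims <- vapply(tiles, function(tl) polygonPerimeter(cbind(tl$x, tl$y)),
                   numeric(1))
  chords <- unlist(lapply(tiles, function(tl) {
    as.vector(dist(cbind(tl$x, tl$y)))
  }))
  setNames(c(statSet(areas), statSet(perims), statSet(chords)), nm)
}

#' Delaunay triangulation features (8)
#'
#' Statistics of the Delaunay edge (triangle side) lengths and triangle
#' areas.
#'
#' @inheritParams voronoiFeatures
#' @return named numeric vector of length 8.
#' @export
delaunayFeatures <- function(centroids, dd = NULL) {
  nm <- delaunayFeatureNames()
  if (!checkNonCollinear(centroids))
    stop("Delaunay triangulation undefined: collinear or too few centroids",
         call. = FALSE)
  if (is.null(dd)) {
    pad <- 1
    bounds <- c(range(centroids[, 1]) + c(-pad, pad),
                range(centroids[, 2]) + c(-pad, pad))
    dd <- tessellate(centroids, bounds)
  }
  seg <- dd$delsgs
  sides <- sqrt((seg$x1 - seg$x2)^2 + (seg$y1 - seg$y2)^2)
  tri <- deldir::triang.list(dd)
  if (length(tri) == 0) return(setNames(rep(NaN, 8L), nm))
  areas <- vapply(tri, function(tr) polygonArea(cbind(tr$x, tr$y)),
                  numeric(1))
  setNames(c(statSet(sides), statSet(areas)), nm)
}

# Exact Euclidean MST edge lengths via Prim's algorithm on the complete
# graph (dense implementation; optimal for complete graphs).
mstEdgeLengths <- function(centroids) {
  n <- nrow(centroids)
  D <- as.matrix(dist(centroids))
  inTree <- logical(n)
  inTree[1] <- TRUE
  best <- D[1, ]
  out <- numeric(n - 1)
  for (e in seq_len(n - 1)) {
    cand <- which(!inTree)
    j <- cand[which.min(best[cand])]
    out[e] <- best[j]
    inTree[j] <- TRUE
    upd <- D[j, ] < best
    best[upd & !inTree] <- D[j, upd & !inTree]
  }
  out
}

#' Minimum spanning tree features (4)
#'
#' Statistics of the edge lengths of the exact Euclidean minimum spanning
#' tree over the nucleus centroids. Coincident centroids are merged
#' beforehand so all edges have positive length.
#'
#' @param centroids n x 2 matrix (n >= 2).
#' @return named numeric vector of length 4.
#' @export
mstFeatures <- function(centroids) {
  nm <- mstFeatureNames()
  centroids <- mergeCoincident(centroids)
  if (nrow(centroids) < 2) return(setNames(rep(NaN, 4L), nm))
  setNames(statSet(mstEdgeLengths(centroids)), nm)
}

#' Nearest-neighbor and density features (27)
#'
#' Per-nucleus neighbor counts within radii of 10-50 px (mean, SD, disorder
#' each), distance to the 3rd/5th/7th nearest neighbor (mean, SD, disorder
#' each), global nuclear density (count / patch area) and the mean and SD of
#' the nearest-neighbor distance.
#'
#' @param centroids n x 2 matrix.
#' @param bounds patch rectangle \code{c(xmin, xmax, ymin, ymax)}.
#' @param D optional precomputed distance matrix.
#' @return named numeric vector of length 27; statistics whose neighbor
#'   order k exceeds n - 1 are NaN.
#' @export
nnFeatures <- function(centroids, bounds, D = NULL) {
  nm <- nnFeatureNames()
  n <- nrow(centroids)
  out <- rep(NaN, 27L)
  names(out) <- nm
  if (n < 2) {
    out[25] <- n / ((bounds[2] - bounds[1]) * (bounds[4] - bounds[3]))
    return(out)
  }
  if (is.null(D)) D <- as.matrix(dist(centroids))
  diag(D) <- Inf
  k <- 1L
  for (r in nnRadii) {
    cnt <- rowSums(D <= r)
    st <- statSet(cnt)
    out[k:(k + 2)] <- st[c("mean", "std", "disorder")]
    k <- k + 3L
  }
  sortedD <- apply(D, 1, sort)  # (n-1) finite values then Inf per column
  for (kk in nnKs) {
    if (n >= kk + 1L) {
      dk <- sortedD[kk, ]
      st <- statSet(dk)
      out[k:(k + 2)] <- st[c("mean", "std", "disorder")]
    }
    k <- k + 3L
  }
  area <- (bounds[2] - bounds[1]) * (bounds[4] - bounds[3])
  nn1 <- sortedD[1, ]
  out[25] <- n / area
  out[26] <- mean(nn1)
  out[27] <- popSd(nn1)
  out
}

#' Build the cell cluster graph (CCG)
#'
#' Deterministic decaying-connectivity rule: nuclei u, v are connected iff
#' \eqn{d(u,v)^{-\alpha} > r}, i.e. iff their distance is below
#' \eqn{r^{-1/\alpha}} (25 px at the defaults \eqn{\alpha = 0.5},
#' \eqn{r = 0.2}). Coincident centroids (d = 0) are treated as connected.
#'
#' @param centroids n x 2 matrix (n >= 1).
#' @param alpha decay exponent (> 0).
#' @param r edge threshold in (0, 1).
#' @param D optional precomputed distance matrix.
#' @return an \code{igraph} graph with edge attribute \code{length}.
#' @export
buildCCG <- function(centroids, alpha = 0.5, r = 0.2, D = NULL) {
  stopIfNot(alpha > 0, "CCG alpha must be > 0")
  stopIfNot(r > 0 && r < 1, "CCG r must be in (0, 1)")
  n <- nrow(centroids)
  if (is.null(D)) D <- as.matrix(dist(centroids))
  cutoff <- r^(-1 / alpha)
  A <- D < cutoff
  diag(A) <- FALSE
  if (any(D[upper.tri(D)] == 0))
    message("coincident centroids in CCG treated as connected")
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  el <- igraph::as_edgelist(g, names = FALSE)
  igraph::E(g)$length <- D[el]
  g
}

eigenExponent <- function(absEv) {
  m <- ceiling(length(absEv) / 2)
  v <- sort(absEv, decreasing = TRUE)[seq_len(m)]
  keep <- v > 1e-12
  v <- v[keep]
  if (length(v) < 2) return(0)
  lr <- log(seq_along(v))
  lv <- log(v)
  den <- sum((lr - mean(lr))^2)
  if (den == 0) return(0)
  sum((lr - mean(lr)) * (lv - mean(lv))) / den
}

#' Cell cluster graph features (39)
#'
#' Global connectivity, eccentricity, path-length, clustering-coefficient,
#' component, edge-length and adjacency-spectrum statistics of a
#' \code{\link{buildCCG}} graph. Clustering coefficient C is the global
#' transitivity, D the mean local clustering over all nodes (isolated and
#' degree-1 nodes contribute 0), E the mean local clustering over nodes of
#' degree >= 2. Edge statistics on an edgeless graph are 0 by convention.
#'
#' @param g an \code{igraph} graph with edge attribute \code{length}.
#' @return named numeric vector of length 39.
#' @export
ccgFeatures <- function(g) {
  nm <- ccgFeatureNames()
  n <- igraph::vcount(g)
  ne <- igraph::ecount(g)
  out <- setNames(numeric(39L), nm)
  out[1] <- n
  out[2] <- ne
  out[3] <- if (n > 1) 2 * ne / (n * (n - 1)) else 0
  deg <- igraph::degree(g)
  ds <- statSet(deg)
  out[4:6] <- ds[c("mean", "std", "disorder")]
  comp <- igraph::components(g)
  giant <- which.max(comp$csize)
  gv <- which(comp$membership == giant)
  sub <- igraph::induced_subgraph(g, gv)
  if (igraph::vcount(sub) > 1) {
    ecc <- igraph::eccentricity(sub)
    out[7] <- mean(ecc)
    out[8] <- popSd(ecc)
    out[9] <- max(ecc)
    out[10] <- min(ecc)
    e90 <- ecc[ecc <= quantile(ecc, 0.9)]
    out[11] <- mean(e90)
    out[12] <- max(e90)
    out[13] <- min(e90)
    dm <- igraph::distances(sub)
    pl <- dm[upper.tri(dm)]
    out[14] <- mean(pl)
    out[15] <- popSd(pl)
  }
  tr <- igraph::transitivity(g, type = "global")
  out[16] <- if (is.nan(tr)) 0 else tr
  loc <- igraph::transitivity(g, type = "local", isolates = "zero")
  out[17] <- if (n > 0) mean(loc) else 0
  hi <- deg >= 2
  out[18] <- if (any(hi)) mean(loc[hi]) else 0
  out[19] <- comp$no
  out[20] <- if (n > 0) max(comp$csize) / n else 0
  out[21] <- mean(comp$csize)
  out[22] <- popSd(comp$csize)
  out[23] <- sum(deg == 0)
  out[24] <- if (n > 0) sum(deg == 0) / n else 0
  out[25] <- sum(deg == 1)
  out[26] <- if (n > 0) sum(deg == 1) / n else 0
  # central nodes: eccentricity equal to the radius of their own component
  central <- 0L
  for (ci in seq_len(comp$no)) {
    vs <- which(comp$membership == ci)
    if (length(vs) == 1) { central <- central + 1L; next }
    sg <- igraph::induced_subgraph(g, vs)
    ec <- igraph::eccentricity(sg)
    central <- central + sum(ec == min(ec))
  }
  out[27] <- central
  out[28] <- if (n > 0) central / n else 0
  if (ne > 0) {
    len <- igraph::E(g)$length
    ls <- statSet(len)
    out[29:32] <- ls
    out[33] <- popSkewness(len)
    out[34] <- popKurtosis(len)
  }
  if (n > 0) {
    A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    absEv <- abs(ev)
    srt <- sort(absEv, decreasing = TRUE)
    out[35] <- srt[1]
    out[36] <- if (n > 1) srt[2] else 0
    out[37] <- sum(absEv)
    sv <- sort(ev)
    out[38] <- if (n == 1) 1 else sum(diff(sv) > 1e-8) + 1
    out[39] <- eigenExponent(absEv)
  }
  out
}

log2z <- function(p) ifelse(p > 0, log2(p), 0)

# The 13 second-order (co-occurrence) statistics of a normalized 8x8 matrix.
haralickStats <- function(P) {
  nb <- nrow(P)
  i <- row(P); j <- col(P)
  pxv <- rowSums(P); pyv <- colSums(P)
  ks <- 0:(nb - 1)
  pdiff <- vapply(ks, function(k) sum(P[abs(i - j) == k]), numeric(1))
  ss <- 2:(2 * nb)
  psum <- vapply(ss, function(s) sum(P[(i + j) == s]), numeric(1))
  ca <- sum(ks * pdiff)
  ia <- sum(ss * psum)
  mux <- sum(seq_len(nb) * pxv); muy <- sum(seq_len(nb) * pyv)
  sx <- sqrt(sum((seq_len(nb) - mux)^2 * pxv))
  sy <- sqrt(sum((seq_len(nb) - muy)^2 * pyv))
  corr <- if (sx > 0 && sy > 0)
    (sum(i * j * P) - mux * muy) / (sx * sy) else 0
  HXY <- -sum(P * log2z(P))
  HX <- -sum(pxv * log2z(pxv))
  HY <- -sum(pyv * log2z(pyv))
  pipj <- outer(pxv, pyv)
  HXY1 <- -sum(P * log2z(pipj))
  HXY2 <- -sum(pipj * log2z(pipj))
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (HXY2 - HXY))))
  setNames(
    c(sum(ks^2 * pdiff),
      sum(pdiff / (1 + ks^2)),
      ca,
      sum((ks - ca)^2 * pdiff),
      -sum(pdiff * log2z(pdiff)),
      ia,
      sum((ss - ia)^2 * psum),
      -sum(psum * log2z(psum)),
      HXY,
      sum(P^2),
      corr,
      imc1,
      imc2),
    coreStatNames)
}

orientationCooccurrence <- function(bins, edges, nb = 8L) {
  P <- matrix(0, nb, nb)
  if (nrow(edges) > 0) {
    bi <- bins[edges[, 1]]; bj <- bins[edges[, 2]]
    for (e in seq_along(bi)) {
      P[bi[e], bj[e]] <- P[bi[e], bj[e]] + 1
      P[bj[e], bi[e]] <- P[bj[e], bi[e]] + 1
    }
    P <- P / sum(P)
  }
  P
}

#' Cell orientation co-occurrence entropy features (COrE, 26)
#'
#' Quantizes nuclear orientations into 8 bins of 22.5 degrees on [0, 180),
#' builds the symmetric orientation co-occurrence matrix over pairs of
#' connected nuclei for two neighbor definitions (the CCG edge set and a
#' 40 px proximity graph), and computes 13 second-order statistics per
#' matrix. A graph with no edges yields all-zero statistics for its variant.
#'
#' @param centroids n x 2 matrix (n >= 5).
#' @param orientationsDeg per-nucleus orientation in degrees on [0, 180).
#' @param ccg optional precomputed \code{\link{buildCCG}} graph.
#' @param D optional precomputed distance matrix.
#' @return named numeric vector of length 26.
#' @export
coreFeatures <- function(centroids, orientationsDeg, ccg = NULL, D = NULL) {
  stopIfNot(length(orientationsDeg) == nrow(centroids),
            "orientations must align with centroids")
  if (any(!is.finite(orientationsDeg)))
    stop("every nucleus needs a finite orientation", call. = FALSE)
  bins <- pmin(floor((orientationsDeg %% 180) / 22.5) + 1L, 8L)
  if (is.null(D)) D <- as.matrix(dist(centroids))
  if (is.null(ccg)) ccg <- buildCCG(centroids, D = D)
  edgesCCG <- igraph::as_edgelist(ccg, names = FALSE)
  prox <- which(D <= corePxRadius & upper.tri(D), arr.ind = TRUE)
  out <- c(haralickStats(orientationCooccurrence(bins, edgesCCG)),
           haralickStats(orientationCooccurrence(bins, prox)))
  setNames(out, coreFeatureNames())
}

#' The 116-feature architecture vector of one compartment
#'
#' Concatenates the Voronoi (12), Delaunay (8), MST (4), nearest-neighbor
#' (27), cell-cluster-graph (39) and orientation co-occurrence (26) feature
#' blocks in fixed catalog order. Compartments with fewer than
#' \code{minNuclei} nuclei yield an all-NaN vector; degenerate geometry in an
#' individual block (e.g. too few interior Voronoi cells) yields NaN for that
#' block only.
#'
#' @param centroids n x 2 matrix of the compartment's nucleus centroids.
#' @param orientationsDeg aligned orientations in degrees.
#' @param bounds patch rectangle \code{c(xmin, xmax, ymin, ymax)}.
#' @param minNuclei minimum nuclei required (default 5).
#' @param ccgParams list with \code{alpha} and \code{r} for
#'   \code{\link{buildCCG}}.
#' @param prefix optional compartment prefix for feature names.
#' @return named numeric vector of length 116.
#' @export
architectureVector <- function(centroids, orientationsDeg, bounds,
                               minNuclei = 5L,
                               ccgParams = list(alpha = 0.5, r = 0.2),
                               prefix = NULL) {
  nm <- architectureFeatureNames(prefix)
  if (nrow(centroids) < minNuclei) return(setNames(rep(NaN, 116L), nm))
  keep <- coincidentKeepIndex(centroids)
  centroids <- centroids[keep, , drop = FALSE]
  orientationsDeg <- orientationsDeg[keep]
  D <- as.matrix(dist(centroids))
  dd <- tryCatch(tessellate(centroids, bounds), error = function(e) NULL)
  vor <- tryCatch(voronoiFeatures(centroids, bounds, dd = dd),
                  error = function(e) rep(NaN, 12L))
  del <- tryCatch(delaunayFeatures(centroids, dd = dd),
                  error = function(e) rep(NaN, 8L))
  mst <- mstFeatures(centroids)
  nn <- nnFeatures(centroids, bounds, D = D)
  ccg <- buildCCG(centroids, alpha = ccgParams$alpha, r = ccgParams$r, D = D)
  cf <- ccgFeatures(ccg)
  core <- coreFeatures(centroids, orientationsDeg, ccg = ccg, D = D)
  setNames(c(vor, del, mst, nn, cf, core), nm)
}
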