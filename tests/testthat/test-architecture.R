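gridCentroids <- function(n, spacing = 1) {
  g <- expand.grid(x = seq_len(n) - 1, y = seq_len(n) - 1) * spacing
  as.matrix(g)
}

test_that("Voronoi features: congruent interior cells of a grid, and degeneracy", {
  cen <- gridCentroids(6)
  v <- voronoiFeatures(cen, bounds = c(0, 5, 0, 5))
  expect_equal(unname(v[1:4]), c(1, 0, 1, 0), tolerance = 1e-9)
  expect_error(voronoiFeatures(cbind(0:9, 0:9), bounds = c(0, 9, 0, 9)),
               "collinear")
})

test_that("jitter strictly increases Voronoi area disorder relative to a grid", {
  cen <- gridCentroids(8, spacing = 10)
  bounds <- c(0, 70, 0, 70)
  base <- voronoiFeatures(cen, bounds)
  withr::with_seed(11, {
    for (i in 1:10) {
      jit <- cen + matrix(runif(nrow(cen) * 2, -3, 3), ncol = 2)
      vj <- voronoiFeatures(jit, bounds + c(-5, 5, -5, 5))
      expect_gt(vj[["Voronoi: Disorder Cell Area"]],
                base[["Voronoi: Disorder Cell Area"]])
    }
  })
})

test_that("Delaunay features match hand geometry and the Euler identity", {
  tri <- cbind(c(0, 1, 0), c(0, 0, 1))
  d <- delaunayFeatures(tri)
  expect_equal(d[["Delaunay: Mean Side Length"]], (2 + sqrt(2)) / 3,
               tolerance = 1e-9)
  expect_equal(d[["Delaunay: Mean Triangle Area"]], 0.5, tolerance = 1e-9)
  # triangle count of a Delaunay triangulation is 2n - 2 - h
  withr::with_seed(21, {
    for (i in 1:25) {
      n <- sample(5:30, 1)
      cen <- cbind(runif(n, 0, 100), runif(n, 0, 100))
      dd <- deldir::deldir(cen[, 1], cen[, 2], suppressMsge = TRUE)
      nTri <- length(deldir::triang.list(dd))
      h <- length(grDevices::chull(cen))
      expect_equal(nTri, 2 * n - 2 - h)
    }
  })
  # equilateral (hexagonal) lattice: all sides equal, disorder ~ 0
  hexpts <- as.matrix(expand.grid(i = 0:4, j = 0:4))
  hex <- cbind(hexpts[, 1] * 10 + hexpts[, 2] * 5, hexpts[, 2] * 10 * sqrt(3) / 2)
  dh <- delaunayFeatures(hex)
  expect_lte(dh[["Delaunay: Disorder Side Length"]], 1e-8)
})

test_that("MST features: collinear chain, edge count, exhaustive minimality", {
  m <- mstFeatures(cbind(c(0, 1, 2), c(0, 0, 0)))
  expect_equal(unname(m), c(1, 0, 1, 0))
  # n points -> n - 1 edges, total equals brute-force min over all labeled
  # spanning trees (enumerated via Pruefer sequences; helper)
  withr::with_seed(33, {
    for (i in 1:30) {
      n <- sample(4:7, 1)
      trees <- pruferTrees(n)
      cen <- cbind(runif(n, 0, 50), runif(n, 0, 50))
      D <- as.matrix(dist(cen))
      bruteMin <- min(vapply(trees, function(e) sum(D[e]), numeric(1)))
      lens <- nucmorph:::mstEdgeLengths(cen)
      expect_length(lens, n - 1)
      expect_equal(sum(lens), bruteMin, tolerance = 1e-9)
    }
  })
})

test_that("nearest-neighbor features match direct counting on a grid", {
  cen <- gridCentroids(10)
  bounds <- c(-0.5, 9.5, -0.5, 9.5)
  v <- nnFeatures(cen, bounds)
  # r = 10 reaches all but the far corners from central points
  expect_lte(v[["Arch: Disorder of Nearest Neighbors in a 10 Pixel Radius"]],
             0.1)
  D <- as.matrix(dist(cen)); diag(D) <- Inf
  expect_equal(v[["Arch: Avg. Nearest Neighbors in a 10 Pixel Radius"]],
               mean(rowSums(D <= 10)))
  # oracle equality for the k-th nearest neighbor distances
  for (k in c(3, 5, 7)) {
    dk <- apply(D, 1, function(r) sort(r)[k])
    expect_equal(
      v[[sprintf("Arch: Avg. Distance to %d Nearest Neighbors", k)]],
      mean(dk))
  }
  expect_equal(v[["Arch: Nuclear Density"]], 100 / 100)
  # radius below the minimal spacing: all counts zero
  sparse <- gridCentroids(4, spacing = 100)
  v2 <- nnFeatures(sparse, c(0, 300, 0, 300))
  expect_equal(v2[["Arch: Avg. Nearest Neighbors in a 50 Pixel Radius"]], 0)
})

test_that("CCG edge rule follows the distance-decay threshold", {
  # d = 10: 10^-0.5 ~ 0.316 > 0.2 -> edge; d = 100: 0.1 < 0.2 -> none
  g1 <- buildCCG(cbind(c(0, 10), c(0, 0)))
  expect_equal(igraph::ecount(g1), 1)
  g2 <- buildCCG(cbind(c(0, 100), c(0, 0)))
  expect_equal(igraph::ecount(g2), 0)
  cen <- cbind(runif(20, 0, 60), runif(20, 0, 60))
  expect_identical(igraph::as_edgelist(buildCCG(cen)),
                   igraph::as_edgelist(buildCCG(cen)))
})

test_that("CCG features match hand computation on canonical graphs", {
  f <- ccgFeatures(buildCCG(cbind(c(0, 10, 5), c(0, 0, 8))))
  expect_equal(unname(f[c("CCG: Clustering Coefficient C",
                          "CCG: Clustering Coefficient D",
                          "CCG: Clustering Coefficient E",
                          "CCG: Diameter")]), c(1, 1, 1, 1))
  # path graph a-b-c
  fp <- ccgFeatures(buildCCG(cbind(c(0, 20, 40), c(0, 0, 0))))
  expect_equal(unname(fp[c("CCG: Clustering Coefficient C",
                           "CCG: Number of End Nodes",
                           "CCG: Number of Central Nodes")]), c(0, 2, 1))
  # 5 isolated nodes
  fi <- ccgFeatures(buildCCG(gridCentroids(5, spacing = 1000)[1:5, ]))
  expect_equal(unname(fi[c("CCG: Number of Connected Components",
                           "CCG: Fraction of Isolated Nodes",
                           "CCG: Graph Density")]), c(5, 1, 0))
})

test_that("orientation co-occurrence statistics behave at the ordered and uniform extremes", {
  withr::with_seed(8, {
    cen <- cbind(runif(40, 0, 40), runif(40, 0, 40))  # dense: CCG-connected
    sameOri <- rep(45, 40)
    f <- coreFeatures(cen, sameOri)
    expect_equal(f[["COrE: CCG Entropy"]], 0)
    expect_equal(f[["COrE: CCG Energy"]], 1)
    expect_equal(f[["COrE: CCG Contrast Energy"]], 0)
    # uniform orientations on an (almost) complete graph: entropy near
    # log2(64) bits
    cen2 <- cbind(runif(500, 0, 20), runif(500, 0, 20))
    ori2 <- runif(500, 0, 180)
    f2 <- coreFeatures(cen2, ori2)
    expect_equal(f2[["COrE: CCG Entropy"]], log2(64), tolerance = 0.05)
  })
})

test_that("orientation coherence lowers co-occurrence entropy in nearly all seeded pairs", {
  coherent <- nucleiPhenotype(orientationKappa = 5)
  incoherent <- nucleiPhenotype(orientationKappa = 0)
  hits <- 0L
  for (s in 1:100) {
    cen <- withr::with_seed(s, cbind(runif(50, 0, 60), runif(50, 0, 60)))
    oc <- vapply(1:50, function(i)
      synthesizeNucleusBoundary(c(0, 0), coherent,
                                seed = s * 977 + i)$orientationDeg,
      numeric(1))
    oi <- vapply(1:50, function(i)
      synthesizeNucleusBoundary(c(0, 0), incoherent,
                                seed = s * 977 + i)$orientationDeg,
      numeric(1))
    ec <- coreFeatures(cen, oc)[["COrE: CCG Entropy"]]
    ei <- coreFeatures(cen, oi)[["COrE: CCG Entropy"]]
    if (ec < ei) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("architectureVector honors the catalog contract and NaN policy", {
  withr::with_seed(3, {
    cen <- cbind(runif(40, 5, 195), runif(40, 5, 195))
    ori <- runif(40, 0, 180)
  })
  bounds <- c(0, 200, 0, 200)
  v <- architectureVector(cen, ori, bounds)
  expect_length(v, 116L)
  expect_true(all(is.finite(v)))
  expect_identical(v, architectureVector(cen, ori, bounds))
  expect_true(all(is.nan(architectureVector(cen[1:4, ], ori[1:4], bounds))))
})

test_that("architecture features are translation invariant and length statistics rotation invariant", {
  withr::with_seed(14, {
    cen <- cbind(runif(35, 30, 170), runif(35, 30, 170))
    ori <- runif(35, 0, 180)
  })
  bounds <- c(0, 200, 0, 200)
  v0 <- architectureVector(cen, ori, bounds)
  sh <- c(7.25, -4.5)
  v1 <- architectureVector(sweep(cen, 2, -sh), ori,
                           bounds + c(sh[1], sh[1], sh[2], sh[2]))
  expect_equal(v0, v1, tolerance = 1e-9)
  lengthStats <- grep(
    "MST|Delaunay|Arch: |CCG: mean edge|CCG: standard deviation edge",
    names(v0), value = TRUE)
  rot90 <- cbind(200 - cen[, 2], cen[, 1])
  v90 <- architectureVector(rot90, (ori + 90) %% 180, bounds)
  expect_equal(v0[lengthStats], v90[lengthStats], tolerance = 1e-9)
  th <- 37 * pi / 180
  cenR <- sweep(cen, 2, c(100, 100))
  cenR <- cenR %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  cenR <- sweep(cenR, 2, c(100, 100), `+`)
  vR <- architectureVector(cenR, ori, bounds)
  free <- grep("MST|Delaunay: Mean Side|Arch: Avg. Distance|CCG: mean edge",
               names(v0), value = TRUE)
  expect_equal(v0[free], vR[free], tolerance = 1e-6)
})
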