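test_that("centroid sampling is seeded-deterministic and respects zero intensities", {
  ph <- nucleiPhenotype()
  a <- sampleCentroids(ph, 200, "epithelial", seed = 5)
  b <- sampleCentroids(ph, 200, "epithelial", seed = 5)
  expect_identical(a, b)
  expect_false(identical(a$points,
                         sampleCentroids(ph, 200, "epithelial", seed = 6)$points))
  empty <- nucleiPhenotype(clusterIntensity = 0, stromalIntensity = 0)
  expect_equal(nrow(sampleCentroids(empty, 200, "epithelial", seed = 1)$points), 0)
  expect_equal(nrow(sampleCentroids(empty, 200, "stromal", seed = 1)$points), 0)
  bad <- nucleiPhenotype()
  bad@stromalIntensity <- NaN
  expect_error(sampleCentroids(bad, 200, "stromal", seed = 1), "invalid")
})

test_that("stromal counts follow the Poisson mean over the free area", {
  lambda <- 5000  # per mm^2
  ph <- nucleiPhenotype(clusterIntensity = 0, stromalIntensity = lambda)
  size <- 200
  # the sampler places stromal nuclei with a 3 px margin on each side
  freeAreaMm2 <- ((size - 7) / 4000)^2
  expected <- lambda * freeAreaMm2
  counts <- vapply(1:500, function(s)
    nrow(sampleCentroids(ph, size, "stromal", seed = s)$points), numeric(1))
  expect_lt(abs(mean(counts) - expected), 3 * sqrt(expected))
})

test_that("nucleus boundaries reproduce analytic circles and ellipses", {
  circle <- nucleiPhenotype(axisRatioMean = 1, axisRatioSd = 0,
                            boundaryIrregularity = 0, meanRadiusPx = 9)
  nb <- synthesizeNucleusBoundary(c(50, 50), circle, seed = 3)
  expect_equal(polygonArea(nb$polygon), pi * 81, tolerance = 0.01)
  expect_true(polygonIsSimple(nb$polygon))
  ell <- nucleiPhenotype(axisRatioMean = 2, axisRatioSd = 0,
                         boundaryIrregularity = 0)
  nb2 <- synthesizeNucleusBoundary(c(0, 0), ell, seed = 4)
  lw <- shapeDescriptors(nb2$polygon)[["length_width_ratio"]]
  expect_equal(lw, 2, tolerance = 0.02)
  expect_identical(synthesizeNucleusBoundary(c(0, 0), ell, seed = 9),
                   synthesizeNucleusBoundary(c(0, 0), ell, seed = 9))
  degen <- nucleiPhenotype()
  degen@meanRadiusPx <- 0
  expect_error(synthesizeNucleusBoundary(c(0, 0), degen, seed = 1),
               "meanRadiusPx")
})

test_that("generateCohort delivers the configured structure, deterministically", {
  cfg <- cohortConfig(nPatientsPerClass = 3L, patchesPerPatient = 2L,
                      seed = 41L)
  coh <- suppressMessages(generateCohort(cfg))
  expect_equal(nrow(cases(coh)), 6L)
  expect_length(patches(coh), 12L)
  expect_setequal(unique(cases(coh)$class), c("low", "high"))
  # scores consistent with the categorization rule by construction
  cs <- cases(coh)
  expect_identical(cs$odx_category, categorizeOdx(cs$odx_score))
  expect_true(all(cs$odx_category[cs$class == "low"] == "low"))
  expect_true(all(cs$odx_category[cs$class == "high"] == "high"))
  # min-nuclei constraint honored in both compartments
  for (p in patches(coh)) {
    tab <- table(factor(compartments(p), levels = c("epithelial", "stromal")))
    expect_true(all(tab >= 12L))
  }
  coh2 <- suppressMessages(generateCohort(cfg))
  expect_identical(cases(coh), cases(coh2))
  expect_identical(centroids(patches(coh)[[1]]), centroids(patches(coh2)[[1]]))
})

test_that("every epithelial centroid lies inside the epithelium mask", {
  cfg <- cohortConfig(nPatientsPerClass = 2L, patchesPerPatient = 2L,
                      seed = 51L)
  coh <- suppressMessages(generateCohort(cfg))
  for (p in patches(coh)) {
    cen <- centroids(p, compartment = "epithelial")
    idx <- cbind(pmin(pmax(round(cen[, 1]), 0), p@width - 1) + 1L,
                 pmin(pmax(round(cen[, 2]), 0), p@height - 1) + 1L)
    expect_true(all(p@epitheliumMask[idx]))
    # and stromal centroids lie outside it
    cs <- centroids(p, compartment = "stromal")
    idxS <- cbind(round(cs[, 1]) + 1L, round(cs[, 2]) + 1L)
    expect_true(all(!p@epitheliumMask[idxS]))
  }
})

test_that("increasing cluster spread increases epithelial neighbor disorder", {
  feat <- "Arch: Disorder of Nearest Neighbors in a 40 Pixel Radius"
  spreads <- seq(8, 60, length.out = 200)
  vals <- vapply(seq_along(spreads), function(i) {
    ph <- nucleiPhenotype(clusterSpread = spreads[i])
    pts <- sampleCentroids(ph, 300, "epithelial", seed = 1000 + i)$points
    if (nrow(pts) < 8) return(NA_real_)
    nnFeatures(pts, c(0, 300, 0, 300))[[feat]]
  }, numeric(1))
  ok <- is.finite(vals)
  expect_gt(cor(spreads[ok], vals[ok], method = "spearman"), 0.5)
})

test_that("rendering produces the documented image and exact label masks", {
  empty <- NucleiPatch(list(), width = 50, height = 50)
  r0 <- renderPatch(empty, noiseSd = 0)
  expect_equal(length(unique(as.vector(r0$image))), 3L)  # flat background
  expect_true(all(r0$labels == 0L))
  disc <- NucleiPatch(list(regularPolygon(25, 25, r = 8)), 50, 50)
  r1 <- renderPatch(disc, noiseSd = 0)
  ncomp <- max(EBImage::bwlabel(EBImage::Image((r1$labels > 0) * 1)))
  expect_equal(ncomp, 1L)
})

test_that("rendered patches re-segment to the true nucleus count", {
  ph <- nucleiPhenotype(boundaryIrregularity = 0.05, axisRatioMean = 1.3,
                        meanRadiusPx = 8)
  centersGrid <- as.matrix(expand.grid(x = seq(25, 175, by = 50),
                                       y = seq(25, 175, by = 50)))
  hits <- 0L
  for (s in 1:100) {
    polys <- lapply(seq_len(nrow(centersGrid)), function(i)
      synthesizeNucleusBoundary(centersGrid[i, ], ph,
                                seed = s * 131 + i)$polygon)
    patch <- NucleiPatch(polys, 200, 200, checkSimple = FALSE)
    lab <- segmentNucleiClassical(renderPatch(patch, noiseSd = 0)$image)
    if (max(lab) == nrow(centersGrid)) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})
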