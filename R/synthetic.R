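# Seeded synthetic nuclei cohorts: compartmentalized patches with tunable
# architectural disorder, nuclear pleomorphism and orientation coherence.
# Pixel scale: nominal 40x, 4000 px/mm (0.25 um/px).

pxPerMm <- 4000

#' Sample one angle from a von Mises distribution centered at 0
#' (Best-Fisher rejection sampler; kappa = 0 falls back to uniform).
#' @keywords internal
rVonMises1 <- function(kappa) {
  if (kappa < 1e-6) return(runif(1, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  repeat {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0)
      return(sign(u[3] - 0.5) * acos(pmin(1, pmax(-1, f))))
  }
}

checkPhenotype <- function(phenotype) {
  v <- validObject(phenotype, test = TRUE)
  if (!isTRUE(v))
    stop("invalid phenotype parameters: ", paste(v, collapse = "; "),
         call. = FALSE)
}

maskFromClusters <- function(parents, offspring, clusterId, sizePx,
                             dilationRadius) {
  mask <- matrix(FALSE, sizePx, sizePx)
  stamp <- function(pts) {
    px <- pmin(pmax(round(pts[, 1]), 0), sizePx - 1) + 1L
    py <- pmin(pmax(round(pts[, 2]), 0), sizePx - 1) + 1L
    mask[cbind(px, py)] <<- TRUE
  }
  if (nrow(offspring) > 0) stamp(offspring)
  if (nrow(parents) > 0) stamp(parents)
  for (ci in unique(clusterId)) {
    pts <- offspring[clusterId == ci, , drop = FALSE]
    if (nrow(pts) >= 3) {
      h <- grDevices::chull(pts)
      hull <- pts[h, , drop = FALSE]
      if (checkNonCollinear(hull)) {
        pix <- polygonPixelCenters(hull)
        keep <- pix[, 1] >= 0 & pix[, 1] < sizePx &
          pix[, 2] >= 0 & pix[, 2] < sizePx
        pix <- pix[keep, , drop = FALSE]
        if (nrow(pix) > 0) mask[cbind(pix[, 1] + 1L, pix[, 2] + 1L)] <- TRUE
      }
    }
  }
  if (any(mask)) {
    brushSize <- 2 * round(dilationRadius) + 1
    img <- EBImage::dilate(EBImage::Image(mask * 1),
                           EBImage::makeBrush(brushSize, shape = "disc"))
    mask <- EBImage::imageData(img) > 0.5
  }
  mask
}

#' Sample nucleus centroids for one compartment of a synthetic patch
#'
#' Epithelial centroids follow a parent-offspring (Thomas-type) cluster
#' process: nest centers are homogeneous Poisson with intensity
#' \code{clusterIntensity} per mm^2, offspring counts are Poisson with mean
#' \code{nucleiPerClusterMean} and offspring positions Gaussian around the
#' nest center with SD \code{clusterSpread}, plus uniform placement jitter.
#' The epithelium mask is the union of the dilated nest hulls (dilation
#' radius two nuclear radii), so every epithelial centroid lies inside it.
#' Stromal centroids are homogeneous Poisson with intensity
#' \code{stromalIntensity} per mm^2 thinned to the region outside the
#' epithelium mask. Points falling outside the patch are discarded.
#'
#' @param phenotype a \linkS4class{NucleiPhenotype}.
#' @param patchSizePx square patch edge length (px), > 0.
#' @param compartment \code{"epithelial"} or \code{"stromal"}.
#' @param seed integer seed; the draw is fully deterministic given it.
#' @param epitheliumMask for the stromal compartment: the logical mask to
#'   avoid (defaults to none).
#' @return list with \code{points} (n x 2 matrix) and \code{mask} (logical
#'   \code{patchSizePx} x \code{patchSizePx} matrix, indexed [x+1, y+1]).
#' @export
sampleCentroids <- function(phenotype, patchSizePx,
                            compartment = c("epithelial", "stromal"),
                            seed = 1L, epitheliumMask = NULL) {
  compartment <- match.arg(compartment)
  checkPhenotype(phenotype)
  stopIfNot(patchSizePx > 0, "patchSizePx must be > 0")
  areaMm2 <- (patchSizePx / pxPerMm)^2
  withSeed(seed, {
    if (compartment == "epithelial") {
      nPar <- rpois(1, phenotype@clusterIntensity * areaMm2)
      parents <- cbind(runif(nPar, 0, patchSizePx),
                       runif(nPar, 0, patchSizePx))
      counts <- if (nPar > 0) rpois(nPar, phenotype@nucleiPerClusterMean)
      else integer(0)
      total <- sum(counts)
      if (total > 0) {
        cid <- rep(seq_len(nPar), counts)
        pts <- parents[cid, , drop = FALSE] +
          matrix(rnorm(2 * total, 0, phenotype@clusterSpread), total, 2) +
          matrix(runif(2 * total, -phenotype@placementJitter,
                       phenotype@placementJitter), total, 2)
        # 3 px margin: the area centroid of an irregular boundary can
        # drift a couple of px from the sampled center
        keep <- pts[, 1] >= 3 & pts[, 1] <= patchSizePx - 4 &
          pts[, 2] >= 3 & pts[, 2] <= patchSizePx - 4
        pts <- pts[keep, , drop = FALSE]
        cid <- cid[keep]
      } else {
        pts <- matrix(numeric(0), 0, 2)
        cid <- integer(0)
      }
      mask <- maskFromClusters(parents, pts, cid, patchSizePx,
                               dilationRadius = 2 * phenotype@meanRadiusPx)
      list(points = pts, mask = mask)
    } else {
      n <- rpois(1, phenotype@stromalIntensity * areaMm2)
      pts <- cbind(runif(n, 3, patchSizePx - 4),
                   runif(n, 3, patchSizePx - 4))
      if (!is.null(epitheliumMask) && length(epitheliumMask) && n > 0) {
        px <- pmin(pmax(round(pts[, 1]), 0), patchSizePx - 1) + 1L
        py <- pmin(pmax(round(pts[, 2]), 0), patchSizePx - 1) + 1L
        inside <- epitheliumMask[cbind(px, py)]
        pts <- pts[!inside, , drop = FALSE]
      }
      mask <- if (is.null(epitheliumMask))
        matrix(FALSE, patchSizePx, patchSizePx) else epitheliumMask
      list(points = pts, mask = mask)
    }
  })
}

#' Synthesize one nucleus boundary polygon
#'
#' An ellipse of equivalent radius \code{meanRadiusPx} (area preserved at
#' pi r^2 regardless of axis ratio), with axis ratio drawn from the
#' phenotype's distribution (truncated at 1), orientation drawn from an
#' axial von Mises centered at 0 with concentration
#' \code{orientationKappa}, and the radius perturbed by a random low-order
#' harmonic (orders 3-6) of total amplitude \code{boundaryIrregularity}
#' (a fraction of the radius, so the polygon stays star-shaped and simple).
#'
#' @param center length-2 numeric centroid (px).
#' @param phenotype a \linkS4class{NucleiPhenotype}.
#' @param seed integer seed.
#' @param compartment \code{"epithelial"} or \code{"stromal"}; the stromal
#'   shape overrides of the phenotype (if set) apply to stromal nuclei.
#' @param nVertices polygon resolution.
#' @return list with \code{polygon} (nVertices x 2 matrix) and
#'   \code{orientationDeg} in [0, 180).
#' @export
synthesizeNucleusBoundary <- function(center, phenotype, seed = 1L,
                                      compartment = "epithelial",
                                      nVertices = 64L) {
  checkPhenotype(phenotype)
  r0 <- phenotype@meanRadiusPx
  stopIfNot(r0 > 0, "meanRadiusPx must be > 0")
  arMean <- phenotype@axisRatioMean
  arSd <- phenotype@axisRatioSd
  irr <- phenotype@boundaryIrregularity
  if (compartment == "stromal") {
    if (!is.na(phenotype@stromalAxisRatioMean))
      arMean <- phenotype@stromalAxisRatioMean
    if (!is.na(phenotype@stromalAxisRatioSd))
      arSd <- phenotype@stromalAxisRatioSd
    if (!is.na(phenotype@stromalBoundaryIrregularity))
      irr <- phenotype@stromalBoundaryIrregularity
  }
  withSeed(seed, {
    ratio <- max(1, rnorm(1, arMean, arSd))
    theta <- rVonMises1(phenotype@orientationKappa)
    orientationDeg <- (theta * 90 / pi) %% 180
    phi <- 2 * pi * (seq_len(nVertices) - 1) / nVertices
    a <- r0 * sqrt(ratio)
    b <- r0 / sqrt(ratio)
    rad <- a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
    if (irr > 0) {
      orders <- 3:6
      amp <- abs(rnorm(length(orders)))
      if (sum(amp) == 0) amp <- rep(1, length(orders))
      amp <- amp / sum(amp) * irr
      phase <- runif(length(orders), 0, 2 * pi)
      pert <- rowSums(vapply(seq_along(orders), function(m)
        amp[m] * cos(orders[m] * phi + phase[m]), numeric(nVertices)))
      rad <- rad * (1 + pert)
    }
    poly <- cbind(rad * cos(phi), rad * sin(phi))
    poly <- rotatePoints(poly, orientationDeg)
    poly <- sweep(poly, 2, center, `+`)
    list(polygon = poly, orientationDeg = orientationDeg)
  })
}

#' Generate one synthetic patch
#'
#' @param phenotype a \linkS4class{NucleiPhenotype}.
#' @param patchSizePx patch edge (px).
#' @param seed integer seed.
#' @param patchId,patientId identifiers for the resulting patch.
#' @return a \linkS4class{NucleiPatch} with ground-truth compartments and
#'   epithelium mask.
#' @export
generatePatch <- function(phenotype, patchSizePx, seed = 1L,
                          patchId = "patch", patientId = "patient") {
  epi <- sampleCentroids(phenotype, patchSizePx, "epithelial",
                         seed = deriveSeed(seed, 1L))
  str <- sampleCentroids(phenotype, patchSizePx, "stromal",
                         seed = deriveSeed(seed, 2L),
                         epitheliumMask = epi$mask)
  pts <- rbind(epi$points, str$points)
  comp <- c(rep("epithelial", nrow(epi$points)),
            rep("stromal", nrow(str$points)))
  polys <- vector("list", nrow(pts))
  ori <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    nb <- synthesizeNucleusBoundary(pts[i, ], phenotype,
                                    seed = deriveSeed(seed, 3L, i),
                                    compartment = comp[i])
    polys[[i]] <- nb$polygon
    ori[i] <- nb$orientationDeg
  }
  NucleiPatch(polys, width = patchSizePx, height = patchSizePx,
              patchId = patchId, patientId = patientId,
              compartment = comp, orientation_deg = ori,
              epitheliumMask = epi$mask, checkSimple = FALSE)
}

#' Generate a synthetic two-class cohort
#'
#' Simulates \code{nPatientsPerClass} patients per risk class; each
#' patient's patches share the patient's class phenotype, the ODx score is
#' drawn uniformly from the class's integer score interval (so the category
#' derived by \code{\link{categorizeOdx}} is consistent by construction) and
#' the mBR score from the class's grade interval. A patch must carry at
#' least \code{minNuclei} nuclei in each compartment; otherwise it is
#' regenerated with a derived sub-seed (at most 20 retries, then an error
#' naming the phenotype class).
#'
#' @param config a \linkS4class{CohortConfig}.
#' @return a \linkS4class{HistoCohort}; \code{cases(x)$class} holds the
#'   ground-truth phenotype class.
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  phenos <- list(low = config@lowPhenotype, high = config@highPhenotype)
  cases <- list()
  allPatches <- list()
  for (ci in 1:2) {
    cls <- c("low", "high")[ci]
    for (i in seq_len(config@nPatientsPerClass)) {
      pid <- sprintf("%s_P%02d", cls, i)
      sr <- config@odxScoreRanges[[cls]]
      mr <- config@mbrScoreRanges[[cls]]
      odx <- withSeed(deriveSeed(config@seed, ci, i, 9001L),
                      sample(sr[1]:sr[2], 1))
      mbr <- withSeed(deriveSeed(config@seed, ci, i, 9002L),
                      sample(mr[1]:mr[2], 1))
      cases[[pid]] <- data.frame(
        patient_id = pid, class = cls, odx_score = odx,
        odx_category = categorizeOdx(odx), mbr_score = mbr,
        mbr_category = categorizeMbr(mbr), stringsAsFactors = FALSE)
      for (j in seq_len(config@patchesPerPatient)) {
        patchId <- sprintf("%s_patch%02d", pid, j)
        patch <- NULL
        for (attempt in 0:20) {
          cand <- generatePatch(
            phenos[[cls]], config@patchSizePx,
            seed = deriveSeed(config@seed, ci, i, j * 100L + attempt),
            patchId = patchId, patientId = pid)
          tab <- table(factor(cand@meta$compartment,
                              levels = c("epithelial", "stromal")))
          if (all(tab >= config@minNuclei)) { patch <- cand; break }
        }
        if (is.null(patch))
          stop(sprintf(
            "could not satisfy min-nuclei constraint for the '%s' phenotype (patch %s)",
            cls, patchId), call. = FALSE)
        allPatches[[patchId]] <- patch
      }
    }
  }
  new("HistoCohort", cases = do.call(rbind, c(cases, make.row.names = FALSE)),
      patches = allPatches)
}

#' Render a synthetic patch as an RGB image
#'
#' Fills nuclei in a hematoxylin-like dark purple on an eosin-like pink
#' background with mild additive Gaussian noise, and returns the
#' pixel-accurate ground-truth label mask alongside.
#'
#' @param patch a \linkS4class{NucleiPatch}.
#' @param noiseSd additive noise SD in [0, 1] intensity units (0 disables).
#' @param seed seed for the noise.
#' @return list with \code{image} (width x height x 3 array in [0, 1],
#'   indexed [x+1, y+1, channel]) and \code{labels} (integer width x height
#'   ground-truth label matrix, 0 = background).
#' @export
renderPatch <- function(patch, noiseSd = 0.01, seed = 1L) {
  w <- as.integer(patch@width); h <- as.integer(patch@height)
  bg <- c(0.91, 0.72, 0.80)
  fg <- c(0.28, 0.12, 0.42)
  img <- array(rep(bg, each = w * h), dim = c(w, h, 3))
  labels <- matrix(0L, w, h)
  for (i in seq_along(patch@polygons)) {
    pix <- polygonPixelCenters(patch@polygons[[i]])
    if (nrow(pix) == 0) next
    keep <- pix[, 1] >= 0 & pix[, 1] < w & pix[, 2] >= 0 & pix[, 2] < h
    pix <- pix[keep, , drop = FALSE]
    if (nrow(pix) == 0) next
    idx <- cbind(pix[, 1] + 1L, pix[, 2] + 1L)
    labels[idx] <- i
    for (ch in 1:3) img[cbind(idx, ch)] <- fg[ch]
  }
  if (noiseSd > 0) {
    img <- withSeed(seed, img + array(rnorm(length(img), 0, noiseSd),
                                      dim = dim(img)))
    img[img < 0] <- 0
    img[img > 1] <- 1
  }
  list(image = img, labels = labels)
}
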