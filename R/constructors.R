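#' Build a NucleiPatch from nucleus boundary polygons
#'
#' Derives per-nucleus metadata (centroid, area, perimeter, principal-axis
#' orientation) from the boundary polygons; rejects non-simple polygons.
#'
#' @param polygons list of n x 2 vertex matrices (pixel units, 0-based,
#'   y down), one simple closed polygon per nucleus.
#' @param width,height patch dimensions in pixels.
#' @param patchId,patientId identifiers; \code{patientId} must be non-empty.
#' @param compartment character vector (recycled) of \code{"epithelial"},
#'   \code{"stromal"} or \code{"unknown"}.
#' @param orientation_deg optional per-nucleus orientation; computed from the
#'   polygon principal axis when \code{NULL}.
#' @param magnification nominal magnification tag.
#' @param epitheliumMask optional logical matrix (indexed [x+1, y+1]).
#' @param checkSimple verify polygon simplicity (O(n^2) per nucleus).
#' @return a \linkS4class{NucleiPatch}.
#' @export
NucleiPatch <- function(polygons, width, height,
                        patchId = "patch", patientId = "patient",
                        compartment = "unknown", orientation_deg = NULL,
                        magnification = "40x",
                        epitheliumMask = matrix(logical(0), 0, 0),
                        checkSimple = TRUE) {
  nn <- length(polygons)
  if (checkSimple && nn > 0) {
    ok <- vapply(polygons, polygonIsSimple, logical(1))
    if (!all(ok))
      stop(sprintf("polygon(s) %s are not simple closed polygons",
                   paste(which(!ok), collapse = ", ")), call. = FALSE)
  }
  cent <- if (nn) t(vapply(polygons, polygonCentroid, numeric(2))) else
    matrix(numeric(0), 0, 2)
  if (is.null(orientation_deg)) {
    orientation_deg <- if (nn)
      vapply(polygons, nucleusOrientation, numeric(1)) else numeric(0)
  }
  meta <- data.frame(
    id = seq_len(nn),
    x = cent[, 1][seq_len(nn)],
    y = cent[, 2][seq_len(nn)],
    compartment = rep_len(compartment, nn),
    orientation_deg = rep_len(orientation_deg, nn),
    area = if (nn) vapply(polygons, polygonArea, numeric(1)) else numeric(0),
    perimeter = if (nn) vapply(polygons, polygonPerimeter, numeric(1))
    else numeric(0),
    stringsAsFactors = FALSE
  )
  new("NucleiPatch", patchId = patchId, patientId = patientId,
      width = width, height = height, magnification = magnification,
      polygons = polygons, meta = meta, epitheliumMask = epitheliumMask)
}

#' Construct a synthetic-nuclei phenotype
#'
#' Defaults describe a generic, moderately organized epithelial-nest
#' morphology; see \code{\link{lowRiskPhenotype}} and
#' \code{\link{highRiskPhenotype}} for the calibrated class presets.
#'
#' @param clusterIntensity epithelial nests per mm^2 (4000 px/mm at 40x).
#' @param clusterSpread within-nest dispersion (px).
#' @param nucleiPerClusterMean expected nuclei per nest.
#' @param stromalIntensity stromal nuclei per mm^2.
#' @param placementJitter uniform positional noise half-width (px).
#' @param axisRatioMean,axisRatioSd nuclear axis-ratio distribution.
#' @param boundaryIrregularity radial perturbation amplitude in [0, 0.5].
#' @param orientationKappa von Mises concentration of orientations.
#' @param meanRadiusPx nuclear equivalent radius (px).
#' @param stromalAxisRatioMean,stromalAxisRatioSd,stromalBoundaryIrregularity
#'   optional stromal shape overrides (NA = inherit).
#' @return a \linkS4class{NucleiPhenotype}.
#' @export
nucleiPhenotype <- function(clusterIntensity = 700,
                            clusterSpread = 25,
                            nucleiPerClusterMean = 12,
                            stromalIntensity = 7000,
                            placementJitter = 2,
                            axisRatioMean = 1.4,
                            axisRatioSd = 0.15,
                            boundaryIrregularity = 0.05,
                            orientationKappa = 0,
                            meanRadiusPx = 8,
                            stromalAxisRatioMean = NA_real_,
                            stromalAxisRatioSd = NA_real_,
                            stromalBoundaryIrregularity = NA_real_) {
  new("NucleiPhenotype",
      clusterIntensity = clusterIntensity, clusterSpread = clusterSpread,
      nucleiPerClusterMean = nucleiPerClusterMean,
      stromalIntensity = stromalIntensity, placementJitter = placementJitter,
      axisRatioMean = axisRatioMean, axisRatioSd = axisRatioSd,
      boundaryIrregularity = boundaryIrregularity,
      orientationKappa = orientationKappa, meanRadiusPx = meanRadiusPx,
      stromalAxisRatioMean = stromalAxisRatioMean,
      stromalAxisRatioSd = stromalAxisRatioSd,
      stromalBoundaryIrregularity = stromalBoundaryIrregularity)
}

#' Calibrated low-risk-like phenotype preset
#'
#' Tight, coherent epithelial nests of round, smooth, co-oriented nuclei:
#' the organized-architecture end of the synthetic contrast.
#' @return a \linkS4class{NucleiPhenotype}.
#' @export
lowRiskPhenotype <- function() {
  nucleiPhenotype(clusterIntensity = 700, clusterSpread = 15,
                  nucleiPerClusterMean = 12, stromalIntensity = 7000,
                  placementJitter = 1.5, axisRatioMean = 1.25,
                  axisRatioSd = 0.08, boundaryIrregularity = 0.02,
                  orientationKappa = 4, meanRadiusPx = 8)
}

#' Calibrated high-risk-like phenotype preset
#'
#' Dispersed, disordered nests of pleomorphic, irregular, incoherently
#' oriented nuclei: the disorganized end of the synthetic contrast.
#' @return a \linkS4class{NucleiPhenotype}.
#' @export
highRiskPhenotype <- function() {
  nucleiPhenotype(clusterIntensity = 700, clusterSpread = 45,
                  nucleiPerClusterMean = 12, stromalIntensity = 7000,
                  placementJitter = 6, axisRatioMean = 2.0,
                  axisRatioSd = 0.35, boundaryIrregularity = 0.25,
                  orientationKappa = 0, meanRadiusPx = 9)
}

#' Construct a synthetic-cohort configuration
#'
#' @param nPatientsPerClass patients per risk class.
#' @param patchesPerPatient patches per patient.
#' @param patchSizePx square patch edge (px).
#' @param lowPhenotype,highPhenotype class phenotypes.
#' @param odxScoreRanges list(low =, high =) integer score intervals; the
#'   defaults map onto the low (<= 17) and high (>= 31) ODx categories.
#' @param mbrScoreRanges list(low =, high =) mBR score intervals; defaults
#'   give concordant low (4-5) and high (8-9) grades.
#' @param minNuclei minimum nuclei per compartment per patch.
#' @param seed integer seed determining the whole cohort.
#' @return a \linkS4class{CohortConfig}.
#' @export
cohortConfig <- function(nPatientsPerClass = 10L,
                         patchesPerPatient = 4L,
                         patchSizePx = 300,
                         lowPhenotype = lowRiskPhenotype(),
                         highPhenotype = highRiskPhenotype(),
                         odxScoreRanges = list(low = c(0L, 17L),
                                               high = c(31L, 100L)),
                         mbrScoreRanges = list(low = c(4L, 5L),
                                               high = c(8L, 9L)),
                         minNuclei = 12L,
                         seed = 1L) {
  new("CohortConfig",
      nPatientsPerClass = as.integer(nPatientsPerClass),
      patchesPerPatient = as.integer(patchesPerPatient),
      patchSizePx = patchSizePx,
      lowPhenotype = lowPhenotype, highPhenotype = highPhenotype,
      odxScoreRanges = odxScoreRanges, mbrScoreRanges = mbrScoreRanges,
      minNuclei = as.integer(minNuclei), seed = as.integer(seed))
}

#' Phenotype pair for the compartment-separation ablation
#'
#' Two phenotypes identical in every architectural and epithelial shape
#' parameter that differ only in stromal nuclear shape (axis ratio
#' 1.40 vs 1.35, boundary irregularity 0.06 vs 0.05). Cohorts built from
#' this pair isolate the value of measuring compartments separately: pooled
#' feature extraction dilutes the stromal signal with unchanged epithelial
#' nuclei.
#'
#' @return list with \code{low} and \code{high}
#'   \linkS4class{NucleiPhenotype} objects.
#' @export
stromalShapeAblationPhenotypes <- function() {
  base <- nucleiPhenotype(axisRatioMean = 1.35, axisRatioSd = 0.12,
                          boundaryIrregularity = 0.05, clusterSpread = 25)
  high <- nucleiPhenotype(axisRatioMean = 1.35, axisRatioSd = 0.12,
                          boundaryIrregularity = 0.05, clusterSpread = 25,
                          stromalAxisRatioMean = 1.40,
                          stromalAxisRatioSd = 0.12,
                          stromalBoundaryIrregularity = 0.06)
  list(low = base, high = high)
}
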