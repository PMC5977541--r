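#' NucleiPatch: a segmented 40x image patch
#'
#' Container for the segmented nuclei of one image patch tied to a patient.
#' Each nucleus carries a simple closed polygon boundary (n x 2 matrix, pixel
#' units, 0-based, x right / y down), and per-nucleus metadata: centroid,
#' compartment (\code{"epithelial"}, \code{"stromal"} or \code{"unknown"}),
#' principal-axis orientation in degrees on [0, 180), and derived area and
#' perimeter.
#'
#' @slot patchId character patch identifier.
#' @slot patientId character patient identifier (non-empty).
#' @slot width,height numeric patch dimensions in pixels.
#' @slot magnification character nominal magnification tag (default "40x").
#' @slot polygons list of n x 2 vertex matrices, one per nucleus.
#' @slot meta data.frame with columns \code{id}, \code{x}, \code{y},
#'   \code{compartment}, \code{orientation_deg}, \code{area}, \code{perimeter}.
#' @slot epitheliumMask optional logical matrix (width x height) marking the
#'   epithelial compartment; may be 0 x 0 when absent.
#'
#' @exportClass NucleiPatch
setClass("NucleiPatch", representation(
  patchId = "character",
  patientId = "character",
  width = "numeric",
  height = "numeric",
  magnification = "character",
  polygons = "list",
  meta = "data.frame",
  epitheliumMask = "matrix"
))

setValidity("NucleiPatch", function(object) {
  msgs <- character()
  if (!nzchar(object@patientId)) msgs <- c(msgs, "patientId must be non-empty")
  if (length(object@polygons) != nrow(object@meta))
    msgs <- c(msgs, "polygons and meta must describe the same nuclei")
  req <- c("id", "x", "y", "compartment", "orientation_deg", "area",
           "perimeter")
  if (!all(req %in% names(object@meta)))
    msgs <- c(msgs, paste("meta must have columns:", paste(req, collapse = ", ")))
  if (nrow(object@meta) > 0) {
    if (any(object@meta$area <= 0)) msgs <- c(msgs, "all nuclei must have area > 0")
    if (!all(object@meta$compartment %in% c("epithelial", "stromal", "unknown")))
      msgs <- c(msgs, "compartment must be epithelial/stromal/unknown")
    inb <- object@meta$x >= 0 & object@meta$x <= object@width &
      object@meta$y >= 0 & object@meta$y <= object@height
    if (!all(inb)) msgs <- c(msgs, "nucleus centroids must lie within the patch")
  }
  if (length(msgs)) msgs else TRUE
})

#' NucleiPhenotype: parameters of the synthetic patch generator
#'
#' Describes one morphologic phenotype used by the synthetic cohort
#' generator: the spatial process of epithelial nests and stromal nuclei, and
#' the nuclear size, elongation, boundary irregularity and orientation
#' coherence. Intensities are per mm^2 at a nominal 40x resolution of
#' 4000 px/mm (0.25 um/px).
#'
#' @slot clusterIntensity expected epithelial nests per mm^2.
#' @slot clusterSpread within-nest centroid dispersion (px).
#' @slot nucleiPerClusterMean expected nuclei per nest.
#' @slot stromalIntensity expected stromal nuclei per mm^2.
#' @slot placementJitter uniform positional noise half-width (px).
#' @slot axisRatioMean,axisRatioSd nuclear major/minor axis ratio distribution
#'   (mean >= 1).
#' @slot boundaryIrregularity amplitude of the radial harmonic perturbation,
#'   as a fraction of the radius, in [0, 0.5].
#' @slot orientationKappa von Mises concentration of nuclear orientations
#'   (0 = uniform).
#' @slot meanRadiusPx nuclear equivalent radius (px).
#' @slot stromalAxisRatioMean,stromalAxisRatioSd,stromalBoundaryIrregularity
#'   optional stromal-compartment shape overrides; NA inherits the global
#'   value (used e.g. to build cohorts whose classes differ only in stromal
#'   nuclear shape).
#'
#' @exportClass NucleiPhenotype
setClass("NucleiPhenotype", representation(
  clusterIntensity = "numeric",
  clusterSpread = "numeric",
  nucleiPerClusterMean = "numeric",
  stromalIntensity = "numeric",
  placementJitter = "numeric",
  axisRatioMean = "numeric",
  axisRatioSd = "numeric",
  boundaryIrregularity = "numeric",
  orientationKappa = "numeric",
  meanRadiusPx = "numeric",
  stromalAxisRatioMean = "numeric",
  stromalAxisRatioSd = "numeric",
  stromalBoundaryIrregularity = "numeric"
))

setValidity("NucleiPhenotype", function(object) {
  msgs <- character()
  num <- c(object@clusterIntensity, object@clusterSpread,
           object@nucleiPerClusterMean, object@stromalIntensity,
           object@placementJitter, object@axisRatioMean, object@axisRatioSd,
           object@boundaryIrregularity, object@orientationKappa,
           object@meanRadiusPx)
  if (any(!is.finite(num)))
    return("phenotype parameters must be finite")
  if (any(c(object@clusterIntensity, object@stromalIntensity,
            object@nucleiPerClusterMean) < 0))
    msgs <- c(msgs, "intensities and counts must be >= 0")
  if (object@axisRatioMean < 1) msgs <- c(msgs, "axisRatioMean must be >= 1")
  if (object@boundaryIrregularity < 0 || object@boundaryIrregularity > 0.5)
    msgs <- c(msgs, "boundaryIrregularity must be in [0, 0.5]")
  if (length(msgs)) msgs else TRUE
})

#' CohortConfig: configuration of a synthetic cohort
#'
#' @slot nPatientsPerClass patients simulated per risk class.
#' @slot patchesPerPatient patches per patient.
#' @slot patchSizePx square patch edge length (px).
#' @slot lowPhenotype,highPhenotype \linkS4class{NucleiPhenotype} of the
#'   low-risk-like and high-risk-like classes.
#' @slot odxScoreRanges list with integer vectors \code{low} and \code{high}:
#'   the ODx recurrence-score interval sampled per class (must map onto the
#'   intended category under \code{\link{categorizeOdx}}).
#' @slot mbrScoreRanges list with integer vectors \code{low} and \code{high}:
#'   mBR grade scores sampled per class.
#' @slot minNuclei minimum nuclei per compartment a patch must carry.
#' @slot seed integer seed; fully determines the cohort.
#'
#' @exportClass CohortConfig
setClass("CohortConfig", representation(
  nPatientsPerClass = "integer",
  patchesPerPatient = "integer",
  patchSizePx = "numeric",
  lowPhenotype = "NucleiPhenotype",
  highPhenotype = "NucleiPhenotype",
  odxScoreRanges = "list",
  mbrScoreRanges = "list",
  minNuclei = "integer",
  seed = "integer"
))

setValidity("CohortConfig", function(object) {
  msgs <- character()
  if (object@nPatientsPerClass < 1L) msgs <- c(msgs, "need >= 1 patient per class")
  if (object@patchesPerPatient < 1L) msgs <- c(msgs, "need >= 1 patch per patient")
  if (object@patchSizePx <= 0) msgs <- c(msgs, "patchSizePx must be > 0")
  for (cl in c("low", "high")) {
    r <- object@odxScoreRanges[[cl]]
    if (is.null(r) || length(r) != 2 || any(r < 0 | r > 100) || r[1] > r[2])
      msgs <- c(msgs, sprintf("odxScoreRanges$%s must be an interval in [0, 100]", cl))
  }
  if (length(msgs)) msgs else TRUE
})

#' HistoCohort: a cohort of patients with segmented patches
#'
#' @slot cases data.frame with one row per patient: \code{patient_id},
#'   \code{class} (for synthetic cohorts: \code{"low"}/\code{"high"} ground
#'   truth), \code{odx_score}, \code{odx_category}, \code{mbr_score},
#'   \code{mbr_category}.
#' @slot patches named list of \linkS4class{NucleiPatch}.
#'
#' @exportClass HistoCohort
setClass("HistoCohort", representation(
  cases = "data.frame",
  patches = "list"
))

setValidity("HistoCohort", function(object) {
  msgs <- character()
  if (!all(c("patient_id", "odx_score", "odx_category") %in%
           names(object@cases)))
    msgs <- c(msgs, "cases must have patient_id, odx_score, odx_category")
  if (anyDuplicated(object@cases$patient_id))
    msgs <- c(msgs, "patient ids must be unique")
  pid <- vapply(object@patches, function(p) p@patientId, character(1))
  if (length(pid) && !all(pid %in% object@cases$patient_id))
    msgs <- c(msgs, "every patch must belong to a listed patient")
  if (length(msgs)) msgs else TRUE
})

#' RankingResult: an ordered feature list from one ranking scheme
#'
#' @slot method one of \code{"ranksum"}, \code{"pls_vip"}, \code{"mrmr_mid"},
#'   \code{"mrmr_miq"}.
#' @slot orderedFeatures character vector of catalog names, best first.
#' @slot scores numeric scores aligned with \code{orderedFeatures} (p-values
#'   for ranksum, VIP for pls_vip, greedy objective for MRMR).
#'
#' @exportClass RankingResult
setClass("RankingResult", representation(
  method = "character",
  orderedFeatures = "character",
  scores = "numeric"
))

setValidity("RankingResult", function(object) {
  if (length(object@orderedFeatures) != length(object@scores))
    "orderedFeatures and scores must be aligned" else TRUE
})

#' CVResult: summary of repeated patient-grouped cross-validation
#'
#' @slot perIterationAuc numeric AUC per CV iteration (pooled out-of-fold).
#' @slot aucMean,aucStd mean and population SD of the per-iteration AUCs.
#' @slot perIterationVotingAccuracy per-patient patch-voting accuracy per
#'   iteration (pooled over folds).
#' @slot votingAccuracyMean mean voting accuracy.
#' @slot outOfFoldScores matrix (patches x iterations) of out-of-fold scores.
#' @slot selectedFeatures list (per iteration) of lists (per fold) of the
#'   selected top feature names.
#' @slot classifier,ranker character tags of the configuration evaluated.
#'
#' @exportClass CVResult
setClass("CVResult", representation(
  perIterationAuc = "numeric",
  aucMean = "numeric",
  aucStd = "numeric",
  perIterationVotingAccuracy = "numeric",
  votingAccuracyMean = "numeric",
  outOfFoldScores = "matrix",
  selectedFeatures = "list",
  classifier = "character",
  ranker = "character"
))

setValidity("CVResult", function(object) {
  a <- object@perIterationAuc
  if (length(a) && (any(a < 0) || any(a > 1))) "AUC values must be in [0, 1]"
  else TRUE
})
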