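#' @describeIn NucleiPatch-accessors number of nuclei in the patch
#' @export
setGeneric("nNuclei", function(x) standardGeneric("nNuclei"))

#' @describeIn NucleiPatch-accessors nucleus centroids as an n x 2 matrix
#' @export
setGeneric("centroids", function(x, ...) standardGeneric("centroids"))

#' @describeIn NucleiPatch-accessors nucleus boundary polygons (list of
#'   n x 2 matrices)
#' @export
setGeneric("polygons", function(x, ...) standardGeneric("polygons"))

#' @describeIn NucleiPatch-accessors compartment labels per nucleus
#' @export
setGeneric("compartments", function(x) standardGeneric("compartments"))

#' @describeIn NucleiPatch-accessors orientations (degrees, [0, 180)) per
#'   nucleus
#' @export
setGeneric("orientations", function(x) standardGeneric("orientations"))

#' @describeIn HistoCohort-accessors per-patient case table
#' @export
setGeneric("cases", function(x) standardGeneric("cases"))

#' @describeIn HistoCohort-accessors list of patches (optionally one patient's)
#' @export
setGeneric("patches", function(x, ...) standardGeneric("patches"))

#' Accessors for NucleiPatch objects
#'
#' @param x a \linkS4class{NucleiPatch}.
#' @param ... for \code{centroids}/\code{polygons}: optional
#'   \code{compartment} to restrict to \code{"epithelial"} or
#'   \code{"stromal"} nuclei.
#' @name NucleiPatch-accessors
NULL

selectNuclei <- function(x, compartment = NULL) {
  if (is.null(compartment)) seq_len(nrow(x@meta))
  else which(x@meta$compartment == compartment)
}

#' @rdname NucleiPatch-accessors
#' @aliases nNuclei,NucleiPatch-method
setMethod("nNuclei", "NucleiPatch", function(x) nrow(x@meta))

#' @rdname NucleiPatch-accessors
setMethod("centroids", "NucleiPatch", function(x, compartment = NULL) {
  i <- selectNuclei(x, compartment)
  cbind(x = x@meta$x[i], y = x@meta$y[i])
})

#' @rdname NucleiPatch-accessors
setMethod("polygons", "NucleiPatch", function(x, compartment = NULL) {
  x@polygons[selectNuclei(x, compartment)]
})

#' @rdname NucleiPatch-accessors
setMethod("compartments", "NucleiPatch", function(x) x@meta$compartment)

#' @rdname NucleiPatch-accessors
setMethod("orientations", "NucleiPatch", function(x) x@meta$orientation_deg)

#' Accessors for HistoCohort objects
#'
#' @param x a \linkS4class{HistoCohort}.
#' @param ... for \code{patches}: optional \code{patient_id}.
#' @name HistoCohort-accessors
NULL

#' @rdname HistoCohort-accessors
setMethod("cases", "HistoCohort", function(x) x@cases)

#' @rdname HistoCohort-accessors
setMethod("patches", "HistoCohort", function(x, patient_id = NULL) {
  if (is.null(patient_id)) return(x@patches)
  keep <- vapply(x@patches, function(p) p@patientId, character(1)) %in%
    patient_id
  x@patches[keep]
})

setMethod("show", "NucleiPatch", function(object) {
  tab <- table(factor(object@meta$compartment,
                      levels = c("epithelial", "stromal", "unknown")))
  cat(sprintf(
    "NucleiPatch '%s' (patient '%s', %gx%g px, %s)\n  %d nuclei: %d epithelial, %d stromal, %d unknown\n",
    object@patchId, object@patientId, object@width, object@height,
    object@magnification, nrow(object@meta),
    tab[["epithelial"]], tab[["stromal"]], tab[["unknown"]]))
})

setMethod("show", "HistoCohort", function(object) {
  cat(sprintf("HistoCohort: %d patients, %d patches\n",
              nrow(object@cases), length(object@patches)))
  print(table(object@cases$odx_category))
})

setMethod("show", "NucleiPhenotype", function(object) {
  cat("NucleiPhenotype\n")
  cat(sprintf("  nests: %.0f/mm^2, spread %.0f px, %.1f nuclei/nest; stroma %.0f/mm^2\n",
              object@clusterIntensity, object@clusterSpread,
              object@nucleiPerClusterMean, object@stromalIntensity))
  cat(sprintf("  nuclei: r = %.1f px, axis ratio %.2f+/-%.2f, irregularity %.2f, kappa %.1f\n",
              object@meanRadiusPx, object@axisRatioMean, object@axisRatioSd,
              object@boundaryIrregularity, object@orientationKappa))
})

setMethod("show", "RankingResult", function(object) {
  cat(sprintf("RankingResult (%s): %d features\n", object@method,
              length(object@orderedFeatures)))
  n <- min(5L, length(object@orderedFeatures))
  for (i in seq_len(n))
    cat(sprintf("  %d. %s (%.4g)\n", i, object@orderedFeatures[i],
                object@scores[i]))
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf(
    "CVResult [%s + %s]: AUC %.3f +/- %.3f over %d iterations; voting accuracy %.3f\n",
    object@ranker, object@classifier, object@aucMean, object@aucStd,
    length(object@perIterationAuc), object@votingAccuracyMean))
})
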