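# Per-patch feature vectors: 216 features (116 architecture + 100 shape) per
# compartment, 432 per patch in separated mode, 216 in pooled mode.

compartmentFeatureNames <- function(prefix) {
  c(architectureFeatureNames(prefix), shapeFeatureNames(prefix))
}

#' The feature catalog
#'
#' Ordered names of the per-patch feature vector: in separated mode the 216
#' epithelial features ("EP:" prefix) followed by the 216 stromal features
#' ("ST:"); in pooled mode 216 features over all nuclei ("All:"), ignoring
#' compartment.
#'
#' @param mode \code{"separated"} (432 names) or \code{"pooled"} (216).
#' @return character vector of catalog names.
#' @export
featureCatalog <- function(mode = c("separated", "pooled")) {
  mode <- match.arg(mode)
  if (mode == "separated")
    c(compartmentFeatureNames("EP"), compartmentFeatureNames("ST"))
  else compartmentFeatureNames("All")
}

compartmentVector <- function(patch, idx, prefix, minNuclei, ccgParams) {
  cen <- cbind(patch@meta$x[idx], patch@meta$y[idx])
  bounds <- c(0, patch@width, 0, patch@height)
  arch <- architectureVector(cen, patch@meta$orientation_deg[idx], bounds,
                             minNuclei = minNuclei, ccgParams = ccgParams,
                             prefix = prefix)
  shp <- shapeVector(patch@polygons[idx], minNuclei = minNuclei,
                     prefix = prefix)
  c(arch, shp)
}

#' Per-patch feature vector
#'
#' Computes the named feature vector of one patch. In \code{"separated"}
#' mode (the default analysis mode) the epithelial and stromal compartments
#' are measured independently, giving 432 features; in \code{"pooled"} mode
#' (the compartment-separation ablation) all nuclei are measured together,
#' giving 216. A compartment with fewer than \code{minNuclei} nuclei yields
#' NaN for its half and marks the patch excluded (attribute
#' \code{"excluded"}), the patch NaN policy used by the modeling stage.
#'
#' @param patch a \linkS4class{NucleiPatch} with compartments assigned
#'   (separated mode).
#' @param mode \code{"separated"} or \code{"pooled"}.
#' @param minNuclei minimum nuclei per compartment (default 5).
#' @param ccgParams list with \code{alpha}, \code{r} for the cell cluster
#'   graph.
#' @return named numeric vector (length 432 or 216) with logical attribute
#'   \code{"excluded"}.
#' @export
patchFeatureVector <- function(patch, mode = c("separated", "pooled"),
                               minNuclei = 5L,
                               ccgParams = list(alpha = 0.5, r = 0.2)) {
  mode <- match.arg(mode)
  if (mode == "pooled") {
    v <- compartmentVector(patch, seq_len(nNuclei(patch)), "All",
                           minNuclei, ccgParams)
    attr(v, "excluded") <- nNuclei(patch) < minNuclei
    return(v)
  }
  ep <- which(patch@meta$compartment == "epithelial")
  st <- which(patch@meta$compartment == "stromal")
  v <- c(compartmentVector(patch, ep, "EP", minNuclei, ccgParams),
         compartmentVector(patch, st, "ST", minNuclei, ccgParams))
  excluded <- length(ep) < minNuclei || length(st) < minNuclei
  if (excluded)
    message(sprintf("patch '%s': compartment below %d nuclei, flagged excluded",
                    patch@patchId, minNuclei))
  attr(v, "excluded") <- excluded
  v
}

#' Feature matrix of a cohort
#'
#' Runs \code{\link{patchFeatureVector}} over every patch of a cohort and
#' assembles the patches x features matrix plus the patch/patient bookkeeping
#' needed by the modeling stage. Patches flagged by the NaN policy are kept
#' in the matrix but marked in the \code{excluded} column.
#'
#' @param cohort a \linkS4class{HistoCohort}.
#' @param mode \code{"separated"} or \code{"pooled"}.
#' @param minNuclei,ccgParams passed to \code{\link{patchFeatureVector}}.
#' @return list with \code{features} (matrix), \code{patchInfo} (data.frame
#'   with \code{patch_id}, \code{patient_id}, \code{excluded}).
#' @export
cohortFeatureMatrix <- function(cohort, mode = c("separated", "pooled"),
                                minNuclei = 5L,
                                ccgParams = list(alpha = 0.5, r = 0.2)) {
  mode <- match.arg(mode)
  plist <- cohort@patches
  p <- if (mode == "separated") 432L else 216L
  X <- matrix(NA_real_, length(plist), p,
              dimnames = list(names(plist), featureCatalog(mode)))
  excluded <- logical(length(plist))
  for (i in seq_along(plist)) {
    v <- patchFeatureVector(plist[[i]], mode = mode, minNuclei = minNuclei,
                            ccgParams = ccgParams)
    X[i, ] <- v
    excluded[i] <- attr(v, "excluded")
  }
  info <- data.frame(
    patch_id = vapply(plist, function(x) x@patchId, character(1)),
    patient_id = vapply(plist, function(x) x@patientId, character(1)),
    excluded = excluded | apply(X, 1, function(r) any(!is.finite(r))),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(features = X, patchInfo = info)
}
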