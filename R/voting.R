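# Patch-based voting: per-patient fraction of positive patches against a
# threshold learned on training patients.

#' Fraction of a patient's scored patches called positive
#'
#' @param patchCalls logical (or 0/1) vector of per-patch positive calls for
#'   one patient; must contain at least one scored patch.
#' @return fraction in [0, 1].
#' @export
patchFractionPositive <- function(patchCalls) {
  patchCalls <- patchCalls[!is.na(patchCalls)]
  if (length(patchCalls) == 0)
    stop("patient has no scored patches", call. = FALSE)
  mean(patchCalls > 0)
}

#' Learn the optimal patch-percentage threshold from training patients
#'
#' Sweeps candidate thresholds (midpoints of the sorted unique training
#' fractions, plus 0 and 1) and returns the one maximizing training patient
#' accuracy under the inclusive rule (positive iff fraction >= threshold);
#' ties resolve to the smallest candidate.
#'
#' @param trainFractions per-patient fractions of positive patches.
#' @param trainLabels aligned binary patient labels (both classes present).
#' @return threshold in [0, 1].
#' @export
optimalThreshold <- function(trainFractions, trainLabels) {
  trainLabels <- asBinaryLabels(trainLabels)
  u <- sort(unique(trainFractions))
  cand <- sort(unique(c(0, if (length(u) > 1) (head(u, -1) + u[-1]) / 2, 1)))
  acc <- vapply(cand, function(t)
    mean((trainFractions >= t) == (trainLabels == 1)), numeric(1))
  cand[which.max(acc)]  # which.max returns the first (smallest) maximizer
}

#' Per-patient patch-voting accuracy
#'
#' @param predicted named (by patient id) binary predictions.
#' @param truth named binary truth for the same patients.
#' @return fraction of patients whose risk category was correctly predicted.
#' @export
votingAccuracy <- function(predicted, truth) {
  if (is.null(names(predicted)) || is.null(names(truth)) ||
      !setequal(names(predicted), names(truth)))
    stop("predicted and truth must cover the same patient ids",
         call. = FALSE)
  truth <- truth[names(predicted)]
  mean((predicted > 0) == (truth > 0))
}

#' Per-patient predictions by threshold voting
#'
#' @param scores per-patch classifier scores.
#' @param patientIds aligned patch-to-patient map.
#' @param threshold patch-fraction threshold (from
#'   \code{\link{optimalThreshold}}).
#' @param scoreThreshold per-patch positive-call cutoff (default 0.5).
#' @return data.frame with \code{patient_id}, \code{fraction_positive},
#'   \code{threshold_used}, \code{predicted_category} (0/1).
#' @export
patientPredictions <- function(scores, patientIds, threshold,
                               scoreThreshold = 0.5) {
  calls <- scores >= scoreThreshold
  frac <- tapply(calls, patientIds, patchFractionPositive)
  data.frame(patient_id = names(frac),
             fraction_positive = as.numeric(frac),
             threshold_used = threshold,
             predicted_category = as.integer(frac >= threshold),
             stringsAsFactors = FALSE, row.names = NULL)
}
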