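# Risk categorization rules, cohort exclusion, the four classification
# experiments, pipeline orchestration, the compartment-separation ablation
# and the frozen-model external-validation protocol.

experimentTasks <- c("LLvsHH", "LvsH", "LvsIH", "LIvsH")

#' Categorize an Oncotype DX recurrence score
#'
#' Scores of 17 or below are low risk, 18-30 intermediate, 31 and above
#' high.
#'
#' @param score integer vector, each in [0, 100].
#' @return character vector in \{"low", "intermediate", "high"\}.
#' @export
categorizeOdx <- function(score) {
  if (any(score < 0 | score > 100))
    stop("ODx score out of range [0, 100]", call. = FALSE)
  ifelse(score <= 17, "low", ifelse(score <= 30, "intermediate", "high"))
}

#' Categorize a modified Bloom-Richardson grade score
#'
#' Scores 4-5 are low, 6-7 moderate, 8-9 high grade. A score of 3 is below
#' the grading buckets and mapped to low (logged).
#'
#' @param score integer vector, each in [3, 9].
#' @return character vector in \{"low", "moderate", "high"\}.
#' @export
categorizeMbr <- function(score) {
  if (any(score < 3 | score > 9))
    stop("mBR score out of range [3, 9]", call. = FALSE)
  if (any(score == 3))
    message("mBR score 3 is below the grade buckets; mapped to 'low'")
  ifelse(score <= 5, "low", ifelse(score <= 7, "moderate", "high"))
}

#' Exclude cases whose mBR grade and ODx category are at opposite extremes
#'
#' Drops cases with (mBR low, ODx high) or (mBR high, ODx low); all other
#' cases are retained. The exclusion log lists the dropped ids with the
#' reason.
#'
#' @param cases data.frame with \code{patient_id}, \code{odx_category},
#'   \code{mbr_category}.
#' @return list with \code{cases} (filtered) and \code{excluded}
#'   (data.frame of dropped ids and reasons).
#' @export
applyExtremeConflictExclusion <- function(cases) {
  conflictLowHigh <- cases$mbr_category == "low" & cases$odx_category == "high"
  conflictHighLow <- cases$mbr_category == "high" & cases$odx_category == "low"
  drop <- which(conflictLowHigh | conflictHighLow)
  log <- data.frame(
    patient_id = cases$patient_id[drop],
    reason = ifelse(conflictLowHigh[drop], "low mBR with high ODx",
                    "high mBR with low ODx"),
    stringsAsFactors = FALSE)
  list(cases = cases[setdiff(seq_len(nrow(cases)), drop), , drop = FALSE],
       excluded = log)
}

#' Select cases and binary labels for one classification experiment
#'
#' The four tasks: \code{LLvsHH} keeps only concordant (low ODx, low mBR)
#' vs (high ODx, high mBR) cases; \code{LvsH} keeps low vs high ODx;
#' \code{LvsIH} uses all cases with \{intermediate, high\} positive;
#' \code{LIvsH} uses all cases with \{high\} positive. The positive label
#' is always the higher-risk side.
#'
#' @param cases case table (after
#'   \code{\link{applyExtremeConflictExclusion}} where applicable).
#' @param task one of \code{"LLvsHH"}, \code{"LvsH"}, \code{"LvsIH"},
#'   \code{"LIvsH"}.
#' @return list with \code{cases} (selected rows) and \code{labels}
#'   (named 0/1 vector by patient id).
#' @export
buildExperiment <- function(cases, task = experimentTasks) {
  task <- match.arg(task)
  sel <- switch(task,
    LLvsHH = (cases$odx_category == "low" & cases$mbr_category == "low") |
      (cases$odx_category == "high" & cases$mbr_category == "high"),
    LvsH = cases$odx_category %in% c("low", "high"),
    LvsIH = rep(TRUE, nrow(cases)),
    LIvsH = rep(TRUE, nrow(cases))
  )
  sub <- cases[sel, , drop = FALSE]
  pos <- switch(task,
    LLvsHH = sub$odx_category == "high",
    LvsH = sub$odx_category == "high",
    LvsIH = sub$odx_category %in% c("intermediate", "high"),
    LIvsH = sub$odx_category == "high"
  )
  labels <- setNames(as.integer(pos), sub$patient_id)
  if (length(unique(labels)) < 2)
    stop(sprintf("experiment '%s' yields an empty class", task),
         call. = FALSE)
  list(cases = sub, labels = labels)
}

filterModelingData <- function(featureData, labels) {
  info <- featureData$patchInfo
  keep <- !info$excluded & info$patient_id %in% names(labels)
  list(X = featureData$features[keep, , drop = FALSE],
       y = unname(labels[info$patient_id[keep]]),
       patientIds = info$patient_id[keep])
}

#' Run one classification experiment over a ranker x classifier grid
#'
#' Extracts (or reuses) the cohort feature matrix, applies the
#' extreme-conflict exclusion and the experiment's case selection, then
#' cross-validates every requested ranker/classifier combination.
#'
#' @param cohort a \linkS4class{HistoCohort}.
#' @param task experiment task (see \code{\link{buildExperiment}}).
#' @param rankers,classifiers character vectors defining the grid.
#' @param nIterations,kFolds,nTop,seed,hyperparams passed to
#'   \code{\link{crossValidate}}.
#' @param mode \code{"separated"} (432 features) or \code{"pooled"} (216,
#'   the compartment ablation arm).
#' @param featureData optional precomputed \code{\link{cohortFeatureMatrix}}
#'   result (skips re-extraction).
#' @param applyExclusion apply the extreme-conflict exclusion first.
#' @return list with \code{results} (named list of \linkS4class{CVResult}),
#'   \code{task}, \code{labels}, \code{featureData}, \code{excluded}
#'   (exclusion log), and \code{topFeatures} (most frequently selected
#'   features of the best grid cell).
#' @export
runExperiment <- function(cohort, task = "LvsH",
                          rankers = "ranksum", classifiers = "lda",
                          nIterations = 10L, kFolds = 3L, nTop = 10L,
                          seed = 1L, hyperparams = list(),
                          mode = "separated", featureData = NULL,
                          applyExclusion = TRUE) {
  stopIfNot(all(rankers %in% c("ranksum", "pls_vip", "mrmr_mid",
                               "mrmr_miq")),
            "unknown ranker requested")
  stopIfNot(all(classifiers %in% classifierKinds),
            "unknown classifier requested")
  if (is.null(featureData))
    featureData <- cohortFeatureMatrix(cohort, mode = mode)
  cs <- cases(cohort)
  excludedLog <- NULL
  if (applyExclusion && "mbr_category" %in% names(cs)) {
    ex <- applyExtremeConflictExclusion(cs)
    cs <- ex$cases
    excludedLog <- ex$excluded
  }
  exp <- buildExperiment(cs, task)
  md <- filterModelingData(featureData, exp$labels)
  results <- list()
  for (rk in rankers) for (cl in classifiers) {
    key <- paste(rk, cl, sep = "+")
    results[[key]] <- crossValidate(
      md$X, md$y, md$patientIds, classifier = cl, ranker = rk,
      nIterations = nIterations, kFolds = kFolds, nTop = nTop,
      seed = deriveSeed(seed, match(rk, rankers), match(cl, classifiers)),
      hyperparams = hyperparams)
  }
  best <- results[[which.max(vapply(results, function(r) r@aucMean,
                                    numeric(1)))]]
  topTab <- sort(table(unlist(best@selectedFeatures)), decreasing = TRUE)
  list(results = results, task = task, labels = exp$labels,
       featureData = featureData, excluded = excludedLog,
       topFeatures = head(names(topTab), nTop))
}

#' Compartment-separation ablation
#'
#' Compares cross-validated AUC with features extracted from epithelial and
#' stromal nuclei separately (432 features) against features extracted from
#' all nuclei pooled (216 features), on the same cohort, task and CV
#' configuration.
#'
#' @inheritParams runExperiment
#' @param ranker,classifier the single pair to evaluate in both arms.
#' @return list with \code{separatedAuc}, \code{pooledAuc},
#'   \code{aucImprovement} and both \linkS4class{CVResult} objects.
#' @export
compartmentAblation <- function(cohort, task = "LvsH", ranker = "ranksum",
                                classifier = "lda", nIterations = 3L,
                                kFolds = 3L, nTop = 10L, seed = 1L) {
  sep <- runExperiment(cohort, task, rankers = ranker,
                       classifiers = classifier, nIterations = nIterations,
                       kFolds = kFolds, nTop = nTop, seed = seed,
                       mode = "separated")
  pool <- runExperiment(cohort, task, rankers = ranker,
                        classifiers = classifier, nIterations = nIterations,
                        kFolds = kFolds, nTop = nTop, seed = seed,
                        mode = "pooled")
  sAuc <- sep$results[[1]]@aucMean
  pAuc <- pool$results[[1]]@aucMean
  list(separatedAuc = sAuc, pooledAuc = pAuc,
       aucImprovement = sAuc - pAuc,
       separated = sep$results[[1]], pooled = pool$results[[1]])
}

#' Train on a full cohort and apply the frozen model to a validation cohort
#'
#' Feature ranking, standardization, the classifier and the patch-voting
#' threshold are all learned once on the training cohort and applied
#' unchanged to the validation cohort (no retraining). Patient id sets must
#' be disjoint.
#'
#' @param trainCohort,testCohort \linkS4class{HistoCohort} objects.
#' @param task experiment task used to define labels in both cohorts.
#' @param ranker,classifier pipeline configuration.
#' @param nTop,seed,hyperparams as in \code{\link{crossValidate}}.
#' @param trainFeatureData,testFeatureData optional precomputed feature
#'   matrices.
#' @return list with \code{accuracy} (per-patient voting accuracy on the
#'   validation cohort), \code{predictions} (per-patient data.frame),
#'   \code{threshold}, \code{topFeatures} and the frozen \code{model}.
#' @export
externalValidation <- function(trainCohort, testCohort, task = "LvsH",
                               ranker = "ranksum",
                               classifier = "random_forest", nTop = 10L,
                               seed = 1L, hyperparams = list(),
                               trainFeatureData = NULL,
                               testFeatureData = NULL) {
  trainIds <- cases(trainCohort)$patient_id
  testIds <- cases(testCohort)$patient_id
  if (length(intersect(trainIds, testIds)) > 0)
    stop("training and validation cohorts share patient ids",
         call. = FALSE)
  if (is.null(trainFeatureData))
    trainFeatureData <- cohortFeatureMatrix(trainCohort)
  if (is.null(testFeatureData))
    testFeatureData <- cohortFeatureMatrix(testCohort)
  trainExp <- buildExperiment(cases(trainCohort), task)
  testExp <- buildExperiment(cases(testCohort), task)
  tr <- filterModelingData(trainFeatureData, trainExp$labels)
  te <- filterModelingData(testFeatureData, testExp$labels)
  std <- standardizeTrainTest(tr$X, te$X)
  rk <- rankFeatures(std$train, tr$y, method = ranker, nTop = nTop)
  top <- head(rk@orderedFeatures, nTop)
  model <- fitClassifier(std$train[, top, drop = FALSE], tr$y,
                         kind = classifier, seed = deriveSeed(seed, 11L),
                         hyperparams = hyperparams)
  trainScores <- predictScores(model, std$train[, top, drop = FALSE])
  trainFrac <- tapply(trainScores >= 0.5, tr$patientIds,
                      patchFractionPositive)
  trainLabels <- tapply(tr$y, tr$patientIds, function(v) v[1])
  thr <- optimalThreshold(as.numeric(trainFrac),
                          trainLabels[names(trainFrac)])
  testScores <- predictScores(model, std$test[, top, drop = FALSE])
  pred <- patientPredictions(testScores, te$patientIds, thr)
  truth <- tapply(te$y, te$patientIds, function(v) v[1])
  acc <- votingAccuracy(setNames(pred$predicted_category, pred$patient_id),
                        truth[pred$patient_id])
  list(accuracy = acc, predictions = pred, threshold = thr,
       topFeatures = top, model = model)
}
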