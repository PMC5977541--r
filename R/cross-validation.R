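# Patient-grouped repeated k-fold cross-validation with in-fold feature
# ranking and standardization (the anti-leakage contract: nothing derived
# from test patches ever influences training).

#' Partition patients into k grouped folds
#'
#' Patient-level partition with fold sizes differing by at most one; all
#' patches of a patient share its fold.
#'
#' @param patientIds character vector (one entry per patch is fine; folds
#'   are built over the unique ids).
#' @param k number of folds.
#' @param seed integer seed.
#' @return list of k character vectors of patient ids.
#' @export
groupedFolds <- function(patientIds, k, seed = 1L) {
  ids <- unique(patientIds)
  if (k > length(ids))
    stop("more folds than patients", call. = FALSE)
  shuffled <- withSeed(seed, sample(ids))
  split(shuffled, rep_len(seq_len(k), length(shuffled)))
}

#' Area under the ROC curve
#'
#' Trapezoidal area over all score thresholds, computed in its
#' Mann-Whitney form: the fraction of (positive, negative) pairs where the
#' positive scores higher, with half credit for ties.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels binary labels, both classes present.
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(scores, labels) {
  y <- asBinaryLabels(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

standardizeTrainTest <- function(Xtrain, Xtest) {
  mu <- colMeans(Xtrain)
  sdev <- apply(Xtrain, 2, popSd)
  sdev[sdev == 0] <- 1
  list(train = sweep(sweep(Xtrain, 2, mu), 2, sdev, "/"),
       test = sweep(sweep(Xtest, 2, mu), 2, sdev, "/"))
}

#' Repeated patient-grouped cross-validation of one ranker/classifier pair
#'
#' Per iteration: a fresh seeded patient-level fold split; per fold,
#' z-score standardization and feature ranking are fit on the training
#' patches only, the top \code{nTop} features feed the classifier, and the
#' held-out patches are scored. The iteration AUC is computed on the pooled
#' out-of-fold scores; the per-patient patch-voting accuracy uses a
#' patch-percentage threshold learned on the training patients of each
#' fold. Iterations whose training split lacks a class are reseeded
#' (bounded retries).
#'
#' @param X patches x features matrix (NaN-flagged patches already
#'   excluded).
#' @param y per-patch binary labels.
#' @param patientIds per-patch patient ids (>= 2 patients per class).
#' @param classifier one of \code{"random_forest"}, \code{"neural_net"},
#'   \code{"svm"}, \code{"lda"}.
#' @param ranker one of \code{"ranksum"}, \code{"pls_vip"},
#'   \code{"mrmr_mid"}, \code{"mrmr_miq"}.
#' @param nIterations CV iterations (the full analysis uses 100).
#' @param kFolds folds per iteration (default 3).
#' @param nTop top-ranked features passed to the classifier (default 10).
#' @param seed integer seed driving folds and classifier fits.
#' @param hyperparams classifier hyperparameter overrides.
#' @param .leakRanking INTERNAL validation canary: if TRUE, deliberately
#'   ranks on all patches (training + held-out). Exists only so tests can
#'   demonstrate that the grouped, in-fold protocol blocks the optimism such
#'   leakage produces. Never enable in an analysis.
#' @return a \linkS4class{CVResult}.
#' @export
crossValidate <- function(X, y, patientIds, classifier = "lda",
                          ranker = "ranksum", nIterations = 100L,
                          kFolds = 3L, nTop = 10L, seed = 1L,
                          hyperparams = list(), .leakRanking = FALSE) {
  y <- asBinaryLabels(y)
  X <- as.matrix(X)
  stopIfNot(!anyNA(X) && all(is.finite(X)),
            "X must be finite: exclude NaN-flagged patches first")
  patientIds <- as.character(patientIds)
  patientLabel <- tapply(y, patientIds, function(v) {
    stopIfNot(length(unique(v)) == 1, "inconsistent labels within a patient")
    v[1]
  })
  stopIfNot(sum(patientLabel == 1) >= 2 && sum(patientLabel == 0) >= 2,
            "need >= 2 patients per class")
  nPatch <- nrow(X)
  aucs <- numeric(nIterations)
  vacc <- numeric(nIterations)
  oof <- matrix(NA_real_, nPatch, nIterations,
                dimnames = list(rownames(X), NULL))
  selFeatures <- vector("list", nIterations)
  for (it in seq_len(nIterations)) {
    folds <- NULL
    for (attempt in 0:20) {
      cand <- groupedFolds(patientIds, kFolds,
                           seed = deriveSeed(seed, it, attempt))
      ok <- all(vapply(seq_len(kFolds), function(f) {
        trainPat <- unlist(cand[-f])
        length(unique(patientLabel[trainPat])) == 2
      }, logical(1)))
      if (ok) { folds <- cand; break }
      message("fold split left a training set single-class; reseeding")
    }
    if (is.null(folds))
      stop("could not build class-balanced grouped folds", call. = FALSE)
    scores <- rep(NA_real_, nPatch)
    iterSel <- vector("list", kFolds)
    patientPred <- integer(0)
    for (f in seq_len(kFolds)) {
      testIdx <- which(patientIds %in% folds[[f]])
      trainIdx <- setdiff(seq_len(nPatch), testIdx)
      std <- standardizeTrainTest(X[trainIdx, , drop = FALSE],
                                  X[testIdx, , drop = FALSE])
      rankX <- if (.leakRanking) rbind(std$train, std$test) else std$train
      rankY <- if (.leakRanking) c(y[trainIdx], y[testIdx]) else y[trainIdx]
      rk <- rankFeatures(rankX, rankY, method = ranker, nTop = nTop)
      top <- head(rk@orderedFeatures, nTop)
      iterSel[[f]] <- top
      model <- fitClassifier(std$train[, top, drop = FALSE], y[trainIdx],
                             kind = classifier,
                             seed = deriveSeed(seed, it, f, 7L),
                             hyperparams = hyperparams)
      scores[testIdx] <- predictScores(model, std$test[, top, drop = FALSE])
      # voting threshold from the training patients of this fold
      trainScores <- predictScores(model, std$train[, top, drop = FALSE])
      trainFrac <- tapply(trainScores >= 0.5, patientIds[trainIdx],
                          patchFractionPositive)
      thr <- optimalThreshold(as.numeric(trainFrac),
                              patientLabel[names(trainFrac)])
      pp <- patientPredictions(scores[testIdx], patientIds[testIdx], thr)
      patientPred <- c(patientPred,
                       setNames(pp$predicted_category, pp$patient_id))
    }
    stopIfNot(!anyNA(scores), "every patch must be scored exactly once")
    aucs[it] <- rocAuc(scores, y)
    vacc[it] <- votingAccuracy(patientPred,
                               patientLabel[names(patientPred)])
    oof[, it] <- scores
    selFeatures[[it]] <- iterSel
  }
  new("CVResult", perIterationAuc = aucs, aucMean = mean(aucs),
      aucStd = popSd(aucs), perIterationVotingAccuracy = vacc,
      votingAccuracyMean = mean(vacc), outOfFoldScores = oof,
      selectedFeatures = selFeatures, classifier = classifier,
      ranker = ranker)
}
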