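test_that("ODx categorization matches the clinical assay cutoffs exactly", {
  expect_identical(categorizeOdx(17), "low")
  expect_identical(categorizeOdx(18), "intermediate")
  expect_identical(categorizeOdx(30), "intermediate")
  expect_identical(categorizeOdx(31), "high")
  expect_error(categorizeOdx(101), "out of range")
  expect_error(categorizeOdx(-1), "out of range")
  # total, monotone partition of 0..100 with recoverable boundaries
  cats <- categorizeOdx(0:100)
  expect_identical(unique(cats), c("low", "intermediate", "high"))
  expect_equal(max(which(cats == "low")) - 1, 17)
  expect_equal(max(which(cats == "intermediate")) - 1, 30)
  expect_equal(min(which(cats == "high")) - 1, 31)
  ord <- c(low = 1, intermediate = 2, high = 3)
  expect_true(all(diff(ord[cats]) >= 0))
})

test_that("mBR categorization matches the grade buckets", {
  expect_identical(categorizeMbr(5), "low")
  expect_identical(categorizeMbr(7), "moderate")
  expect_identical(categorizeMbr(8), "high")
  expect_message(out <- categorizeMbr(3), "below the grade buckets")
  expect_identical(out, "low")
  expect_error(categorizeMbr(10), "out of range")
})

test_that("extreme mBR/ODx conflicts are excluded with a reasoned log", {
  cases <- data.frame(
    patient_id = c("a", "b", "c", "d"),
    odx_category = c("low", "high", "low", "high"),
    mbr_category = c("high", "low", "moderate", "high"),
    stringsAsFactors = FALSE)
  ex <- applyExtremeConflictExclusion(cases)
  expect_setequal(ex$cases$patient_id, c("c", "d"))
  expect_setequal(ex$excluded$patient_id, c("a", "b"))
  expect_identical(ex$excluded$reason[ex$excluded$patient_id == "a"],
                   "high mBR with low ODx")
  expect_identical(ex$excluded$reason[ex$excluded$patient_id == "b"],
                   "low mBR with high ODx")
})

test_that("experiment definitions select and label cases per task", {
  cases <- data.frame(
    patient_id = sprintf("p%d", 1:6),
    odx_category = c("low", "low", "intermediate", "intermediate", "high",
                     "high"),
    mbr_category = c("low", "moderate", "moderate", "high", "high",
                     "moderate"),
    stringsAsFactors = FALSE)
  llhh <- buildExperiment(cases, "LLvsHH")
  expect_setequal(llhh$cases$patient_id, c("p1", "p5"))
  expect_equal(unname(llhh$labels[c("p1", "p5")]), c(0L, 1L))
  lvh <- buildExperiment(cases, "LvsH")
  expect_false("p3" %in% lvh$cases$patient_id)
  lvih <- buildExperiment(cases, "LvsIH")
  expect_equal(unname(lvih$labels["p3"]), 1L)
  livh <- buildExperiment(cases, "LIvsH")
  expect_equal(unname(livh$labels["p3"]), 0L)
  # consistency: high cases positive in every task that includes them, low
  # cases negative everywhere
  for (task in c("LLvsHH", "LvsH", "LvsIH", "LIvsH")) {
    lab <- buildExperiment(cases, task)$labels
    hi <- intersect(names(lab),
                    cases$patient_id[cases$odx_category == "high"])
    lo <- intersect(names(lab),
                    cases$patient_id[cases$odx_category == "low"])
    expect_true(all(lab[hi] == 1L))
    expect_true(all(lab[lo] == 0L))
  }
  onlyLow <- cases[cases$odx_category == "low", ]
  expect_error(buildExperiment(onlyLow, "LvsH"), "empty class")
})

test_that("runExperiment completes a ranker x classifier grid deterministically", {
  fx <- smallStrongCohort()
  rep1 <- suppressMessages(runExperiment(
    fx$cohort, "LvsH", rankers = c("ranksum", "pls_vip"),
    classifiers = c("lda", "svm"), nIterations = 1L, seed = 5L,
    featureData = fx$featureData))
  expect_length(rep1$results, 4L)
  expect_true(all(vapply(rep1$results, function(r) is(r, "CVResult"),
                         logical(1))))
  rep2 <- suppressMessages(runExperiment(
    fx$cohort, "LvsH", rankers = c("ranksum", "pls_vip"),
    classifiers = c("lda", "svm"), nIterations = 1L, seed = 5L,
    featureData = fx$featureData))
  expect_identical(
    vapply(rep1$results, function(r) r@aucMean, numeric(1)),
    vapply(rep2$results, function(r) r@aucMean, numeric(1)))
  expect_error(suppressMessages(runExperiment(fx$cohort, "LvsH",
                                              rankers = "bogus")),
               "unknown ranker")
})

test_that("the frozen external-validation protocol transfers and never retrains", {
  fx <- smallStrongCohort()
  # validation cohort: same generator, different seed and ids
  cfg <- cohortConfig(nPatientsPerClass = 6L, patchesPerPatient = 3L,
                      seed = 3033L)
  testCoh <- suppressMessages(generateCohort(cfg))
  testCoh@cases$patient_id <- paste0("v_", testCoh@cases$patient_id)
  testCoh@patches <- lapply(testCoh@patches, function(p) {
    p@patientId <- paste0("v_", p@patientId); p
  })
  testFd <- suppressMessages(cohortFeatureMatrix(testCoh))
  ev <- externalValidation(fx$cohort, testCoh, task = "LvsH",
                           ranker = "ranksum", classifier = "lda",
                           seed = 17L, trainFeatureData = fx$featureData,
                           testFeatureData = testFd)
  expect_gte(ev$accuracy, 0.95)
  # frozen model is independent of the test cohort contents
  half <- testCoh
  keepIds <- cases(testCoh)$patient_id[c(1:3, 7:9)]
  half@cases <- half@cases[half@cases$patient_id %in% keepIds, ]
  half@patches <- patches(half, patient_id = keepIds)
  halfFd <- suppressMessages(cohortFeatureMatrix(half))
  ev2 <- externalValidation(fx$cohort, half, task = "LvsH",
                            ranker = "ranksum", classifier = "lda",
                            seed = 17L, trainFeatureData = fx$featureData,
                            testFeatureData = halfFd)
  expect_identical(ev$model, ev2$model)
  expect_identical(ev$topFeatures, ev2$topFeatures)
  expect_identical(ev$threshold, ev2$threshold)
  # overlapping patient ids are rejected
  expect_error(externalValidation(fx$cohort, fx$cohort), "share patient ids")
})

test_that("label-permuted validation accuracy stays near the majority rate", {
  fx <- smallStrongCohort()
  cfg <- cohortConfig(nPatientsPerClass = 6L, patchesPerPatient = 3L,
                      seed = 4044L)
  permCoh <- suppressMessages(generateCohort(cfg))
  permCoh@cases$patient_id <- paste0("w_", permCoh@cases$patient_id)
  permCoh@patches <- lapply(permCoh@patches, function(p) {
    p@patientId <- paste0("w_", p@patientId); p
  })
  # permute the class-defining scores across patients (seeded)
  permCoh@cases[, c("odx_score", "odx_category")] <-
    withr::with_seed(5, permCoh@cases[sample(nrow(permCoh@cases)),
                                      c("odx_score", "odx_category")])
  permFd <- suppressMessages(cohortFeatureMatrix(permCoh))
  ev <- externalValidation(fx$cohort, permCoh, task = "LvsH",
                           ranker = "ranksum", classifier = "lda",
                           seed = 17L, trainFeatureData = fx$featureData,
                           testFeatureData = permFd)
  truth <- buildExperiment(cases(permCoh), "LvsH")$labels
  majority <- max(mean(truth == 1), mean(truth == 0))
  expect_lte(abs(ev$accuracy - majority), 0.15)
})
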