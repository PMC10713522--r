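# completed labeled cohort with a single decisive marker ("pac"):
# feature value 1 for intended positives, 0 for intended negatives
decisiveCohort <- function(calls, labels) {
  sch <- paSchema()
  enc <- encodedColumns(sch)
  set.seed(99)
  vals <- matrix(rnorm(length(calls) * nrow(enc), sd = 0.01),
                 nrow = nrow(enc), dimnames = list(enc$column, NULL))
  vals["pac", ] <- as.numeric(calls)
  PACohort(vals, center = rep("C", length(calls)), label = labels,
           schema = sch)
}

test_that("the f-score is the harmonic mean of TPR and TNR", {
  expect_equal(fScore(1, 1), 1)
  expect_equal(round(fScore(0.87, 0.85), 2), 0.86)
  expect_equal(round(fScore(0.87, 0.81), 2), 0.84)
  expect_equal(fScore(0.9, 0), 0)
  expect_equal(fScore(0, 0), 0)
  expect_error(fScore(1.2, 0.5), "0, 1")
  # symmetry and bounds
  set.seed(2)
  a <- runif(50); b <- runif(50)
  expect_equal(fScore(a, b), fScore(b, a))
  expect_true(all(fScore(a, b) <= pmax(a, b) + 1e-12))
  expect_true(all(fScore(a, b) >= 0))
})

test_that("binary track labels pool the two other classes as negative", {
  labs <- c("surgery-track", "AVS-recommended", "medication-track")
  expect_equal(makeBinaryLabels(labs, "surgery"), c(1L, 0L, 0L))
  expect_equal(makeBinaryLabels(labs, "medication"), c(0L, 0L, 1L))
  expect_equal(makeBinaryLabels(rep("medication-track", 4), "surgery"),
               rep(0L, 4))
  expect_error(makeBinaryLabels(c("surgery-track", "oops"), "surgery"),
               "unknown label")
  expect_error(makeBinaryLabels(character(), "surgery"), "non-empty")
})

test_that("training refuses masked, single-class or non-finite input", {
  cfg <- cohortConfig(nPatients = 60, seed = 41)
  coh <- applyMissingness(generateCohort(cfg)$cohort, cfg)
  expect_error(trainClassifier(coh, "surgery", "lr-l2"),
               "imputation must precede")
  full <- generateCohort(cfg)$cohort
  oneClass <- generateCohort(cohortConfig(nPatients = 20, seed = 41,
                                          classProb = c(0, 0, 1)))$cohort
  expect_error(trainClassifier(oneClass, "surgery", "lr-l2"),
               "single-class")
})

test_that("all families separate linearly separable data and reproduce", {
  y <- rep(c(1, 0), each = 40)
  labels <- ifelse(y == 1, "surgery-track", "medication-track")
  coh <- decisiveCohort(y, labels)
  probe <- decisiveCohort(rep(c(1, 0), 10),
                          rep(c("surgery-track", "medication-track"), 10))
  for (fam in c("lr-l2", "lr-l1", "rf", "mlp")) {
    clf <- trainClassifier(coh, "surgery", fam, seed = 7)
    met <- evaluateClassifier(clf, coh)
    expect_equal(met$fScore, 1, label = paste("training f of", fam))
    clf2 <- trainClassifier(coh, "surgery", fam, seed = 7)
    expect_identical(predictProb(clf, probe), predictProb(clf2, probe),
                     label = paste("determinism of", fam))
  }
})

test_that("confusion metrics follow the rate definitions", {
  # training set pins the decision boundary to the decisive marker
  train <- decisiveCohort(rep(c(1, 0), each = 50),
                          rep(c("surgery-track", "medication-track"),
                              each = 50))
  clf <- trainClassifier(train, "surgery", "lr-l2", seed = 1)

  # evaluation set constructed to give TP=9 FN=1 TN=87 FP=13
  calls <- c(rep(1, 9), 0, rep(0, 87), rep(1, 13))
  truth <- c(rep("surgery-track", 10), rep("medication-track", 100))
  test <- decisiveCohort(calls, truth)
  met <- evaluateClassifier(clf, test)
  expect_equal(unname(met$counts), c(9L, 1L, 87L, 13L))
  expect_equal(met$sensitivity, 0.90)
  expect_equal(met$specificity, 0.87)
  expect_equal(round(met$fScore, 3), 0.885)

  perfect <- decisiveCohort(c(1, 1, 0, 0),
                            c("surgery-track", "surgery-track",
                              "medication-track", "medication-track"))
  expect_equal(evaluateClassifier(clf, perfect)$fScore, 1)

  allPos <- decisiveCohort(rep(1, 20),
                           rep(c("surgery-track", "medication-track"), 10))
  mAP <- evaluateClassifier(clf, allPos)
  expect_equal(mAP$sensitivity, 1)
  expect_equal(mAP$specificity, 0)
  expect_equal(mAP$fScore, 0)

  onlyPos <- decisiveCohort(rep(1, 5), rep("surgery-track", 5))
  expect_true(evaluateClassifier(clf, onlyPos)$flagged)
})

test_that("raising the threshold trades sensitivity for specificity", {
  sim <- generateCohort(cohortConfig(nPatients = 200, seed = 51))
  st <- referenceStats(sim$cohort)
  coh <- standardizeCohort(sim$cohort, st)
  clf <- trainClassifier(coh, "surgery", "lr-l2", seed = 1)
  sens <- spec <- numeric(0)
  for (thr in seq(0.1, 0.9, by = 0.1)) {
    clf@threshold <- thr
    met <- evaluateClassifier(clf, coh)
    sens <- c(sens, met$sensitivity)
    spec <- c(spec, met$specificity)
  }
  expect_true(all(diff(sens) <= 1e-12))
  expect_true(all(diff(spec) >= -1e-12))
})

test_that("grid search maximizes validation f-score with first-wins ties", {
  y <- rep(c(1, 0), each = 30)
  labels <- ifelse(y == 1, "surgery-track", "medication-track")
  train <- decisiveCohort(y, labels)
  val <- decisiveCohort(rep(c(1, 0), 15),
                        rep(c("surgery-track", "medication-track"), 15))

  one <- gridSearch(train, val, "surgery", "lr-l2",
                    grid = list(list(C = 2)), seed = 1)
  expect_equal(one$classifier@hyper$C, 2)

  tie <- gridSearch(train, val, "surgery", "lr-l2",
                    grid = list(list(C = 3), list(C = 3)), seed = 1)
  expect_equal(tie$trace$fScore[1], tie$trace$fScore[2])
  expect_equal(tie$trace$point[which.max(tie$trace$fScore)], 1)
  expect_equal(tie$metrics$fScore, 1)

  expect_error(gridSearch(train, val, "surgery", "lr-l2", grid = list()),
               "empty")
})

test_that("logistic coefficients recover a planted signal", {
  sch <- paSchema()
  enc <- encodedColumns(sch)
  set.seed(61)
  n <- 500
  X <- matrix(rnorm(n * nrow(enc)), nrow = nrow(enc),
              dimnames = list(enc$column, NULL))
  eta <- 2 * X["pac", ]
  y <- rbinom(n, 1, plogis(eta))
  coh <- PACohort(X, center = rep("C", n),
                  label = ifelse(y == 1, "surgery-track",
                                 "medication-track"), schema = sch)
  clf <- trainClassifier(coh, "surgery", "lr-l2", hyper = list(C = 1))
  rep <- coefficientReport(clf)
  expect_equal(rep$marker[1], "pac")
  expect_gt(rep$coefficient[rep$marker == "pac"], 0)

  # strong regularization shrinks zero-signal coefficients toward 0
  y0 <- rbinom(n, 1, 0.5)
  coh0 <- PACohort(X, center = rep("C", n),
                   label = ifelse(y0 == 1, "surgery-track",
                                  "medication-track"), schema = sch)
  clf0 <- trainClassifier(coh0, "surgery", "lr-l2",
                          hyper = list(C = 1e-4))
  expect_lt(max(abs(coefficientReport(clf0)$coefficient)), 0.01)

  rfclf <- trainClassifier(coh, "surgery", "rf",
                           hyper = list(nTrees = 50), seed = 2)
  expect_error(coefficientReport(rfclf), "logistic")
})

test_that("random forests learn the default synthetic class signal", {
  trainSim <- generateCohort(cohortConfig(nPatients = 300, seed = 71))
  testSim <- generateCohort(cohortConfig(nPatients = 200, seed = 72))
  st <- referenceStats(trainSim$cohort)
  clf <- trainClassifier(standardizeCohort(trainSim$cohort, st),
                         "surgery", "rf", hyper = list(nTrees = 2000),
                         seed = 3)
  met <- evaluateClassifier(clf, standardizeCohort(testSim$cohort, st))
  expect_gt(met$fScore, 0.5)
})
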