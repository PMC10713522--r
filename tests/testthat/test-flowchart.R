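test_that("routing follows the sequential gates", {
  ct <- deriveCTFeatures(
    right_size = c(0, 4, 0, 8, 0, 5),
    left_size = c(12, 9, 0, 0, 0, 5)
  )
  dec <- routeCases(
    surgeryPositive = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE),
    medicationPositive = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    arrCCT = c(105.8, 55.9, NA, NA, NA, 73.0),
    ct = ct
  )
  expect_equal(as.character(dec$route),
               c("surgery", "AVS", "medication", "AVS", "AVS", "AVS"))
  expect_equal(as.character(dec$surgery_side[1]), "left")
  expect_equal(as.character(dec$branch),
               c("surgery-gate-pass", "surgery-gate-fail-ARR",
                 "medication-gate-pass", "medication-gate-fail-CT",
                 "no-model-positive", "surgery-gate-fail-ARR"))
  # ARR exactly at the cutoff fails the strict gate (case 6)
})

test_that("surgery needs a defined larger side; missing ARR is a contract error", {
  negCT <- deriveCTFeatures(0, 0)
  d <- routeCases(TRUE, FALSE, 200, negCT)
  expect_equal(as.character(d$route), "AVS")
  expect_equal(as.character(d$branch), "surgery-gate-fail-CT")
  eqCT <- deriveCTFeatures(7, 7)
  d2 <- routeCases(TRUE, FALSE, 200, eqCT)
  expect_equal(as.character(d2$branch), "surgery-gate-fail-CT")

  expect_error(routeCases(TRUE, FALSE, NA, negCT), "imputation")
  d3 <- routeCases(TRUE, FALSE, NA, negCT, missingArrToAVS = TRUE)
  expect_equal(as.character(d3$route), "AVS")
})

test_that("cohort accounting reproduces identities exactly", {
  set.seed(5)
  n <- 500
  ct <- deriveCTFeatures(round(runif(n, 0, 15)) *
                           rbinom(n, 1, 0.5),
                         round(runif(n, 0, 15)) * rbinom(n, 1, 0.5))
  dec <- routeCases(rbinom(n, 1, 0.4) == 1, rbinom(n, 1, 0.6) == 1,
                    runif(n, 0, 300), ct)
  truth <- sample(paTracks(), n, replace = TRUE)
  sm <- summarizeFlowchart(dec, truth)
  # partition: every patient gets exactly one route
  expect_equal(sum(sm$routeCounts), n)
  expect_equal(sum(sm$branchCounts), n)
  # branch tags determine routes
  expect_equal(unname(sm$routeCounts["AVS"]),
               unname(sum(sm$branchCounts[c("surgery-gate-fail-ARR",
                                            "surgery-gate-fail-CT",
                                            "medication-gate-fail-CT",
                                            "no-model-positive")])))
  expect_equal(sm$avs_fraction,
               round(100 * sm$routeCounts[["AVS"]] / n, 1))
  expect_equal(sm$decision_accuracy,
               round(100 * sm$decided_correct / sm$decided_total, 1))
})

test_that("raising the ARR cutoff never shrinks the AVS pool", {
  set.seed(6)
  n <- 300
  ct <- deriveCTFeatures(round(runif(n, 0, 15)) * rbinom(n, 1, 0.6),
                         round(runif(n, 0, 15)) * rbinom(n, 1, 0.6))
  sPos <- rbinom(n, 1, 0.5) == 1
  mPos <- rbinom(n, 1, 0.5) == 1
  arr <- runif(n, 0, 300)
  prev <- -1L
  for (cut in c(0, 40, 73, 150, 400)) {
    dec <- routeCases(sPos, mPos, arr, ct, arrCutoff = cut)
    nAVS <- sum(dec$route == "AVS")
    expect_gte(nAVS, prev)
    prev <- nAVS
  }
})

test_that("an all-AVS cohort has undefined accuracy, flagged", {
  ct <- deriveCTFeatures(c(0, 0), c(0, 0))
  dec <- routeCases(c(FALSE, FALSE), c(FALSE, FALSE), c(NA, NA), ct)
  sm <- summarizeFlowchart(dec, c("surgery-track", "medication-track"))
  expect_equal(sm$avs_fraction, 100)
  expect_true(sm$flagged)
  expect_true(is.na(sm$decision_accuracy))
})

test_that("the pipeline runs end to end and is a no-op without missingness", {
  ref <- generateCohort(cohortConfig(nPatients = 120, seed = 81,
                                     centers = "Reference"))$cohort
  tgt <- generateCohort(cohortConfig(nPatients = 80, seed = 82))$cohort
  res <- runPipeline(ref, tgt, grid = defaultGrid("lr-l2")[3], q = 8,
                     maxIter = 300, seed = 3)
  expect_s4_class(res$bpca, "BPCAModel")
  expect_equal(nrow(res$decisions), 80L)
  expect_equal(sum(res$summary$routeCounts), 80L)
  # fully observed target: the imputation stage changes nothing
  st <- res$stats
  expect_equal(cohortValues(res$completedTarget),
               cohortValues(standardizeCohort(tgt, st)))
  # determinism: identical inputs and seed give identical accounting
  res2 <- runPipeline(ref, tgt, grid = defaultGrid("lr-l2")[3], q = 8,
                      maxIter = 300, seed = 3)
  expect_identical(res$summary, res2$summary)
  expect_identical(res$decisions, res2$decisions)
})

test_that("grid-search validation on the target cohort is available", {
  ref <- generateCohort(cohortConfig(nPatients = 100, seed = 83,
                                     centers = "Reference"))$cohort
  tgt <- generateCohort(cohortConfig(nPatients = 60, seed = 84))$cohort
  res <- runPipeline(ref, tgt, grid = defaultGrid("lr-l2")[c(1, 3)],
                     validation = "target", q = 6, maxIter = 200, seed = 2)
  expect_equal(nrow(res$gridTraces$surgery), 2L)
  expect_false(is.null(res$summary))
})
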