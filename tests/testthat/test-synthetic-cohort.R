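test_that("generation is deterministic under a fixed seed, to the byte", {
  cfg <- cohortConfig(nPatients = 40, seed = 77)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(cohortValues(a$cohort), cohortValues(b$cohort))
  expect_identical(a$truth, b$truth)
  fa <- withr::local_tempfile(fileext = ".csv")
  fb <- withr::local_tempfile(fileext = ".csv")
  writeCohort(applyMissingness(a$cohort, cfg), fa)
  writeCohort(applyMissingness(b$cohort, cfg), fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("class mix matches the 84/18/108 three-class frequencies", {
  cfg <- cohortConfig(nPatients = 210, seed = 1)
  lab <- table(generateCohort(cfg)$truth$label)
  expected <- c(84, 18, 108)
  sds <- sqrt(210 * (expected / 210) * (1 - expected / 210))
  expect_true(all(abs(as.numeric(lab) - expected) <= 3 * sds))
})

test_that("degenerate single-class mixtures generate consistently", {
  cfg <- cohortConfig(nPatients = 30, seed = 3,
                      classProb = c(1, 0, 0))
  sim <- generateCohort(cfg)
  expect_true(all(sim$truth$label == "surgery-track"))
  # every surgery-track patient has a CT-visible tumor on the APA side
  sz <- ifelse(sim$truth$apa_side == "right",
               sim$truth$right_size, sim$truth$left_size)
  expect_true(all(sz > 0))
})

test_that("structural CT invariants hold on the default cohort", {
  sim <- generateCohort(cohortConfig(nPatients = 400, seed = 9))
  tr <- sim$truth
  surg <- tr$label == "surgery-track"
  apaSz <- ifelse(tr$apa_side == "right", tr$right_size, tr$left_size)
  othSz <- ifelse(tr$apa_side == "right", tr$left_size, tr$right_size)
  expect_true(all(apaSz[surg] > 0))
  expect_true(all(apaSz[surg] >= othSz[surg]))
  neg <- tr$right_size == 0 & tr$left_size == 0
  ctneg <- cohortValues(sim$cohort)["ct_laterality.image_negative", ] == 1
  expect_identical(unname(ctneg), neg)
  # labeling rule applied to ground truth reproduces the generator labels
  ct <- deriveCTFeatures(tr$right_size, tr$left_size)
  diag <- ifelse(tr$label == "medication-track", "IHA-medical",
                 "APA-surgical")
  expect_identical(assignSubtypeLabel(diag, tr$apa_side, ct),
                   factor(tr$label, levels = paTracks()))
})

test_that("class-conditional distributions match their targets", {
  # 3-SE Monte-Carlo window on untruncated normal means and on log-normal
  # medians (floors truncate far tails of the checked normals)
  cfg <- cohortConfig(nPatients = 15000, seed = 13)
  sim <- generateCohort(cfg)
  vals <- cohortValues(sim$cohort)
  lab <- sim$truth$label
  dist <- markerDistributions()
  for (mk in c("age", "bmi", "sbp", "dbp", "egfr")) {
    for (cls in paTracks()) {
      row <- dist[dist$marker == mk & dist$class == cls, ]
      x <- vals[mk, lab == cls]
      se <- row$p2 / sqrt(length(x))
      expect_lt(abs(mean(x) - row$p1), 3 * se,
                label = sprintf("mean of %s in %s", mk, cls))
    }
  }
  for (mk in c("pac", "pra", "arr_cct", "pac_ast")) {
    for (cls in paTracks()) {
      row <- dist[dist$marker == mk & dist$class == cls, ]
      x <- vals[mk, lab == cls]
      sdlog <- (log(row$p3) - log(row$p2)) / (2 * qnorm(0.75))
      seMed <- 1.2533 * sdlog * row$p1 / sqrt(length(x))
      expect_lt(abs(median(x) - row$p1), 3 * seMed,
                label = sprintf("median of %s in %s", mk, cls))
    }
  }
})

test_that("summarizeCohort mirrors the published descriptive rows", {
  sim <- generateCohort(cohortConfig(nPatients = 210, seed = 1))
  sm <- summarizeCohort(sim$cohort)
  nod <- sm$markers[sm$markers$class == "surgery-track" &
                      sm$markers$marker == "larger_tumor_mm", ]
  expect_lt(abs(nod$mean - 15.7), 3 * 6.2)
  expect_true(all(missingFraction(sim$cohort)$missing == 0))
  one <- summarizeCohort(
    generateCohort(cohortConfig(nPatients = 12, seed = 3,
                                classProb = c(0, 0, 1)))$cohort)
  expect_setequal(unique(one$markers$class), "medication-track")
})

test_that("missingness respects per-center rates and the 0.2 cap", {
  cfg0 <- cohortConfig(nPatients = 50, seed = 4,
                       missingRates = list(Yokohama = c(pac = 0)))
  coh <- generateCohort(cfg0)$cohort
  expect_identical(observedMask(applyMissingness(coh, cfg0)),
                   observedMask(coh))

  cfg <- cohortConfig(nPatients = 4000, seed = 4, centers = "A",
                      missingRates = list(A = c(arr_cct = 0.2)))
  coh <- generateCohort(cfg)$cohort
  masked <- applyMissingness(coh, cfg)
  frac <- mean(!observedMask(masked)["arr_cct", ])
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / 4000))
  other <- rownames(observedMask(masked)) != "arr_cct"
  expect_true(all(observedMask(masked)[other, ]))

  expect_error(cohortConfig(missingRates = list(A = c(pac = 0.25))),
               "0, 0.2")
})

test_that("MAR missingness produces the configured covariate dependence", {
  cfg <- cohortConfig(nPatients = 4000, seed = 8, centers = "A",
                      missingRates = list(A = c(cortisol_dst = 0.1)),
                      missingMode = "MAR")
  coh <- generateCohort(cfg)$cohort
  masked <- applyMissingness(coh, cfg)
  age <- cohortValues(coh)["age", ]
  older <- age > median(age)
  miss <- !observedMask(masked)["cortisol_dst", ]
  fOld <- mean(miss[older])
  fYng <- mean(miss[!older])
  expect_lt(abs(fOld - 0.2), 3 * sqrt(0.2 * 0.8 / sum(older)))
  expect_lt(abs(fYng - 0.05), 3 * sqrt(0.05 * 0.95 / sum(!older)))
})
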