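test_that("noiseless low-rank data recovers the exact SVD subspace", {
  dat <- lowRankData(seed = 42, d = 10, n = 300, qTrue = 2, snr = 1e12)
  coh <- matrixCohort(dat$full)
  fit <- fitBPCA(coh, maxIter = 500)
  expect_equal(qEff(fit), 2L)
  Xc <- dat$full - rowMeans(dat$full)
  sv <- svd(Xc, nu = 2)
  expect_lt(max(principalAngles(loadings(fit), sv$u)), 1e-3)
})

test_that("tiny fits respect the dimension bound", {
  X <- matrix(c(1, 2, 1.5, 2.5, 0.9, 2.1), nrow = 2)
  fit <- suppressWarnings(fitBPCA(matrixCohort(X), maxIter = 200))
  expect_lte(qEff(fit), 1L)
  expect_equal(ncol(fit@W), 1L)
})

test_that("underdetermined columns are refused by name", {
  dat <- lowRankData(seed = 3, d = 6, n = 20, qTrue = 2)
  X <- dat$full
  X[4, 2:20] <- NA
  expect_error(fitBPCA(matrixCohort(X)), "m04")
})

test_that("the ELBO is non-decreasing and reproducible", {
  dat <- lowRankData(seed = 7, d = 10, n = 200, qTrue = 3, snr = 5,
                     missRate = 0.1)
  coh <- matrixCohort(dat$masked)
  fit <- fitBPCA(coh, maxIter = 2000)
  tr <- elboTrace(fit)
  expect_true(all(diff(tr) >= -1e-8))
  expect_gte(tr[length(tr)], tr[1])
  e1 <- bpcaELBO(fit, coh)
  e2 <- bpcaELBO(fit, coh)
  expect_identical(e1, e2)
})

test_that("the ELBO is invariant under latent column permutation", {
  dat <- lowRankData(seed = 5, d = 8, n = 150, qTrue = 2, snr = 8,
                     missRate = 0.05)
  coh <- matrixCohort(dat$masked)
  fit <- fitBPCA(coh, maxIter = 1000)
  set.seed(1)
  perm <- sample(ncol(fit@W))
  fit2 <- fit
  fit2@W <- fit@W[, perm]
  fit2@SigmaW <- lapply(fit@SigmaW, function(s) s[perm, perm, drop = FALSE])
  fit2@alphaShape <- fit@alphaShape[perm]
  fit2@alphaRate <- fit@alphaRate[perm]
  expect_equal(bpcaELBO(fit, coh), bpcaELBO(fit2, coh), tolerance = 1e-12)
})

test_that("imputation conserves observed entries and conditions on them", {
  dat <- lowRankData(seed = 15, d = 10, n = 250, qTrue = 2, snr = 10,
                     missRate = 0.15)
  coh <- matrixCohort(dat$masked)
  fit <- fitBPCA(coh, maxIter = 1000)
  imp <- bpcaImpute(fit, coh)
  obs <- !dat$mask
  expect_identical(imp$completed[obs], dat$masked[obs])
  expect_true(all(imp$sd[dat$mask] > 0))
  expect_true(all(is.na(imp$sd[obs])))

  # identity on a fully observed cohort
  full <- matrixCohort(dat$full)
  expect_identical(unname(bpcaImpute(fit, full)$completed), dat$full)

  # two patients with different observed values get different imputations
  # for the same missing coordinate
  Xp <- dat$full[, 1:2]
  Xp[1, ] <- NA
  expect_false(isTRUE(all.equal(Xp[, 1], Xp[, 2])))
  imp2 <- bpcaImpute(fit, matrixCohort(Xp))
  expect_gt(abs(imp2$completed[1, 1] - imp2$completed[1, 2]), 1e-6)
})

test_that("a fully unobserved patient falls back to the model marginal", {
  dat <- lowRankData(seed = 23, d = 6, n = 120, qTrue = 2, snr = 10)
  fit <- fitBPCA(matrixCohort(dat$full), maxIter = 500)
  Xe <- dat$full[, 1:3]
  Xe[, 2] <- NA
  expect_warning(imp <- bpcaImpute(fit, matrixCohort(Xe)),
                 "no observed entries")
  expect_equal(unname(imp$completed[, 2]), fit@mu)
  marg <- sqrt(diag(tcrossprod(fit@W)) + 1 / noisePrecision(fit))
  expect_equal(unname(imp$sd[, 2]), unname(marg), tolerance = 1e-12)
})

test_that("center adaptation recovers a constant level shift", {
  dat <- lowRankData(seed = 91, d = 10, n = 500, qTrue = 2, snr = 1e6)
  fit <- fitBPCA(matrixCohort(dat$full), maxIter = 1000)

  set.seed(92)
  shift <- rnorm(10)
  n2 <- 300
  X2 <- dat$W %*% matrix(rnorm(2 * n2), 2) + rowMeans(dat$full) + shift +
    1e-3 * matrix(rnorm(10 * n2), 10)
  mask <- matrix(runif(10 * n2) < 0.15, 10, n2)
  X2m <- X2; X2m[mask] <- NA
  ctr <- matrixCohort(X2m)

  frozen <- adaptCenter(fit, ctr, mode = "frozen")
  expect_identical(frozen$completed, bpcaImpute(fit, ctr)$completed)

  rec <- adaptCenter(fit, ctr, mode = "recenter")
  rmseRec <- sqrt(mean((rec$completed[mask] - X2[mask])^2))
  rmseFrz <- sqrt(mean((frozen$completed[mask] - X2[mask])^2))
  expect_lt(rmseRec, rmseFrz / 5)

  # no missing data: both modes return the input unchanged
  full2 <- matrixCohort(X2)
  expect_identical(unname(adaptCenter(fit, full2, "frozen")$completed), X2)
  expect_identical(unname(adaptCenter(fit, full2, "recenter")$completed),
                   X2)
})
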