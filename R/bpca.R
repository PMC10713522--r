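#' @include schema.R standardize.R
NULL

# --- internal helpers -------------------------------------------------------

# group columns of a logical matrix by identical pattern; returns list of
# integer index vectors
patternGroups <- function(mask) {
  key <- apply(mask, 2L, function(z) paste(as.integer(z), collapse = ""))
  split(seq_len(ncol(mask)), key)
}

gammaMeans <- function(shape, rate) {
  list(mean = shape / rate, logMean = digamma(shape) - log(rate))
}

# Kullback-type ELBO contribution of a Gamma factor: E[log p] - E[log q]
gammaElboTerm <- function(shape, rate, a0, b0) {
  gm <- gammaMeans(shape, rate)
  a0 * log(b0) - lgamma(a0) + (a0 - shape) * gm$logMean - b0 * gm$mean -
    shape * log(rate) + lgamma(shape) + shape
}

#' Fit a Bayesian PCA imputation model
#'
#' Fits the linear-Gaussian latent factor model with ARD column priors on a
#' (standardized) reference cohort by mean-field variational EM, marginalizing
#' missing entries patient-wise: only the observed rows of the loading matrix
#' enter each patient's likelihood. The ARD precisions prune latent columns
#' the data do not support, so the effective subspace dimension is selected
#' automatically; broad conjugate Gamma hyperpriors keep the procedure
#' essentially parameter-free. Iterates until the relative change of the
#' evidence lower bound falls below \code{tol} (the ELBO is non-decreasing
#' across iterations).
#'
#' @param cohort a \linkS4class{PACohort}, typically standardized with
#'   [standardizeCohort()]; every column must have at least 2 observed
#'   entries, and at least 3 patients are required.
#' @param q maximal latent dimension; default \code{min(d - 1, n - 1)}.
#' @param maxIter,tol iteration cap and relative-ELBO convergence tolerance.
#' @param pruneThreshold a latent column is counted as retained when its
#'   posterior-mean loading norm exceeds this (standardized scale).
#' @param hyper broad Gamma(shape, rate) hyperprior used for both the ARD
#'   precisions and the noise precision.
#' @return A \linkS4class{BPCAModel}. If \code{maxIter} is reached before
#'   convergence the model is returned with \code{converged = FALSE} and a
#'   warning.
#' @export
#' @examples
#' sim <- generateCohort(cohortConfig(nPatients = 60, seed = 3))
#' ref <- standardizeCohort(sim$cohort, referenceStats(sim$cohort))
#' fit <- fitBPCA(ref, q = 5, maxIter = 50)
#' qEff(fit)
fitBPCA <- function(cohort, q = NULL, maxIter = 2000L, tol = 1e-7,
                    pruneThreshold = 1e-3,
                    hyper = c(shape = 1e-3, rate = 1e-3)) {
  X <- cohortValues(cohort)          # d x n
  obs <- observedMask(cohort)
  d <- nrow(X)
  n <- ncol(X)
  if (n < 3L) stop("fit error: need at least 3 patients")
  nObsPerRow <- rowSums(obs)
  if (any(nObsPerRow < 2L))
    stop("fit error: column(s) with fewer than 2 observed entries: ",
         paste(rownames(X)[nObsPerRow < 2L], collapse = ", "))
  if (is.null(q)) q <- min(d - 1L, n - 1L)
  q <- as.integer(q)
  stopifnot(q >= 1L, q <= d - 1L)
  a0 <- hyper[["shape"]]; b0 <- hyper[["rate"]]
  Nobs <- sum(obs)

  # deterministic initialization from the mean-imputed matrix
  mu <- rowSums(X * obs, na.rm = TRUE) / nObsPerRow
  X0 <- X
  X0[!obs] <- 0
  Xc <- (X0 - mu) * obs
  sv <- svd(Xc, nu = q, nv = 0)
  M <- sv$u %*% diag(sv$d[seq_len(q)] / sqrt(n), q)   # d x q loadings E[W]
  SigmaW <- rep(list(diag(1e-2, q)), d)
  res0 <- max(sum((Xc - sv$u %*% (crossprod(sv$u, Xc)))^2) / Nobs, 1e-9)
  tauShape <- a0 + Nobs / 2 + d * q / 2
  tauRate <- tauShape * res0
  Ew2 <- colSums(M^2) + d * 1e-2
  alphaShape <- rep(a0 + d / 2, q)
  alphaRate <- b0 + Ew2 / (2 * res0)

  pat <- patternGroups(obs)
  patObs <- lapply(pat, function(ix) which(obs[, ix[1L]]))
  nPat <- length(pat)
  patOf <- integer(n)
  for (g in seq_len(nPat)) patOf[pat[[g]]] <- g

  m <- matrix(0, q, n)
  Slist <- vector("list", nPat)
  elbo <- numeric(0)
  converged <- FALSE
  iter <- 0L

  sigArr <- function() {
    # q x q x d array view of SigmaW for fast subsetting
    array(unlist(SigmaW), dim = c(q, q, d))
  }

  for (iter in seq_len(maxIter)) {
    Et <- tauShape / tauRate
    Ea <- alphaShape / alphaRate

    # ---- q(Z): per missingness pattern ----
    SA <- sigArr()
    for (g in seq_len(nPat)) {
      O <- patObs[[g]]
      idx <- pat[[g]]
      if (!length(O)) {
        Slist[[g]] <- diag(1, q)
        m[, idx] <- 0
        next
      }
      MO <- M[O, , drop = FALSE]
      A <- crossprod(MO) +
        matrix(rowSums(SA[, , O, drop = FALSE], dims = 2L), q, q)
      S <- solve(diag(1, q) + Et * A)
      S <- (S + t(S)) / 2
      Slist[[g]] <- S
      R <- X[O, idx, drop = FALSE] - mu[O]
      m[, idx] <- Et * (S %*% crossprod(MO, R))
    }

    # per-pattern sums reused by the W-step: sum over patients of
    # (m m^T + S), accumulated pattern-wise
    patCount <- lengths(pat)
    # ---- q(W): per marker row ----
    Ezz <- vector("list", nPat)       # per-pattern sum of m m^T + n_p S
    for (g in seq_len(nPat)) {
      mg <- m[, pat[[g]], drop = FALSE]
      Ezz[[g]] <- tcrossprod(mg) + patCount[g] * Slist[[g]]
    }
    for (i in seq_len(d)) {
      Ni <- which(obs[i, ])
      gTab <- tabulate(patOf[Ni], nPat)
      B <- matrix(0, q, q)
      for (g in which(gTab > 0L)) {
        if (gTab[g] == patCount[g]) B <- B + Ezz[[g]]
        else {
          sub <- intersect(pat[[g]], Ni)
          mg <- m[, sub, drop = FALSE]
          B <- B + tcrossprod(mg) + length(sub) * Slist[[g]]
        }
      }
      Sig <- solve(Et * (diag(Ea, q) + B))
      Sig <- (Sig + t(Sig)) / 2
      SigmaW[[i]] <- Sig
      M[i, ] <- Et * (Sig %*% (m[, Ni, drop = FALSE] %*%
                                 (X[i, Ni] - mu[i])))
    }

    # ---- mu (exact coordinate maximization) ----
    P <- M %*% m
    mu <- rowSums((X0 - P) * obs) / nObsPerRow

    # ---- q(alpha) ----
    SA <- sigArr()
    sigDiagSums <- vapply(seq_len(q), function(j) sum(SA[j, j, ]), 0)
    Ew2 <- colSums(M^2) + sigDiagSums
    alphaRate <- b0 + Et * Ew2 / 2
    Ea <- alphaShape / alphaRate

    # ---- q(tau): expected sum of squared residuals over observed cells ----
    P <- M %*% m
    Rsq <- sum((((X0 - mu) - P) * obs)^2)
    crossTerms <- 0
    for (g in seq_len(nPat)) {
      O <- patObs[[g]]
      idx <- pat[[g]]
      if (!length(O)) next
      S <- Slist[[g]]
      MO <- M[O, , drop = FALSE]
      # sum_i in O  M_i^T S M_i, once per patient of the pattern
      crossTerms <- crossTerms +
        patCount[g] * sum((MO %*% S) * MO)
      # sum_n in pattern  m_n^T Sigma_i m_n + tr(Sigma_i S), rows i in O
      mg <- m[, idx, drop = FALSE]
      Zg <- tcrossprod(mg) + patCount[g] * S    # sum over pattern of E[z z^T]
      for (i in O)
        crossTerms <- crossTerms + sum(SigmaW[[i]] * Zg)
    }
    Rexp <- Rsq + crossTerms
    ga <- gammaMeans(alphaShape, alphaRate)
    tauRate <- b0 + Rexp / 2 + sum(ga$mean * Ew2) / 2
    gt <- gammaMeans(tauShape, tauRate)
    Et <- gt$mean

    # ---- ELBO ----
    Llik <- 0.5 * Nobs * (gt$logMean - log(2 * pi)) - 0.5 * Et * Rexp
    Lz <- 0
    for (g in seq_len(nPat)) {
      S <- Slist[[g]]
      mg <- m[, pat[[g]], drop = FALSE]
      Lz <- Lz + patCount[g] *
        (0.5 * determinant(S)$modulus[1] + 0.5 * q -
           0.5 * sum(diag(S))) - 0.5 * sum(mg^2)
    }
    Lw <- 0.5 * d * q + 0.5 * d * q * gt$logMean +
      0.5 * d * sum(ga$logMean) -
      0.5 * Et * sum(ga$mean * Ew2) +
      0.5 * sum(vapply(SigmaW, function(s) determinant(s)$modulus[1], 0))
    Lalpha <- sum(gammaElboTerm(alphaShape, alphaRate, a0, b0))
    Ltau <- gammaElboTerm(tauShape, tauRate, a0, b0)
    elbo <- c(elbo, Llik + Lz + Lw + Lalpha + Ltau)

    if (iter > 1L) {
      rel <- abs(elbo[iter] - elbo[iter - 1L]) /
        max(abs(elbo[iter]), 1e-12)
      if (rel < tol) { converged <- TRUE; break }
    }
  }
  if (!converged)
    warning("BPCA did not converge in ", maxIter, " iterations")

  keep <- sqrt(colSums(M^2)) > pruneThreshold
  new("BPCAModel",
      W = M, SigmaW = SigmaW, mu = as.numeric(mu),
      tauShape = tauShape, tauRate = tauRate,
      alphaShape = alphaShape, alphaRate = alphaRate,
      keep = keep, qEff = as.integer(sum(keep)),
      elboTrace = elbo, iterations = iter, converged = converged,
      markerNames = rownames(X), pruneThreshold = pruneThreshold)
}

#' Impute missing cohort entries with a fitted BPCA model
#'
#' For each patient, forms the posterior over the latent position given the
#' patient's observed entries under the frozen model, and fills every missing
#' entry with its posterior predictive mean; observed entries are never
#' altered. The predictive SD of each imputed cell is reported. Because the
#' posterior is conditioned per patient, two patients with different observed
#' values receive different imputations for the same missing marker --
#' unlike mean imputation.
#'
#' @param model a \linkS4class{BPCAModel}.
#' @param cohort a \linkS4class{PACohort} on the same standardized scale and
#'   column layout as the model's training cohort.
#' @return list with \code{completed} (markers x patients matrix),
#'   \code{sd} (predictive SD, \code{NA} at observed cells), \code{latent}
#'   (q x patients posterior mean). A patient with no observed entries is
#'   imputed to the model mean with marginal predictive SD (with a warning).
#' @export
bpcaImpute <- function(model, cohort) {
  X <- cohortValues(cohort)
  obs <- observedMask(cohort)
  if (!identical(rownames(X), model@markerNames))
    stop("cohort columns do not match the model's marker layout")
  d <- nrow(X); n <- ncol(X); q <- ncol(model@W)
  W <- model@W; mu <- model@mu
  tau <- model@tauShape / model@tauRate
  completed <- X
  sdMat <- matrix(NA_real_, d, n, dimnames = dimnames(X))
  latent <- matrix(0, q, n)
  empty <- which(colSums(obs) == 0L)
  if (length(empty))
    warning(length(empty), " patient(s) with no observed entries imputed ",
            "to the model mean")
  pat <- patternGroups(obs)
  for (g in seq_along(pat)) {
    idx <- pat[[g]]
    O <- which(obs[, idx[1L]])
    Mi <- setdiff(seq_len(d), O)
    if (length(O)) {
      WO <- W[O, , drop = FALSE]
      S <- solve(diag(1, q) + tau * crossprod(WO))
      S <- (S + t(S)) / 2
      mg <- tau * (S %*% crossprod(WO, X[O, idx, drop = FALSE] - mu[O]))
    } else {
      S <- diag(1, q)
      mg <- matrix(0, q, length(idx))
    }
    latent[, idx] <- mg
    if (length(Mi)) {
      WM <- W[Mi, , drop = FALSE]
      completed[Mi, idx] <- mu[Mi] + WM %*% mg
      predVar <- rowSums((WM %*% S) * WM) + 1 / tau
      sdMat[Mi, idx] <- sqrt(predVar)
    }
  }
  list(completed = completed, sd = sdMat, latent = latent)
}

#' Completed cohort from an imputation result
#'
#' Rebuilds a fully observed \linkS4class{PACohort} from a cohort and the
#' imputation of its missing cells, preserving center, labels, schema and
#' metadata.
#'
#' @param cohort the original \linkS4class{PACohort}.
#' @param imputation result of [bpcaImpute()] / [adaptCenter()] on it.
#' @return A fully observed \linkS4class{PACohort}.
#' @export
completedCohort <- function(cohort, imputation) {
  out <- cohort
  SummarizedExperiment::assay(out, "values") <- imputation$completed
  SummarizedExperiment::assay(out, "observed") <-
    matrix(TRUE, nrow(imputation$completed), ncol(imputation$completed),
           dimnames = dimnames(imputation$completed))
  out
}

#' Evidence lower bound of a model on a cohort
#'
#' Recomputes the variational lower bound of the model evidence on the
#' observed entries of \code{cohort}, with the latent posterior set to its
#' optimum under the (frozen) model state. Deterministic: identical inputs
#' give identical values to full floating precision. Invariant under joint
#' permutation of the latent columns of the model.
#'
#' @param model a \linkS4class{BPCAModel}.
#' @param cohort a \linkS4class{PACohort} matching the model layout.
#' @return scalar ELBO.
#' @export
bpcaELBO <- function(model, cohort) {
  X <- cohortValues(cohort)
  obs <- observedMask(cohort)
  if (!identical(rownames(X), model@markerNames))
    stop("cohort columns do not match the model's marker layout")
  d <- nrow(X); n <- ncol(X); q <- ncol(model@W)
  M <- model@W; mu <- model@mu; SigmaW <- model@SigmaW
  a0 <- 1e-3; b0 <- 1e-3
  gt <- gammaMeans(model@tauShape, model@tauRate)
  ga <- gammaMeans(model@alphaShape, model@alphaRate)
  Et <- gt$mean
  Nobs <- sum(obs)
  SA <- array(unlist(SigmaW), dim = c(q, q, d))
  pat <- patternGroups(obs)
  Lz <- 0; Rexp <- 0
  X0 <- X; X0[!obs] <- 0
  for (g in seq_along(pat)) {
    idx <- pat[[g]]
    O <- which(obs[, idx[1L]])
    np <- length(idx)
    if (length(O)) {
      MO <- M[O, , drop = FALSE]
      A <- crossprod(MO) +
        matrix(rowSums(SA[, , O, drop = FALSE], dims = 2L), q, q)
      S <- solve(diag(1, q) + Et * A)
      S <- (S + t(S)) / 2
      R <- X[O, idx, drop = FALSE] - mu[O]
      mg <- Et * (S %*% crossprod(MO, R))
      r <- R - MO %*% mg
      Zg <- tcrossprod(mg) + np * S
      Rexp <- Rexp + sum(r^2) + np * sum((MO %*% S) * MO)
      for (i in O) Rexp <- Rexp + sum(SigmaW[[i]] * Zg)
    } else {
      S <- diag(1, q)
      mg <- matrix(0, q, np)
    }
    Lz <- Lz + np * (0.5 * determinant(S)$modulus[1] + 0.5 * q -
                       0.5 * sum(diag(S))) - 0.5 * sum(mg^2)
  }
  Ew2 <- colSums(M^2) + vapply(seq_len(q), function(j)
    sum(SA[j, j, ]), 0)
  Llik <- 0.5 * Nobs * (gt$logMean - log(2 * pi)) - 0.5 * Et * Rexp
  Lw <- 0.5 * d * q + 0.5 * d * q * gt$logMean + 0.5 * d * sum(ga$logMean) -
    0.5 * Et * sum(ga$mean * Ew2) +
    0.5 * sum(vapply(SigmaW, function(s) determinant(s)$modulus[1], 0))
  Lalpha <- sum(gammaElboTerm(model@alphaShape, model@alphaRate, a0, b0))
  Ltau <- gammaElboTerm(model@tauShape, model@tauRate, a0, b0)
  as.numeric(Llik + Lz + Lw + Lalpha + Ltau)
}

#' Adapt a target-center cohort to the reference model
#'
#' Cross-center adaptation by imputation: the latent principal subspace
#' learned on the data-rich reference center is reused to fill the missing
#' fields of another center so that the estimated distribution fits the
#' center's observed fields. \code{"frozen"} (default) applies the reference
#' model unchanged; \code{"recenter"} first re-estimates the mean vector on
#' the center's observed entries (loadings, noise and ARD state stay frozen),
#' for centers with a systematic level shift.
#'
#' @param model a \linkS4class{BPCAModel} fitted on the reference cohort.
#' @param cohort the target-center \linkS4class{PACohort} (standardized with
#'   the reference statistics).
#' @param mode "frozen" or "recenter".
#' @return As [bpcaImpute()]; for \code{"recenter"} the list also carries the
#'   re-estimated mean as \code{mu}.
#' @export
adaptCenter <- function(model, cohort, mode = c("frozen", "recenter")) {
  mode <- match.arg(mode)
  if (mode == "frozen") return(bpcaImpute(model, cohort))
  X <- cohortValues(cohort)
  obs <- observedMask(cohort)
  if (!identical(rownames(X), model@markerNames))
    stop("cohort columns do not match the model's marker layout")
  W <- model@W
  q <- ncol(W)
  tau <- model@tauShape / model@tauRate
  mu <- model@mu
  nObsPerRow <- rowSums(obs)
  X0 <- X; X0[!obs] <- 0
  pat <- patternGroups(obs)
  m <- matrix(0, q, ncol(X))
  for (k in seq_len(200L)) {
    for (g in seq_along(pat)) {
      idx <- pat[[g]]
      O <- which(obs[, idx[1L]])
      if (!length(O)) { m[, idx] <- 0; next }
      WO <- W[O, , drop = FALSE]
      S <- solve(diag(1, q) + tau * crossprod(WO))
      m[, idx] <- tau * (S %*% crossprod(WO, X[O, idx, drop = FALSE] -
                                           mu[O]))
    }
    muNew <- rowSums((X0 - W %*% m) * obs) / nObsPerRow
    muNew[nObsPerRow == 0L] <- model@mu[nObsPerRow == 0L]
    if (max(abs(muNew - mu)) < 1e-12) { mu <- muNew; break }
    mu <- muNew
  }
  shifted <- model
  shifted@mu <- as.numeric(mu)
  out <- bpcaImpute(shifted, cohort)
  out$mu <- as.numeric(mu)
  out
}

#' @rdname BPCAModel-accessors
#' @export
setMethod("loadings", "BPCAModel", function(x, all = FALSE) {
  if (all) x@W else x@W[, x@keep, drop = FALSE]
})

#' @rdname BPCAModel-accessors
#' @export
setMethod("qEff", "BPCAModel", function(x) x@qEff)

#' @rdname BPCAModel-accessors
#' @export
setMethod("noisePrecision", "BPCAModel", function(x) x@tauShape / x@tauRate)

#' @rdname BPCAModel-accessors
#' @export
setMethod("ardPrecisions", "BPCAModel",
          function(x) x@alphaShape / x@alphaRate)

#' @rdname BPCAModel-accessors
#' @export
setMethod("elboTrace", "BPCAModel", function(x) x@elboTrace)

setMethod("show", "BPCAModel", function(object) {
  cat("BPCAModel:", nrow(object@W), "markers,",
      ncol(object@W), "latent columns,", object@qEff, "retained\n")
  cat(sprintf("  noise precision %.4g; %d iterations (%s)\n",
              noisePrecision(object), object@iterations,
              if (object@converged) "converged" else "NOT converged"))
  cat(sprintf("  final ELBO %.6g\n",
              object@elboTrace[length(object@elboTrace)]))
})
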