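#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
NULL

#' Subtype track labels
#'
#' The three retrospective treatment categories used throughout the package:
#' patients whose aldosterone-producing adenoma (APA) is visible on CT and can
#' go straight to adrenalectomy (\code{"surgery-track"}), APA patients whom CT
#' cannot localize and who therefore need adrenal venous sampling
#' (\code{"AVS-recommended"}), and idiopathic hyperaldosteronism treated with
#' mineralocorticoid receptor antagonists (\code{"medication-track"}).
#'
#' @return Character vector of the three track labels, in canonical order.
#' @export
#' @examples
#' paTracks()
paTracks <- function() {
  c("surgery-track", "AVS-recommended", "medication-track")
}

#' MarkerSchema: the clinical marker dictionary
#'
#' An ordered dictionary of the predictor markers a cohort table carries:
#' marker name, kind (continuous, binary or categorical), measurement units,
#' and the allowed levels for categorical markers. Categorical markers are
#' expanded to one indicator column per level in the encoded cohort matrix.
#'
#' @slot markers data.frame with columns \code{name}, \code{kind},
#'   \code{units}.
#' @slot levels named list: allowed levels per categorical marker.
#' @slot labelColumn name of the subtype label column in cohort files.
#' @slot centerColumn name of the center identifier column in cohort files.
#' @slot missingToken token representing a missing cell in cohort files.
#'
#' @seealso [markerSchema()], [paSchema()]
#' @export
setClass("MarkerSchema",
  representation(
    markers = "data.frame",
    levels = "list",
    labelColumn = "character",
    centerColumn = "character",
    missingToken = "character"
  )
)

setValidity("MarkerSchema", function(object) {
  m <- object@markers
  msg <- character()
  if (!all(c("name", "kind", "units") %in% names(m)))
    msg <- c(msg, "markers must have columns name, kind, units")
  else {
    if (anyDuplicated(m$name))
      msg <- c(msg, "marker names must be unique")
    if (!all(m$kind %in% c("continuous", "binary", "categorical")))
      msg <- c(msg, "kind must be continuous, binary or categorical")
    if (any(m$kind == "continuous" & (is.na(m$units) | m$units == "")))
      msg <- c(msg, "every continuous marker must declare units")
    cat_names <- m$name[m$kind == "categorical"]
    if (!all(cat_names %in% names(object@levels)))
      msg <- c(msg, "every categorical marker needs an entry in levels")
    if (any(vapply(object@levels[cat_names], length, 1L) < 2))
      msg <- c(msg, "categorical markers need at least 2 levels")
  }
  if (length(object@missingToken) != 1L || !nzchar(object@missingToken))
    msg <- c(msg, "missingToken must be a single non-empty string")
  if (length(msg)) msg else TRUE
})

#' PACohort: a patient cohort with explicit missingness
#'
#' A \linkS4class{SummarizedExperiment} holding an encoded patient cohort:
#' rows are encoded markers (categorical markers expanded to indicator
#' columns), columns are patients. Two assays: \code{values} (numeric, with
#' \code{NA} as the internal sentinel for unobserved cells) and
#' \code{observed} (logical mask; \code{TRUE} iff the value is finite).
#' \code{colData} carries the center identifier and, when available, the
#' three-way subtype label. The governing \linkS4class{MarkerSchema} lives in
#' \code{metadata(x)$schema}.
#'
#' @export
setClass("PACohort", contains = "SummarizedExperiment")

setValidity("PACohort", function(object) {
  msg <- character()
  if (!all(c("values", "observed") %in% names(assays(object))))
    msg <- c(msg, "PACohort needs assays 'values' and 'observed'")
  else {
    v <- assay(object, "values")
    o <- assay(object, "observed")
    if (!is.numeric(v)) msg <- c(msg, "'values' assay must be numeric")
    if (!is.logical(o)) msg <- c(msg, "'observed' assay must be logical")
    if (is.numeric(v) && is.logical(o)) {
      # mask TRUE <=> value finite
      if (!all(is.finite(v[o])) || any(is.finite(v[!o])))
        msg <- c(msg, "observed mask must be TRUE exactly where values are finite")
    }
  }
  if (!"center" %in% names(colData(object)))
    msg <- c(msg, "colData must contain 'center'")
  if (length(msg)) msg else TRUE
})

#' ReferenceStats: standardization statistics of the reference cohort
#'
#' Per-marker location/scale computed over the observed entries of a reference
#' cohort, used to put reference and target cohorts on one standardized
#' coordinate system before BPCA. Continuous markers are z-scored; binary and
#' indicator columns are left on their natural [0, 1] scale. Level frequencies
#' of categorical markers are retained for reporting.
#'
#' @slot stats data.frame with columns \code{column}, \code{mean}, \code{sd},
#'   \code{scaled} (logical: does standardization touch this column).
#' @slot levelFreq named list of level frequency tables for categorical
#'   markers.
#' @export
setClass("ReferenceStats",
  representation(stats = "data.frame", levelFreq = "list")
)

setValidity("ReferenceStats", function(object) {
  s <- object@stats
  if (!all(c("column", "mean", "sd", "scaled") %in% names(s)))
    return("stats must have columns column, mean, sd, scaled")
  if (any(s$scaled & (!is.finite(s$sd) | s$sd <= 0)))
    return("standard deviations must be > 0 for all standardized markers")
  TRUE
})

#' BPCAModel: variational Bayesian PCA imputation model
#'
#' The fitted linear-Gaussian latent factor model
#' \deqn{x_n = W z_n + \mu + \epsilon_n,\quad z_n \sim N(0, I_q),\quad
#'       \epsilon_n \sim N(0, \tau^{-1} I_d),}
#' with an automatic relevance determination (ARD) prior on the columns of the
#' loading matrix, \eqn{w_j \sim N(0, \alpha_j^{-1} I_d)}, fitted by
#' mean-field variational EM with per-entry missingness. Redundant latent
#' directions are pruned by the ARD mechanism; \code{qEff} counts the retained
#' ones.
#'
#' @slot W d x q posterior-mean loading matrix.
#' @slot SigmaW list of d per-row q x q posterior covariances.
#' @slot mu length-d mean vector (point estimate).
#' @slot tauShape,tauRate Gamma posterior of the noise precision tau.
#' @slot alphaShape,alphaRate Gamma posteriors of the ARD precisions.
#' @slot keep logical: which latent columns survive ARD pruning.
#' @slot qEff number of retained latent dimensions.
#' @slot elboTrace evidence lower bound per iteration (non-decreasing).
#' @slot iterations iterations run; @slot converged convergence flag.
#' @slot markerNames encoded column names the model was fitted on.
#' @slot pruneThreshold loading-norm threshold used for \code{qEff}.
#' @export
setClass("BPCAModel",
  representation(
    W = "matrix", SigmaW = "list", mu = "numeric",
    tauShape = "numeric", tauRate = "numeric",
    alphaShape = "numeric", alphaRate = "numeric",
    keep = "logical", qEff = "integer",
    elboTrace = "numeric", iterations = "integer", converged = "logical",
    markerNames = "character", pruneThreshold = "numeric"
  )
)

setValidity("BPCAModel", function(object) {
  msg <- character()
  q <- ncol(object@W)
  d <- nrow(object@W)
  if (length(object@mu) != d) msg <- c(msg, "mu must have length nrow(W)")
  if (object@tauShape <= 0 || object@tauRate <= 0)
    msg <- c(msg, "tau posterior parameters must be positive")
  if (any(object@alphaShape <= 0) || any(object@alphaRate <= 0))
    msg <- c(msg, "alpha posterior parameters must be positive")
  if (object@qEff > q) msg <- c(msg, "qEff cannot exceed ncol(W)")
  if (length(msg)) msg else TRUE
})

#' TrackClassifier: a binary subtype classifier for one track
#'
#' Wraps a fitted binary classifier for one of the two triage questions:
#' surgery-track vs the rest, or medication-track vs the rest. Families:
#' L2/L1-regularized logistic regression (\code{"lr-l2"}, \code{"lr-l1"}),
#' random forest (\code{"rf"}), multilayer perceptron (\code{"mlp"}).
#' Predicts a probability per patient; the binary call thresholds it.
#'
#' @slot track "surgery" or "medication".
#' @slot family one of "lr-l2", "lr-l1", "rf", "mlp".
#' @slot hyper hyperparameter list used for the fit.
#' @slot fit the underlying fitted model object.
#' @slot threshold decision threshold on the predicted probability.
#' @slot featureNames encoded marker columns the model consumes, in order.
#' @slot seed RNG seed used for the fit (stochastic families).
#' @slot metrics validation metrics recorded at selection time (list).
#' @export
setClass("TrackClassifier",
  representation(
    track = "character", family = "character", hyper = "list",
    fit = "ANY", threshold = "numeric", featureNames = "character",
    seed = "integer", metrics = "list"
  )
)

setValidity("TrackClassifier", function(object) {
  msg <- character()
  if (!object@track %in% c("surgery", "medication"))
    msg <- c(msg, "track must be 'surgery' or 'medication'")
  if (!object@family %in% c("lr-l2", "lr-l1", "rf", "mlp"))
    msg <- c(msg, "unknown classifier family")
  if (object@threshold < 0 || object@threshold > 1)
    msg <- c(msg, "threshold must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
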