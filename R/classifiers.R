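#' @include schema.R
NULL

#' Harmonic-mean f-score of sensitivity and specificity
#'
#' The model-selection metric used throughout: the harmonic mean of the true
#' positive rate and the true negative rate, \eqn{2 \cdot TPR \cdot TNR /
#' (TPR + TNR)}. This is not the precision/recall F1; it balances the two
#' error types of a diagnostic rule symmetrically and is 0 as soon as either
#' rate is 0.
#'
#' @param tpr,tnr rates in [0, 1]; vectors allowed.
#' @return numeric f-score(s); \code{NA} propagates.
#' @export
#' @examples
#' fScore(0.87, 0.85)  # 0.86 to two decimals
#' fScore(0.9, 0)      # 0
fScore <- function(tpr, tnr) {
  if (any(stats::na.omit(c(tpr, tnr)) < 0) ||
      any(stats::na.omit(c(tpr, tnr)) > 1))
    stop("rates must lie in [0, 1]")
  out <- ifelse(tpr + tnr == 0, 0, 2 * tpr * tnr / (tpr + tnr))
  as.numeric(out)
}

#' Binary labels for one triage track
#'
#' Pools the three subtype categories into the binary question one track
#' classifier answers: the track's own class is positive, the other two are
#' negative.
#'
#' @param labels subtype labels (values of [paTracks()]).
#' @param track "surgery" or "medication".
#' @return integer 0/1 vector.
#' @export
#' @examples
#' makeBinaryLabels(paTracks(), "surgery")    # 1 0 0
#' makeBinaryLabels(paTracks(), "medication") # 0 0 1
makeBinaryLabels <- function(labels, track = c("surgery", "medication")) {
  track <- match.arg(track)
  labels <- as.character(labels)
  if (!length(labels)) stop("labels must be non-empty")
  if (any(is.na(labels)) || !all(labels %in% paTracks()))
    stop("unknown label value(s): ",
         paste(unique(labels[is.na(labels) | !labels %in% paTracks()]),
               collapse = ", "))
  pos <- if (track == "surgery") paTracks()[1L] else paTracks()[3L]
  as.integer(labels == pos)
}

defaultHyper <- function(family) {
  switch(family,
    "lr-l2" = list(C = 1, class_weight = "balanced"),
    "lr-l1" = list(C = 1, class_weight = "balanced"),
    "rf" = list(nTrees = 2000),
    "mlp" = list(size = 6, epochs = 100, decay = 1e-3,
                 class_weight = "balanced")
  )
}

#' Default hyperparameter grids
#'
#' Small per-family grids spanning the regions where the published optima
#' live: logistic C in \{0.005 .. 4\} for either penalty, forests up to 2000
#' trees, perceptron hidden widths 5-6 with up to 100 epochs.
#'
#' @param family classifier family.
#' @return list of hyperparameter lists, in declared (tie-break) order.
#' @export
defaultGrid <- function(family = c("lr-l2", "lr-l1", "rf", "mlp")) {
  family <- match.arg(family)
  switch(family,
    "lr-l2" = lapply(c(0.005, 0.11, 1, 4), function(C)
      list(C = C, class_weight = "balanced")),
    "lr-l1" = lapply(c(0.005, 0.11, 1, 4), function(C)
      list(C = C, class_weight = "balanced")),
    "rf" = lapply(c(500, 1000, 2000), function(k) list(nTrees = k)),
    "mlp" = {
      g <- expand.grid(size = c(5, 6), decay = c(1e-3, 1e-2))
      lapply(seq_len(nrow(g)), function(i)
        list(size = g$size[i], epochs = 100, decay = g$decay[i],
             class_weight = "balanced"))
    }
  )
}

checkCompleted <- function(cohort) {
  if (!all(observedMask(cohort)))
    stop("cohort contains masked entries; imputation must precede ",
         "classification (see bpcaImpute/adaptCenter)")
}

balancedWeights <- function(y) {
  n <- length(y)
  tab <- table(y)
  as.numeric(n / (2 * tab[as.character(y)]))
}

#' Train a binary track classifier
#'
#' Fits one of the four families on a completed (fully observed, typically
#' standardized) cohort: L2- or L1-regularized logistic regression minimizing
#' the penalized negative log-likelihood (glmnet; the regularization strength
#' is exposed sklearn-style as \code{C}, larger = weaker penalty), random
#' forest minimizing Gini impurity (randomForest), or a single-hidden-layer
#' perceptron minimizing binary cross-entropy (nnet). \code{class_weight =
#' "balanced"} reweights patients inversely to class frequency. Stochastic
#' families are seeded, so refits reproduce identical predictions.
#'
#' @param cohort completed \linkS4class{PACohort} with labels.
#' @param track "surgery" or "medication".
#' @param family "lr-l2", "lr-l1", "rf" or "mlp".
#' @param hyper hyperparameter list; missing entries take family defaults.
#' @param seed RNG seed for the stochastic families.
#' @param threshold decision threshold on the predicted probability.
#' @param labels override labels (default: the cohort's own).
#' @return A \linkS4class{TrackClassifier}.
#' @export
trainClassifier <- function(cohort, track = c("surgery", "medication"),
                            family = c("lr-l2", "lr-l1", "rf", "mlp"),
                            hyper = list(), seed = 1L, threshold = 0.5,
                            labels = subtypeLabels(cohort)) {
  track <- match.arg(track)
  family <- match.arg(family)
  checkCompleted(cohort)
  hy <- utils::modifyList(defaultHyper(family), hyper)
  X <- t(cohortValues(cohort))
  if (any(!is.finite(X))) stop("non-finite features")
  y <- makeBinaryLabels(labels, track)
  if (length(unique(y)) < 2L)
    stop("single-class training data: cannot fit a binary classifier")
  w <- if (identical(hy$class_weight, "balanced")) balancedWeights(y)
       else rep(1, length(y))
  fit <- withSeed(seed, switch(family,
    "lr-l2" = ,
    "lr-l1" = {
      lambda <- 1 / (nrow(X) * hy$C)
      glmnet::glmnet(X, y, family = "binomial",
                     alpha = if (family == "lr-l1") 1 else 0,
                     lambda = lambda, weights = w, standardize = FALSE)
    },
    "rf" = randomForest::randomForest(
      x = X, y = factor(y, levels = c(0, 1)), ntree = hy$nTrees),
    "mlp" = nnet::nnet(X, y, size = hy$size, decay = hy$decay,
                       maxit = hy$epochs, entropy = TRUE, weights = w,
                       trace = FALSE, MaxNWts = 5000)
  ))
  new("TrackClassifier", track = track, family = family, hyper = hy,
      fit = fit, threshold = threshold, featureNames = colnames(X),
      seed = as.integer(seed), metrics = list())
}

#' Predicted track probability per patient
#'
#' @param classifier a \linkS4class{TrackClassifier}.
#' @param cohort completed \linkS4class{PACohort} with the same marker
#'   layout.
#' @return numeric vector of probabilities in [0, 1].
#' @export
predictProb <- function(classifier, cohort) {
  checkCompleted(cohort)
  X <- t(cohortValues(cohort))
  if (!identical(colnames(X), classifier@featureNames))
    stop("cohort markers do not match the classifier's feature layout")
  p <- switch(classifier@family,
    "lr-l2" = ,
    "lr-l1" = as.numeric(stats::predict(classifier@fit, X,
                                        type = "response")),
    "rf" = as.numeric(stats::predict(classifier@fit, X,
                                     type = "prob")[, "1"]),
    "mlp" = as.numeric(stats::predict(classifier@fit, X))
  )
  pmin(pmax(p, 0), 1)
}

#' Confusion metrics of a track classifier
#'
#' Thresholds the predicted probability, tallies the confusion counts and
#' reports sensitivity (TPR), specificity (TNR) and their harmonic-mean
#' f-score. If the evaluation set has no positive (or no negative) patients
#' the undefined rate and the f-score are \code{NaN} and the result is
#' flagged.
#'
#' @param classifier a \linkS4class{TrackClassifier}.
#' @param cohort completed \linkS4class{PACohort}.
#' @param labels subtype labels (default: the cohort's own).
#' @return list: \code{sensitivity}, \code{specificity}, \code{fScore},
#'   \code{counts} (TP, FN, TN, FP), \code{flagged}.
#' @export
evaluateClassifier <- function(classifier, cohort,
                               labels = subtypeLabels(cohort)) {
  y <- makeBinaryLabels(labels, classifier@track)
  p <- predictProb(classifier, cohort)
  call <- as.integer(p >= classifier@threshold)
  tp <- sum(call == 1 & y == 1); fn <- sum(call == 0 & y == 1)
  tn <- sum(call == 0 & y == 0); fp <- sum(call == 1 & y == 0)
  tpr <- tp / (tp + fn)
  tnr <- tn / (tn + fp)
  flagged <- !is.finite(tpr) || !is.finite(tnr)
  f <- if (flagged) NaN else fScore(tpr, tnr)
  list(sensitivity = tpr, specificity = tnr, fScore = f,
       counts = c(TP = tp, FN = fn, TN = tn, FP = fp), flagged = flagged)
}

#' Grid search maximizing the validation f-score
#'
#' Trains one classifier per grid point on the training cohort, evaluates
#' each on the validation cohort, and returns the point with the highest
#' validation f-score; exact ties go to the earlier point in grid order. The
#' full grid trace is returned for bookkeeping.
#'
#' @param train,validation completed labeled \linkS4class{PACohort}s.
#' @param track,family as in [trainClassifier()].
#' @param grid list of hyperparameter lists, e.g. [defaultGrid()].
#' @param seed RNG seed shared by all fits.
#' @return list: \code{classifier} (selected, with its validation metrics in
#'   \code{@metrics}), \code{metrics}, \code{trace} (data.frame of the grid).
#' @export
gridSearch <- function(train, validation, track, family,
                       grid = defaultGrid(family), seed = 1L) {
  if (!length(grid)) stop("empty hyperparameter grid")
  best <- NULL
  bestMetrics <- NULL
  bestF <- -Inf
  trace <- vector("list", length(grid))
  for (k in seq_along(grid)) {
    clf <- trainClassifier(train, track, family, hyper = grid[[k]],
                           seed = seed)
    met <- evaluateClassifier(clf, validation)
    f <- if (is.finite(met$fScore)) met$fScore else -Inf
    trace[[k]] <- data.frame(
      point = k,
      hyper = paste(names(grid[[k]]),
                    vapply(grid[[k]], function(v) paste(format(v),
                                                        collapse = "/"), ""),
                    sep = "=", collapse = ", "),
      sensitivity = met$sensitivity, specificity = met$specificity,
      fScore = met$fScore
    )
    if (f > bestF) {   # strict: ties keep the earlier grid point
      bestF <- f
      best <- clf
      bestMetrics <- met
    }
  }
  if (is.null(best)) stop("no grid point produced a usable classifier")
  best@metrics <- bestMetrics
  list(classifier = best, metrics = bestMetrics,
       trace = do.call(rbind, trace))
}

#' Ranked coefficients of a logistic track classifier
#'
#' Signed logistic-regression coefficients on the standardized marker scale,
#' sorted by magnitude; these approximate per-marker importances.
#'
#' @param classifier a \linkS4class{TrackClassifier} of a logistic family.
#' @return data.frame with columns \code{marker}, \code{coefficient}, sorted
#'   by decreasing |coefficient|.
#' @export
coefficientReport <- function(classifier) {
  if (!classifier@family %in% c("lr-l2", "lr-l1"))
    stop("coefficient report requires a logistic-regression classifier")
  cf <- as.matrix(stats::coef(classifier@fit))
  cf <- cf[rownames(cf) != "(Intercept)", 1L]
  out <- data.frame(marker = names(cf), coefficient = unname(cf))
  out[order(-abs(out$coefficient)), , drop = FALSE]
}

#' Stratified train/validation split of a labeled cohort
#'
#' @param cohort labeled \linkS4class{PACohort}.
#' @param fraction training fraction per class.
#' @param seed RNG seed.
#' @return list of two \linkS4class{PACohort}s: \code{train},
#'   \code{validation}.
#' @export
splitCohort <- function(cohort, fraction = 0.7, seed = 1L) {
  lab <- subtypeLabels(cohort)
  if (all(is.na(lab))) stop("cohort has no labels to stratify on")
  idx <- withSeed(seed, {
    unlist(lapply(levels(lab), function(cls) {
      members <- which(lab == cls)
      if (!length(members)) return(integer())
      sample(members, max(1L, round(fraction * length(members))))
    }))
  })
  list(train = cohort[, sort(idx)],
       validation = cohort[, setdiff(seq_len(ncol(cohort)), idx)])
}

setMethod("show", "TrackClassifier", function(object) {
  cat("TrackClassifier:", object@track, "track,", object@family, "\n")
  cat("  hyperparameters:",
      paste(names(object@hyper),
            vapply(object@hyper, function(v) paste(format(v),
                                                   collapse = "/"), ""),
            sep = "=", collapse = ", "), "\n")
  if (length(object@metrics))
    cat(sprintf("  validation: sens %.2f spec %.2f f %.2f\n",
                object@metrics$sensitivity, object@metrics$specificity,
                object@metrics$fScore))
})
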