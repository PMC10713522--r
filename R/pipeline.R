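#' @include bpca.R classifiers.R flowchart.R standardize.R
NULL

#' End-to-end adaptation--classification--triage pipeline
#'
#' Runs the full framework: standardize both cohorts on the reference
#' statistics, fit the BPCA imputer on the reference center, adapt (impute)
#' the multicenter target cohort, train the surgery-track and
#' medication-track classifiers by grid search, route every target patient
#' through the triage flowchart, and account for the AVS fraction and
#' decision accuracy. Fully reproducible from the inputs and \code{seed}.
#'
#' @param reference labeled reference-center \linkS4class{PACohort}.
#' @param target target multicenter \linkS4class{PACohort}; labels, when
#'   present, feed the accuracy accounting.
#' @param family classifier family used for both tracks.
#' @param grid hyperparameter grid; default [defaultGrid()] of the family.
#' @param validation \code{"split"} selects hyperparameters on a stratified
#'   held-out fraction of the reference cohort; \code{"target"} validates on
#'   the (labeled) target cohort itself, reproducing the two-cohort design in
#'   which train and test data are separate by construction.
#' @param trainFraction reference training fraction for \code{"split"}.
#' @param adaptMode "frozen" or "recenter", see [adaptCenter()].
#' @param arrCutoff surgery gate cutoff on ARR after captopril (strict).
#' @param arrGate \code{"completed"} gates on the (possibly imputed) value;
#'   \code{"observed"} gates on observed values only and routes
#'   surgery-positive patients with missing ARR to AVS conservatively.
#' @param q,maxIter passed to [fitBPCA()].
#' @param seed master seed for splitting and the stochastic families.
#' @return list of class \code{"paPipeline"}: \code{stats}, \code{bpca},
#'   \code{classifiers} (surgery, medication), \code{gridTraces},
#'   \code{completedTarget}, \code{decisions}, \code{summary}.
#' @export
#' @examples
#' ref <- generateCohort(cohortConfig(nPatients = 120, seed = 11,
#'                                    centers = "Reference"))$cohort
#' tgt <- generateCohort(cohortConfig(nPatients = 80, seed = 12))$cohort
#' res <- runPipeline(ref, tgt, grid = defaultGrid("lr-l2")[3], q = 8,
#'                    maxIter = 200)
#' res$summary
runPipeline <- function(reference, target,
                        family = "lr-l2", grid = defaultGrid(family),
                        validation = c("split", "target"),
                        trainFraction = 0.7,
                        adaptMode = c("frozen", "recenter"),
                        arrCutoff = 73.0,
                        arrGate = c("completed", "observed"),
                        q = NULL, maxIter = 2000L, seed = 1L) {
  validation <- match.arg(validation)
  adaptMode <- match.arg(adaptMode)
  arrGate <- match.arg(arrGate)
  if (all(is.na(subtypeLabels(reference))))
    stop("pipeline error [reference]: reference cohort must be labeled")

  stats <- referenceStats(reference)
  refStd <- standardizeCohort(reference, stats)
  tgtStd <- standardizeCohort(target, stats)

  model <- fitBPCA(refStd, q = q, maxIter = maxIter)
  refCompleted <- completedCohort(refStd, bpcaImpute(model, refStd))
  tgtImp <- adaptCenter(model, tgtStd, mode = adaptMode)
  tgtCompleted <- completedCohort(tgtStd, tgtImp)

  if (validation == "split") {
    sp <- splitCohort(refCompleted, fraction = trainFraction, seed = seed)
    trainSet <- sp$train
    valSet <- sp$validation
  } else {
    if (all(is.na(subtypeLabels(target))))
      stop("pipeline error [grid search]: validation = 'target' needs a ",
           "labeled target cohort")
    trainSet <- refCompleted
    valSet <- tgtCompleted
  }

  gsS <- gridSearch(trainSet, valSet, "surgery", family, grid, seed = seed)
  gsM <- gridSearch(trainSet, valSet, "medication", family, grid,
                    seed = seed)

  surgeryPos <- predictProb(gsS$classifier, tgtCompleted) >=
    gsS$classifier@threshold
  medicationPos <- predictProb(gsM$classifier, tgtCompleted) >=
    gsM$classifier@threshold

  natural <- unstandardizeValues(cohortValues(tgtCompleted), stats)
  arrCCT <- natural["arr_cct", ]
  if (arrGate == "observed")
    arrCCT[!observedMask(target)["arr_cct", ]] <- NA_real_
  ct <- deriveCTFeatures(pmax(natural["right_tumor_mm", ], 0),
                         pmax(natural["left_tumor_mm", ], 0))
  decisions <- routeCases(surgeryPos, medicationPos, arrCCT, ct,
                          arrCutoff = arrCutoff,
                          missingArrToAVS = arrGate == "observed")
  truth <- subtypeLabels(target)
  summary <- if (any(!is.na(truth)))
    summarizeFlowchart(decisions, truth) else NULL

  structure(list(
    stats = stats, bpca = model,
    classifiers = list(surgery = gsS$classifier,
                       medication = gsM$classifier),
    gridTraces = list(surgery = gsS$trace, medication = gsM$trace),
    completedTarget = tgtCompleted,
    decisions = decisions, summary = summary
  ), class = "paPipeline")
}

#' @export
print.paPipeline <- function(x, ...) {
  cat("Adaptation-classification pipeline\n")
  show(x$bpca)
  show(x$classifiers$surgery)
  show(x$classifiers$medication)
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}
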