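#' @include features.R classifiers.R
NULL

flowchartBranches <- function() {
  c("surgery-gate-pass", "surgery-gate-fail-ARR", "surgery-gate-fail-CT",
    "medication-gate-pass", "medication-gate-fail-CT", "no-model-positive")
}

#' Route patients through the sequential triage flowchart
#'
#' The surgery model is consulted first: a surgery-positive patient is sent
#' to surgery only when the post-captopril aldosterone-to-renin ratio
#' strictly exceeds the cutoff AND CT offers a defined larger tumor side (the
#' adrenalectomy side); otherwise the patient needs AVS. Surgery-negative
#' patients face the medication model: medication-positive AND CT
#' image-negative goes to medication, a visible tumor sends the patient to
#' AVS to rule out a surgical indication, and patients neither model claims
#' go to AVS as well.
#'
#' @param surgeryPositive,medicationPositive logical vectors: the two
#'   classifiers' calls per patient.
#' @param arrCCT aldosterone-to-renin ratio after the captopril challenge
#'   test (completed values: imputation precedes routing). A missing value
#'   for a surgery-positive patient is a contract error unless
#'   \code{missingArrToAVS} is set, in which case the patient is routed to
#'   AVS conservatively.
#' @param ct CT features from [deriveCTFeatures()].
#' @param arrCutoff surgery gate cutoff on \code{arrCCT} (strict inequality).
#' @param missingArrToAVS route surgery-positive patients with missing
#'   \code{arrCCT} to AVS instead of erroring.
#' @return data.frame: \code{route} (surgery/medication/AVS),
#'   \code{surgery_side} (right/left/none), \code{branch} (the gate that
#'   produced the route).
#' @export
#' @examples
#' ct <- deriveCTFeatures(c(0, 0), c(12, 0))
#' routeCases(c(TRUE, FALSE), c(FALSE, TRUE), c(105.8, NA), ct)
routeCases <- function(surgeryPositive, medicationPositive, arrCCT, ct,
                       arrCutoff = 73.0, missingArrToAVS = FALSE) {
  n <- nrow(ct)
  surgeryPositive <- rep_len(as.logical(surgeryPositive), n)
  medicationPositive <- rep_len(as.logical(medicationPositive), n)
  arrCCT <- rep_len(as.numeric(arrCCT), n)
  badArr <- surgeryPositive & !is.finite(arrCCT)
  if (any(badArr) && !missingArrToAVS)
    stop("missing ARR-after-CCT for surgery-model-positive patient(s); ",
         "imputation must precede routing")
  route <- character(n)
  side <- rep("none", n)
  branch <- character(n)
  larger <- as.character(ct$larger_side)
  lat <- as.character(ct$laterality)
  for (k in seq_len(n)) {
    if (surgeryPositive[k]) {
      if (!is.finite(arrCCT[k]) || arrCCT[k] <= arrCutoff) {
        route[k] <- "AVS"; branch[k] <- "surgery-gate-fail-ARR"
      } else if (larger[k] %in% c("right", "left")) {
        route[k] <- "surgery"; side[k] <- larger[k]
        branch[k] <- "surgery-gate-pass"
      } else {
        route[k] <- "AVS"; branch[k] <- "surgery-gate-fail-CT"
      }
    } else if (medicationPositive[k]) {
      if (lat[k] == "image-negative") {
        route[k] <- "medication"; branch[k] <- "medication-gate-pass"
      } else {
        route[k] <- "AVS"; branch[k] <- "medication-gate-fail-CT"
      }
    } else {
      route[k] <- "AVS"; branch[k] <- "no-model-positive"
    }
  }
  data.frame(
    route = factor(route, levels = c("surgery", "medication", "AVS")),
    surgery_side = factor(side, levels = c("right", "left", "none")),
    branch = factor(branch, levels = flowchartBranches())
  )
}

#' Cohort-level accounting of flowchart decisions
#'
#' Tallies routes and branches, the AVS fraction (share of patients the
#' flowchart sends to AVS), and the decision accuracy over the decided
#' (non-AVS) patients: a surgery routing is correct when the patient is truly
#' surgery-track, a medication routing when the patient is truly
#' medication-track. Percentages are reported to one decimal.
#'
#' @param decisions data.frame from [routeCases()].
#' @param truth true subtype labels (values of [paTracks()]).
#' @return list of class \code{"flowchartSummary"}: \code{n_total},
#'   \code{routeCounts}, \code{branchCounts}, \code{avs_fraction} (%),
#'   \code{decided_total}, \code{decided_correct}, \code{decision_accuracy}
#'   (%, \code{NA} and flagged when nothing was decided).
#' @export
summarizeFlowchart <- function(decisions, truth) {
  if (nrow(decisions) != length(truth))
    stop("decisions and truth must have equal length")
  truth <- as.character(truth)
  n <- nrow(decisions)
  routeCounts <- table(decisions$route)
  branchCounts <- table(decisions$branch)
  avs <- sum(decisions$route == "AVS")
  decided <- decisions$route != "AVS"
  correct <-
    sum(decisions$route == "surgery" & truth == paTracks()[1L]) +
    sum(decisions$route == "medication" & truth == paTracks()[3L])
  decidedTotal <- sum(decided)
  acc <- if (decidedTotal == 0) NA_real_ else
    round(100 * correct / decidedTotal, 1)
  structure(list(
    n_total = n,
    routeCounts = routeCounts,
    branchCounts = branchCounts,
    avs_fraction = round(100 * avs / n, 1),
    decided_total = decidedTotal,
    decided_correct = correct,
    decision_accuracy = acc,
    flagged = decidedTotal == 0
  ), class = "flowchartSummary")
}

#' @export
print.flowchartSummary <- function(x, ...) {
  cat("Flowchart summary over", x$n_total, "patients\n")
  cat("  routes: ", paste(sprintf("%s %d", names(x$routeCounts),
                                  x$routeCounts), collapse = ", "), "\n")
  cat("  branches:\n")
  for (b in names(x$branchCounts))
    if (x$branchCounts[b] > 0)
      cat(sprintf("    %-24s %d\n", b, x$branchCounts[b]))
  cat(sprintf("  AVS fraction: %.1f%%\n", x$avs_fraction))
  if (x$flagged) cat("  decision accuracy: undefined (no decided cases)\n")
  else cat(sprintf("  decision accuracy: %.1f%% (%d/%d decided correct)\n",
                   x$decision_accuracy, x$decided_correct,
                   x$decided_total))
  invisible(x)
}
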