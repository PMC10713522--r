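#' @include schema.R
NULL

#' Derive CT tumor features from per-side sizes
#'
#' Turns the two measured adrenal tumor diameters into the CT feature set the
#' classifiers consume: per-side sizes, 4-level laterality, and the larger
#' tumor's size and side. A patient with both sizes zero is image-negative
#' (image-negative tumors are carried as size 0). With bilateral tumors of
#' exactly equal size no larger side exists (\code{larger_side = "none"}).
#'
#' @param right_size,left_size tumor diameters in mm (vectors allowed);
#'   must be finite and non-negative.
#' @return data.frame with columns \code{right_size}, \code{left_size},
#'   \code{laterality} (right/left/bilateral/image-negative),
#'   \code{larger_size}, \code{larger_side} (right/left/none).
#' @export
#' @examples
#' deriveCTFeatures(5, 8)   # bilateral, larger 8 mm on the left
#' deriveCTFeatures(0, 0)   # image-negative
deriveCTFeatures <- function(right_size, left_size) {
  n <- max(length(right_size), length(left_size))
  right_size <- rep_len(as.numeric(right_size), n)
  left_size <- rep_len(as.numeric(left_size), n)
  if (any(!is.finite(right_size)) || any(!is.finite(left_size)))
    stop("tumor sizes must be finite")
  if (any(right_size < 0) || any(left_size < 0))
    stop("tumor sizes must be non-negative")
  laterality <- ifelse(
    right_size > 0 & left_size > 0, "bilateral",
    ifelse(right_size > 0, "right",
           ifelse(left_size > 0, "left", "image-negative"))
  )
  larger_size <- pmax(right_size, left_size)
  larger_side <- ifelse(
    right_size > left_size, "right",
    ifelse(left_size > right_size, "left", "none")
  )
  larger_side[larger_size == 0] <- "none"
  data.frame(
    right_size = right_size, left_size = left_size,
    laterality = factor(laterality, levels = ctLateralityLevels()),
    larger_size = larger_size,
    larger_side = factor(larger_side, levels = c("right", "left", "none"))
  )
}

#' Aldosterone-to-renin ratio with PA screening flag
#'
#' ARR = PAC / PRA; the screening flag is raised when the ratio strictly
#' exceeds the cutoff (default 20, the usual screening criterion with PAC in
#' ng/dl and PRA in ng/ml/hr). Undetectable renin is clamped to a floor
#' before division (standard practice; configurable off, in which case a
#' non-positive PRA is a domain error).
#'
#' @param pac plasma aldosterone concentration (ng/dl), >= 0.
#' @param pra plasma renin activity (ng/ml/hr).
#' @param cutoff screening cutoff on the ratio (strict inequality).
#' @param praFloor floor applied to PRA, default 0.1; \code{NULL} disables
#'   clamping.
#' @return data.frame with columns \code{arr} and \code{screen_positive}.
#' @export
#' @examples
#' aldosteroneReninRatio(40, 2)      # ARR 20 is NOT screening-positive
#' aldosteroneReninRatio(37.7, 0.2)  # ARR 188.5, positive
aldosteroneReninRatio <- function(pac, pra, cutoff = 20, praFloor = 0.1) {
  n <- max(length(pac), length(pra))
  pac <- rep_len(as.numeric(pac), n)
  pra <- rep_len(as.numeric(pra), n)
  if (any(!is.finite(pac)) || any(pac < 0))
    stop("PAC must be finite and non-negative")
  if (any(!is.finite(pra)) || any(pra < 0))
    stop("PRA must be finite and non-negative")
  if (is.null(praFloor)) {
    if (any(pra <= 0)) stop("PRA must be positive (no renin floor in use)")
  } else {
    pra <- pmax(pra, praFloor)
  }
  arr <- pac / pra
  data.frame(arr = arr, screen_positive = arr > cutoff)
}

#' Retrospective three-way subtype labeling
#'
#' Maps the definitive diagnosis, the true APA side and the CT findings to
#' the three triage categories. IHA cases are medication-track. APA cases are
#' surgery-track only when CT shows a tumor and the APA sits on the larger
#' (for unilateral findings: the visible) tumor side -- tumor size being the
#' only clue CT offers for choosing the adrenalectomy side. All other APA
#' cases, including CT-image-negative ones, APAs behind the smaller of
#' bilateral tumors, APAs contralateral to the only visible tumor, and
#' bilateral tumors of exactly equal size, are AVS-recommended.
#'
#' @param diagnosis "APA-surgical" or "IHA-medical" (vector allowed).
#' @param apa_side "right", "left", or "none"; must be "none" exactly for
#'   IHA cases.
#' @param ct CT features as returned by [deriveCTFeatures()].
#' @return factor of subtype labels (see [paTracks()]).
#' @export
#' @examples
#' ct <- deriveCTFeatures(c(5, 0), c(8, 0))
#' assignSubtypeLabel(c("APA-surgical", "APA-surgical"),
#'                    c("right", "left"), ct)
assignSubtypeLabel <- function(diagnosis, apa_side, ct) {
  n <- nrow(ct)
  diagnosis <- rep_len(as.character(diagnosis), n)
  apa_side <- rep_len(as.character(apa_side), n)
  if (!all(diagnosis %in% c("APA-surgical", "IHA-medical")))
    stop("diagnosis must be 'APA-surgical' or 'IHA-medical'")
  if (!all(apa_side %in% c("right", "left", "none")))
    stop("apa_side must be 'right', 'left' or 'none'")
  if (any((diagnosis == "IHA-medical") != (apa_side == "none")))
    stop("apa_side must be 'none' exactly for IHA-medical cases")
  lat <- as.character(ct$laterality)
  larger <- as.character(ct$larger_side)
  label <- rep(paTracks()[2L], n)                      # AVS-recommended
  label[diagnosis == "IHA-medical"] <- paTracks()[3L]  # medication-track
  apa <- diagnosis == "APA-surgical"
  onLarger <- apa & lat != "image-negative" & larger == apa_side
  label[onLarger] <- paTracks()[1L]                    # surgery-track
  factor(label, levels = paTracks())
}
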