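#' @include AllClasses.R
NULL

#' @rdname PACohort-accessors
#' @export
setGeneric("cohortValues", function(x) standardGeneric("cohortValues"))

#' @rdname PACohort-accessors
#' @export
setGeneric("observedMask", function(x) standardGeneric("observedMask"))

#' @rdname PACohort-accessors
#' @export
setGeneric("centerIds", function(x) standardGeneric("centerIds"))

#' @rdname PACohort-accessors
#' @export
setGeneric("subtypeLabels", function(x) standardGeneric("subtypeLabels"))

#' @rdname PACohort-accessors
#' @export
setGeneric("markerSchemaOf", function(x) standardGeneric("markerSchemaOf"))

#' @rdname PACohort-accessors
#' @export
setGeneric("missingFraction", function(x, byCenter = FALSE)
  standardGeneric("missingFraction"))

#' @rdname BPCAModel-accessors
#' @export
setGeneric("loadings", function(x, ...) standardGeneric("loadings"))

#' @rdname BPCAModel-accessors
#' @export
setGeneric("qEff", function(x) standardGeneric("qEff"))

#' @rdname BPCAModel-accessors
#' @export
setGeneric("noisePrecision", function(x) standardGeneric("noisePrecision"))

#' @rdname BPCAModel-accessors
#' @export
setGeneric("ardPrecisions", function(x) standardGeneric("ardPrecisions"))

#' @rdname BPCAModel-accessors
#' @export
setGeneric("elboTrace", function(x) standardGeneric("elboTrace"))

#' Accessors for PACohort
#'
#' \code{cohortValues} returns the encoded marker x patient numeric matrix
#' (NA at unobserved cells); \code{observedMask} the logical mask;
#' \code{centerIds} the per-patient center; \code{subtypeLabels} the
#' per-patient track label (factor, NA when unlabeled);
#' \code{markerSchemaOf} the governing schema; \code{missingFraction} the
#' fraction of masked cells per marker, overall or per center.
#'
#' @param x a \linkS4class{PACohort}
#' @param byCenter compute per-center fractions?
#' @return matrix, vector, factor, schema or data.frame as described.
#' @name PACohort-accessors
NULL

#' Accessors for BPCAModel
#'
#' \code{loadings} returns the posterior-mean loading matrix (by default only
#' the ARD-retained columns); \code{qEff} the retained latent dimension count;
#' \code{noisePrecision} the posterior mean of tau; \code{ardPrecisions} the
#' posterior means of the ARD precisions alpha; \code{elboTrace} the evidence
#' lower bound per iteration.
#'
#' @param x a \linkS4class{BPCAModel}
#' @param ... for \code{loadings}: \code{all = TRUE} returns pruned columns
#'   too.
#' @return matrix or numeric vector as described.
#' @name BPCAModel-accessors
NULL
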