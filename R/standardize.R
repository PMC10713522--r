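#' @include schema.R
NULL

#' Standardization statistics from a reference cohort
#'
#' Computes per-column mean and standard deviation over the observed entries
#' of a reference cohort. Continuous markers are flagged for z-scoring;
#' binary and categorical indicator columns stay on their natural [0, 1]
#' scale (they already feed the linear-Gaussian imputer sensibly there).
#' Level frequencies of categorical markers are recorded for reporting.
#'
#' @param cohort a \linkS4class{PACohort}, typically the reference center.
#' @return A \linkS4class{ReferenceStats}.
#' @export
referenceStats <- function(cohort) {
  vals <- cohortValues(cohort)
  rd <- as.data.frame(rowData(cohort))
  mn <- apply(vals, 1L, function(x) mean(x[is.finite(x)]))
  sdv <- apply(vals, 1L, function(x) stats::sd(x[is.finite(x)]))
  scaled <- rd$kind == "continuous"
  bad <- scaled & (!is.finite(sdv) | sdv <= 0)
  if (any(bad))
    stop("zero or undefined standard deviation for marker(s): ",
         paste(rd$column[bad], collapse = ", "))
  schema <- markerSchemaOf(cohort)
  lf <- list()
  for (nm in schema@markers$name[schema@markers$kind == "categorical"]) {
    lev <- schema@levels[[nm]]
    encNames <- paste0(nm, ".", gsub("-", "_", lev))
    counts <- rowSums(vals[encNames, , drop = FALSE] == 1, na.rm = TRUE)
    lf[[nm]] <- stats::setNames(counts / max(sum(counts), 1L), lev)
  }
  new("ReferenceStats",
      stats = data.frame(column = rd$column, mean = unname(mn),
                         sd = unname(sdv), scaled = scaled),
      levelFreq = lf)
}

#' Standardize a cohort against reference statistics
#'
#' z-scores the observed entries of every continuous marker with the
#' reference mean and SD, so that reference and target cohorts share one
#' coordinate system for the BPCA imputer. The mask is untouched;
#' [unstandardizeCohort()] inverts the transform exactly.
#'
#' @param cohort a \linkS4class{PACohort}.
#' @param stats a \linkS4class{ReferenceStats} covering the cohort's columns.
#' @return A standardized \linkS4class{PACohort} (flagged in its metadata).
#' @export
standardizeCohort <- function(cohort, stats) {
  vals <- cohortValues(cohort)
  s <- stats@stats
  if (!all(rownames(vals) %in% s$column))
    stop("reference stats do not cover column(s): ",
         paste(setdiff(rownames(vals), s$column), collapse = ", "))
  s <- s[match(rownames(vals), s$column), ]
  if (any(s$scaled & (!is.finite(s$sd) | s$sd <= 0)))
    stop("zero standard deviation for marker(s): ",
         paste(s$column[s$scaled & (!is.finite(s$sd) | s$sd <= 0)],
               collapse = ", "))
  idx <- which(s$scaled)
  vals[idx, ] <- (vals[idx, , drop = FALSE] - s$mean[idx]) / s$sd[idx]
  out <- cohort
  SummarizedExperiment::assay(out, "values") <- vals
  metadata(out)$standardized <- TRUE
  metadata(out)$referenceStats <- stats
  out
}

#' @rdname standardizeCohort
#' @export
unstandardizeCohort <- function(cohort, stats = metadata(cohort)$referenceStats) {
  vals <- unstandardizeValues(cohortValues(cohort), stats)
  out <- cohort
  SummarizedExperiment::assay(out, "values") <- vals
  metadata(out)$standardized <- FALSE
  out
}

#' @rdname standardizeCohort
#' @param values an encoded markers x patients matrix on the standardized
#'   scale (e.g. a BPCA-completed matrix) to map back to natural units.
#' @export
unstandardizeValues <- function(values, stats) {
  s <- stats@stats[match(rownames(values), stats@stats$column), ]
  idx <- which(s$scaled)
  values[idx, ] <- values[idx, , drop = FALSE] * s$sd[idx] + s$mean[idx]
  values
}

setMethod("show", "ReferenceStats", function(object) {
  cat("ReferenceStats:", nrow(object@stats), "columns,",
      sum(object@stats$scaled), "standardized\n")
})
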