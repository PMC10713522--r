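#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a marker schema
#'
#' @param markers data.frame with columns \code{name}, \code{kind}
#'   (continuous/binary/categorical) and \code{units}.
#' @param levels named list of allowed levels for each categorical marker.
#' @param labelColumn,centerColumn column names used in cohort files for the
#'   subtype label and the center identifier.
#' @param missingToken literal token written/read for a missing cell.
#' @return A \linkS4class{MarkerSchema}.
#' @export
#' @examples
#' sch <- markerSchema(
#'   data.frame(name = c("pac", "sex_male"),
#'              kind = c("continuous", "binary"),
#'              units = c("ng/dl", "")),
#'   levels = list()
#' )
#' markerNames(sch)
markerSchema <- function(markers, levels = list(),
                         labelColumn = "subtype",
                         centerColumn = "center",
                         missingToken = "NA") {
  markers$name <- as.character(markers$name)
  markers$kind <- as.character(markers$kind)
  markers$units <- as.character(markers$units)
  new("MarkerSchema", markers = markers, levels = levels,
      labelColumn = labelColumn, centerColumn = centerColumn,
      missingToken = missingToken)
}

#' Default primary-aldosteronism marker schema
#'
#' The package's reconstruction of the 36 predictor markers used for subtype
#' triage: demographics and common biochemistry, renin-angiotensin and
#' ACTH-axis test readouts (captopril challenge, ACTH infusion, dexamethasone
#' suppression, furosemide-upright and saline-loading tests), and
#' CT-derived tumor features (per-side sizes, 4-level laterality expanded to
#' indicator columns, larger-tumor size and side). Encoded width is exactly
#' 36 columns. The exact marker set of any particular study is
#' site-dependent; pass your own [markerSchema()] to override.
#'
#' @param missingToken missing-cell token, default \code{"NA"}.
#' @return A \linkS4class{MarkerSchema} with 33 raw markers encoding to 36
#'   columns.
#' @export
#' @examples
#' sch <- paSchema()
#' nrow(encodedColumns(sch))  # 36
paSchema <- function(missingToken = "NA") {
  cont <- c(
    age = "yr", duration_ht = "yr", bmi = "kg/m2",
    ddd = "defined daily dose", sbp = "mmHg", dbp = "mmHg",
    pac = "ng/dl", pra = "ng/ml/hr", arr = "(ng/dl)/(ng/ml/hr)",
    cortisol = "ug/dl", acth = "pg/ml",
    cortisol_dst = "ug/dl", pac_dst = "ng/dl",
    serum_k = "mmol/L", lowest_k = "mmol/L", sodium = "mmol/L",
    creatinine = "mg/dl", egfr = "mL/min/1.73m2",
    pac_cct = "ng/dl", pra_cct = "ng/ml/hr",
    arr_cct = "(ng/dl)/(ng/ml/hr)",
    pac_ast = "ng/dl", cortisol_ast = "ug/dl",
    pra_furosemide = "ng/ml/hr", pac_saline = "ng/dl",
    right_tumor_mm = "mm", left_tumor_mm = "mm", larger_tumor_mm = "mm"
  )
  bin <- c("sex_male", "k_replacement", "larger_side_right",
           "larger_side_left")
  markers <- rbind(
    data.frame(name = names(cont), kind = "continuous", units = unname(cont)),
    data.frame(name = bin, kind = "binary", units = ""),
    data.frame(name = "ct_laterality", kind = "categorical", units = "")
  )
  markerSchema(
    markers,
    levels = list(ct_laterality = ctLateralityLevels()),
    missingToken = missingToken
  )
}

ctLateralityLevels <- function() {
  c("right", "left", "bilateral", "image-negative")
}

#' @describeIn markerSchema raw marker names, in schema order.
#' @param schema a \linkS4class{MarkerSchema}
#' @export
markerNames <- function(schema) schema@markers$name

#' Encoded column layout of a schema
#'
#' Categorical markers expand to one indicator column per level (no baseline
#' dropped: a CT-image-negative indicator is itself a clinically meaningful
#' predictor). Continuous and binary markers map to one column each.
#'
#' @param schema a \linkS4class{MarkerSchema}
#' @return data.frame with one row per encoded column: \code{column} (encoded
#'   name), \code{source} (raw marker), \code{kind}, \code{level} (for
#'   indicator columns, else NA), \code{units}.
#' @export
encodedColumns <- function(schema) {
  m <- schema@markers
  out <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    if (m$kind[i] == "categorical") {
      lev <- schema@levels[[m$name[i]]]
      out[[i]] <- data.frame(
        column = paste0(m$name[i], ".", gsub("-", "_", lev)),
        source = m$name[i], kind = "indicator", level = lev, units = ""
      )
    } else {
      out[[i]] <- data.frame(
        column = m$name[i], source = m$name[i], kind = m$kind[i],
        level = NA_character_, units = m$units[i]
      )
    }
  }
  do.call(rbind, out)
}

#' Construct a PACohort from encoded values
#'
#' @param values numeric matrix, encoded markers x patients (or a transposed
#'   patients x markers matrix with \code{byPatient = TRUE}). \code{NA} marks
#'   unobserved cells.
#' @param center per-patient center identifier.
#' @param label optional per-patient subtype label (see [paTracks()]).
#' @param schema the governing \linkS4class{MarkerSchema}.
#' @param byPatient is \code{values} patients x markers?
#' @return A \linkS4class{PACohort}.
#' @export
PACohort <- function(values, center, label = NULL, schema = paSchema(),
                     byPatient = FALSE) {
  if (byPatient) values <- t(values)
  enc <- encodedColumns(schema)
  if (is.null(rownames(values))) rownames(values) <- enc$column
  stopifnot(identical(rownames(values), enc$column))
  n <- ncol(values)
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("P%03d", seq_len(n))
  if (is.null(label)) label <- rep(NA_character_, n)
  values[!is.finite(values)] <- NA_real_
  cd <- DataFrame(
    center = as.character(center),
    label = factor(as.character(label), levels = paTracks()),
    row.names = colnames(values)
  )
  rd <- DataFrame(enc, row.names = enc$column)
  se <- SummarizedExperiment(
    assays = list(values = values, observed = is.finite(values)),
    colData = cd, rowData = rd
  )
  metadata(se)$schema <- schema
  new("PACohort", se)
}

#' @rdname PACohort-accessors
#' @export
setMethod("cohortValues", "PACohort", function(x) assay(x, "values"))

#' @rdname PACohort-accessors
#' @export
setMethod("observedMask", "PACohort", function(x) assay(x, "observed"))

#' @rdname PACohort-accessors
#' @export
setMethod("centerIds", "PACohort", function(x) colData(x)$center)

#' @rdname PACohort-accessors
#' @export
setMethod("subtypeLabels", "PACohort", function(x) colData(x)$label)

#' @rdname PACohort-accessors
#' @export
setMethod("markerSchemaOf", "PACohort", function(x) metadata(x)$schema)

#' @rdname PACohort-accessors
#' @export
setMethod("missingFraction", "PACohort", function(x, byCenter = FALSE) {
  obs <- observedMask(x)
  if (!byCenter) {
    data.frame(column = rownames(obs), missing = rowMeans(!obs),
               row.names = NULL)
  } else {
    ctr <- centerIds(x)
    out <- lapply(unique(ctr), function(cc) {
      data.frame(center = cc, column = rownames(obs),
                 missing = rowMeans(!obs[, ctr == cc, drop = FALSE]),
                 row.names = NULL)
    })
    do.call(rbind, out)
  }
})

setMethod("show", "MarkerSchema", function(object) {
  m <- object@markers
  cat("MarkerSchema:", nrow(m), "markers (",
      sum(m$kind == "continuous"), "continuous,",
      sum(m$kind == "binary"), "binary,",
      sum(m$kind == "categorical"), "categorical ) ->",
      nrow(encodedColumns(object)), "encoded columns\n")
  cat("  missing token:", dQuote(object@missingToken),
      " label column:", object@labelColumn,
      " center column:", object@centerColumn, "\n")
})

setMethod("show", "PACohort", function(object) {
  cat("PACohort:", ncol(object), "patients x", nrow(object),
      "encoded markers\n")
  ctr <- table(centerIds(object))
  cat("  centers:", paste(sprintf("%s (%d)", names(ctr), ctr),
                          collapse = ", "), "\n")
  lab <- subtypeLabels(object)
  if (any(!is.na(lab))) {
    tl <- table(lab)
    cat("  labels: ", paste(sprintf("%s %d", names(tl), tl),
                            collapse = ", "), "\n")
  } else cat("  labels: none\n")
  cat(sprintf("  missing cells: %.1f%%\n",
              100 * mean(!observedMask(object))))
})
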