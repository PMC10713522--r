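#' @include schema.R
NULL

#' Read a cohort table
#'
#' Reads a delimited cohort file (one row per patient, header = raw marker
#' names plus the center and, optionally, the subtype label column) and
#' encodes it: binary markers to \{0, 1\}, categorical markers to indicator
#' columns. Cells equal to the schema's missing token become unobserved
#' entries in the mask.
#'
#' @param path file path of a CSV cohort table.
#' @param schema a \linkS4class{MarkerSchema}; default [paSchema()].
#' @return A \linkS4class{PACohort}.
#' @export
#' @seealso [writeCohort()]
loadCohort <- function(path, schema = paSchema()) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE,
                         na.strings = schema@missingToken)
  m <- schema@markers
  expected <- c(schema@centerColumn, schema@labelColumn, m$name)
  unknown <- setdiff(names(raw), expected)
  if (length(unknown))
    stop("schema error: unknown column(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  required <- c(schema@centerColumn, m$name)
  absent <- setdiff(required, names(raw))
  if (length(absent))
    stop("schema error: missing column(s) in ", path, ": ",
         paste(absent, collapse = ", "))

  n <- nrow(raw)
  enc <- encodedColumns(schema)
  values <- matrix(NA_real_, nrow = n, ncol = nrow(enc),
                   dimnames = list(NULL, enc$column))
  for (i in seq_len(nrow(m))) {
    nm <- m$name[i]
    col <- raw[[nm]]
    if (m$kind[i] == "categorical") {
      lev <- schema@levels[[nm]]
      bad <- which(!is.na(col) & !col %in% lev)
      if (length(bad))
        stop("parse error: column '", nm, "', row ", bad[1],
             ": level '", col[bad[1]], "' not in schema levels")
      for (l in lev) {
        encName <- paste0(nm, ".", gsub("-", "_", l))
        values[, encName] <- ifelse(is.na(col), NA_real_,
                                    as.numeric(col == l))
      }
    } else {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad))
        stop("parse error: non-numeric value '", col[bad[1]],
             "' in column '", nm, "', row ", bad[1])
      if (m$kind[i] == "binary" && any(!is.na(num) & !num %in% c(0, 1)))
        stop("parse error: binary column '", nm, "' has values outside {0,1}")
      values[, nm] <- num
    }
  }
  label <- if (schema@labelColumn %in% names(raw))
    raw[[schema@labelColumn]] else NULL
  PACohort(values, center = raw[[schema@centerColumn]], label = label,
           schema = schema, byPatient = TRUE)
}

#' Write a cohort table
#'
#' Serializes a \linkS4class{PACohort} back to CSV in schema column order,
#' decoding indicator columns to the categorical level and writing masked
#' entries as the missing token. Numeric cells are written with enough digits
#' to round-trip doubles exactly.
#'
#' @param cohort a \linkS4class{PACohort}.
#' @param path output file path.
#' @param schema schema to serialize under; defaults to the cohort's own.
#' @return \code{path}, invisibly.
#' @export
writeCohort <- function(cohort, path, schema = markerSchemaOf(cohort)) {
  vals <- cohortValues(cohort)   # markers x patients
  m <- schema@markers
  n <- ncol(vals)
  tok <- schema@missingToken
  fmtNum <- function(x) {
    out <- rep(tok, length(x))
    ok <- is.finite(x)
    out[ok] <- sprintf("%.17g", x[ok])
    out
  }
  cols <- list()
  cols[[schema@centerColumn]] <- centerIds(cohort)
  lab <- subtypeLabels(cohort)
  if (any(!is.na(lab)))
    cols[[schema@labelColumn]] <- ifelse(is.na(lab), tok, as.character(lab))
  for (i in seq_len(nrow(m))) {
    nm <- m$name[i]
    if (m$kind[i] == "categorical") {
      lev <- schema@levels[[nm]]
      encNames <- paste0(nm, ".", gsub("-", "_", lev))
      block <- t(vals[encNames, , drop = FALSE])  # patients x levels
      out <- rep(tok, n)
      ok <- apply(is.finite(block), 1L, all)
      if (any(ok))
        out[ok] <- lev[max.col(block[ok, , drop = FALSE], "first")]
      cols[[nm]] <- out
    } else {
      cols[[nm]] <- fmtNum(vals[nm, ])
    }
  }
  df <- as.data.frame(cols, check.names = FALSE, optional = TRUE)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("I/O error: cannot open '", path, "' for writing: ",
         conditionMessage(e)))
  on.exit(close(con))
  utils::write.table(df, con, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
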