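#' @include schema.R features.R
NULL

# run code under a temporary RNG state derived from `seed`, restoring the
# caller's stream afterwards
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

lnormFromQuartiles <- function(median, q1, q3) {
  c(meanlog = log(median),
    sdlog = (log(q3) - log(q1)) / (2 * stats::qnorm(0.75)))
}

rtruncnorm <- function(n, mean, sd, lower) {
  p0 <- stats::pnorm((lower - mean) / sd)
  mean + sd * stats::qnorm(p0 + stats::runif(n) * (1 - p0))
}

#' Class-conditional marker distributions of the default generator
#'
#' One row per (marker, track): symmetric markers are normal with the
#' class mean and SD; skewed markers (hormone levels, ratios, durations,
#' doses) are log-normal with parameters solved from the class median and
#' interquartile range. Binary markers carry a class prevalence. Values for
#' the three tracks follow the published per-class cohort summaries where
#' those exist; the remaining routine-workup markers use representative
#' clinic values graded across classes. \code{floor} truncates implausible
#' draws (e.g. negative creatinine).
#'
#' @return data.frame with columns \code{marker}, \code{class}, \code{type}
#'   (normal / lognormal / binary), \code{p1}, \code{p2}, \code{p3}
#'   (mean,sd / median,q1,q3 / prevalence), \code{floor}.
#' @export
markerDistributions <- function() {
  tr <- paTracks()
  N <- function(marker, m, s, floor = -Inf)
    data.frame(marker = marker, class = tr, type = "normal",
               p1 = m, p2 = s, p3 = NA_real_, floor = floor)
  L <- function(marker, med, q1, q3)
    data.frame(marker = marker, class = tr, type = "lognormal",
               p1 = med, p2 = q1, p3 = q3, floor = 0)
  B <- function(marker, p)
    data.frame(marker = marker, class = tr, type = "binary",
               p1 = p, p2 = NA_real_, p3 = NA_real_, floor = NA_real_)
  rbind(
    N("age", c(50.5, 57.7, 49.9), c(11.1, 10.1, 11.2), floor = 18),
    L("duration_ht", c(10, 6.5, 8), c(4, 3, 3), c(17.3, 16.5, 15)),
    N("bmi", c(24.3, 23.7, 24.4), c(3.6, 3.7, 3.5), floor = 14),
    L("ddd", c(2, 2, 2), c(1, 1.2, 1), c(3.3, 3.1, 3)),
    N("sbp", c(142.6, 147.9, 142.2), c(17.1, 14.8, 19.5), floor = 80),
    N("dbp", c(88.7, 89, 87), c(12.8, 13.4, 13), floor = 40),
    L("pac", c(40.4, 27, 17.8), c(23.7, 18.6, 13.9), c(58.8, 55.6, 24.2)),
    L("pra", c(0.2, 0.3, 0.3), c(0.1, 0.2, 0.2), c(0.3, 0.4, 0.5)),
    L("cortisol", c(8.2, 9.3, 9), c(6.5, 7.5, 7), c(10.7, 12.4, 11.5)),
    L("acth", c(15, 15, 15), c(10, 10, 10), c(25, 25, 25)),
    L("cortisol_dst", c(1.1, 1, 1.1), c(0.7, 0.5, 0.7), c(1.6, 1.4, 1.5)),
    L("pac_dst", c(30, 22, 14), c(18, 14, 10), c(45, 35, 20)),
    N("serum_k", c(3.2, 3.3, 3.7), c(0.5, 0.5, 0.4), floor = 2),
    N("lowest_k", c(3.2, 3.3, 3.7), c(0.6, 0.4, 0.4), floor = 2),
    N("sodium", c(141, 141, 141), c(2.5, 2.5, 2.5), floor = 120),
    N("creatinine", c(0.8, 0.8, 0.8), c(0.3, 0.2, 0.2), floor = 0.2),
    N("egfr", c(79.4, 75.2, 78), c(24.4, 14, 18), floor = 5),
    L("pac_cct", c(35, 25, 15), c(22, 17, 11), c(55, 45, 21)),
    L("pra_cct", c(0.3, 0.4, 0.5), c(0.15, 0.2, 0.3), c(0.5, 0.7, 0.9)),
    L("arr_cct", c(105.8, 55.9, 30), c(62.6, 38.0, 18), c(214, 151.6, 50)),
    L("pac_ast", c(67.2, 46.1, 40), c(37.9, 29.6, 28), c(91.1, 64.6, 58)),
    L("cortisol_ast", c(22.2, 26, 25), c(19.9, 21.6, 21), c(25.4, 28.5, 28)),
    L("pra_furosemide", c(0.4, 0.5, 0.6), c(0.2, 0.3, 0.3), c(0.7, 0.9, 1.1)),
    L("pac_saline", c(25, 18, 10), c(15, 11, 7), c(40, 30, 15)),
    B("sex_male", c(42 / 84, 15 / 18, 40 / 108)),
    B("k_replacement", c(56 / 84, 11 / 18, 0.30))
  )
}

defaultCTPatterns <- function() {
  # right / left / bilateral / image-negative counts per track, taken from
  # the published laterality rows and rescaled to class size at draw time
  list(
    "surgery-track" = c(34, 37, 13, 0),
    "AVS-recommended" = c(1, 4, 6, 7),
    "medication-track" = c(7, 16, 9, 76)
  )
}

#' Default per-center per-marker missing rates
#'
#' Emulates center-specific measurement gaps: every lab marker has a small
#' base missing rate, and each center systematically under-collects one
#' dynamic-test panel. Demographics and CT features are always observed (CT
#' is the entry point of the triage). All rates stay below 0.2.
#'
#' @param centers center names.
#' @param base base MCAR rate for lab markers.
#' @return named list (one element per center) of named rate vectors.
#' @export
defaultMissingRates <- function(centers, base = 0.03) {
  lab <- c("duration_ht", "ddd", "cortisol", "acth", "cortisol_dst",
           "pac_dst", "lowest_k", "sodium", "pac_cct", "pra_cct",
           "arr_cct", "pac_ast", "cortisol_ast", "pra_furosemide",
           "pac_saline")
  panels <- list(
    c(cortisol_dst = 0.15, pac_dst = 0.15),
    c(pac_ast = 0.12, cortisol_ast = 0.12),
    c(pra_furosemide = 0.1, pac_saline = 0.1)
  )
  out <- list()
  for (i in seq_along(centers)) {
    r <- stats::setNames(rep(base, length(lab)), lab)
    extra <- panels[[((i - 1L) %% length(panels)) + 1L]]
    r[names(extra)] <- pmax(r[names(extra)], extra)
    out[[centers[i]]] <- r
  }
  out
}

#' Configuration of the synthetic multicenter cohort generator
#'
#' @param nPatients number of patients to draw.
#' @param classProb probability of the three tracks, in [paTracks()] order.
#'   The default reflects the observed 84 / 18 / 108 mix.
#' @param centers,centerProb center names and per-patient assignment
#'   probabilities.
#' @param seed master seed; sub-stages use fixed offsets from it so each
#'   stage is independently reproducible.
#' @param distributions class-conditional marker distribution table, see
#'   [markerDistributions()].
#' @param ctPatterns per-track right/left/bilateral/image-negative CT
#'   frequencies.
#' @param surgeryNodule,avsNodule,medNodule mean and SD (mm) of visible
#'   tumor diameters per track.
#' @param minVisible CT detection limit (mm); visible tumors are truncated
#'   above it, image-negative tumors carry size 0.
#' @param latentRank,latentShare optional shared low-rank correlation
#'   structure across continuous markers: \code{latentRank} factors explain
#'   a \code{latentShare} fraction of each marker's variance (on the draw
#'   scale). Default 0 = class-conditional independence. The correlated
#'   option gives the BPCA imputer a recoverable subspace.
#' @param missingRates per-center per-marker rates for [applyMissingness()];
#'   all must lie in [0, 0.2].
#' @param missingMode "MCAR" (default) or "MAR" (rates modulated by the
#'   patient's observed age relative to the center median, capped at 0.2).
#' @return a classed list, validated.
#' @export
cohortConfig <- function(nPatients = 210,
                         classProb = c(84, 18, 108) / 210,
                         centers = c("Yokohama", "Sapporo", "Sendai"),
                         centerProb = NULL,
                         seed = 1L,
                         distributions = markerDistributions(),
                         ctPatterns = defaultCTPatterns(),
                         surgeryNodule = c(15.7, 6.2),
                         avsNodule = c(8, 2.5),
                         medNodule = c(9, 3),
                         minVisible = 6,
                         latentRank = 0L,
                         latentShare = 0,
                         missingRates = defaultMissingRates(centers),
                         missingMode = c("MCAR", "MAR")) {
  if (length(classProb) != 3L || any(classProb < 0) ||
      abs(sum(classProb) - 1) > 1e-8)
    stop("config error: classProb must be a 3-vector summing to 1")
  if (is.null(centerProb)) centerProb <- rep(1 / length(centers),
                                             length(centers))
  if (abs(sum(centerProb) - 1) > 1e-8)
    stop("config error: centerProb must sum to 1")
  bad <- distributions$type == "normal" & distributions$p2 <= 0
  if (any(bad)) stop("config error: non-positive SD for marker(s): ",
                     paste(unique(distributions$marker[bad]), collapse = ", "))
  allRates <- unlist(missingRates)
  if (length(allRates) && (any(allRates < 0) || any(allRates > 0.2)))
    stop("config error: missing rates must lie in [0, 0.2]")
  if (latentShare < 0 || latentShare >= 1)
    stop("config error: latentShare must lie in [0, 1)")
  structure(list(
    nPatients = as.integer(nPatients), classProb = classProb,
    centers = centers, centerProb = centerProb, seed = as.integer(seed),
    distributions = distributions, ctPatterns = ctPatterns,
    surgeryNodule = surgeryNodule, avsNodule = avsNodule,
    medNodule = medNodule, minVisible = minVisible,
    latentRank = as.integer(latentRank), latentShare = latentShare,
    missingRates = missingRates, missingMode = match.arg(missingMode)
  ), class = "cohortConfig")
}

drawCTStructure <- function(label, config) {
  n <- length(label)
  right <- left <- numeric(n)
  apa <- rep("none", n)
  pat <- config$ctPatterns
  mv <- config$minVisible
  drawSize <- function(k, ms) rtruncnorm(k, ms[1], ms[2], mv)
  lat <- character(n)
  for (cls in paTracks()) {
    idx <- which(label == cls)
    if (!length(idx)) next
    p <- pat[[cls]]
    lat[idx] <- sample(ctLateralityLevels(), length(idx), replace = TRUE,
                       prob = p / sum(p))
  }
  # surgery-track: APA on the visible (or larger of bilateral) tumor side
  for (side in c("right", "left")) {
    idx <- which(label == paTracks()[1L] & lat == side)
    if (!length(idx)) next
    sz <- drawSize(length(idx), config$surgeryNodule)
    if (side == "right") right[idx] <- sz else left[idx] <- sz
    apa[idx] <- side
  }
  idx <- which(label == paTracks()[1L] & lat == "bilateral")
  if (length(idx)) {
    apaSide <- sample(c("right", "left"), length(idx), replace = TRUE)
    big <- drawSize(length(idx), config$surgeryNodule)
    small <- mv + stats::runif(length(idx)) * 0.8 * pmax(big - mv, 0.1)
    right[idx] <- ifelse(apaSide == "right", big, small)
    left[idx] <- ifelse(apaSide == "left", big, small)
    apa[idx] <- apaSide
  }
  # AVS-recommended: CT-negative APA, APA behind the smaller of bilateral
  # tumors, or APA contralateral to the only visible tumor
  idx <- which(label == paTracks()[2L] & lat == "image-negative")
  if (length(idx)) apa[idx] <- sample(c("right", "left"), length(idx),
                                      replace = TRUE)
  for (side in c("right", "left")) {
    idx <- which(label == paTracks()[2L] & lat == side)
    if (!length(idx)) next
    sz <- drawSize(length(idx), config$avsNodule)
    if (side == "right") right[idx] <- sz else left[idx] <- sz
    apa[idx] <- setdiff(c("right", "left"), side)
  }
  idx <- which(label == paTracks()[2L] & lat == "bilateral")
  if (length(idx)) {
    apaSide <- sample(c("right", "left"), length(idx), replace = TRUE)
    big <- drawSize(length(idx), config$avsNodule)
    small <- mv + stats::runif(length(idx)) * 0.8 * pmax(big - mv, 0.1)
    # APA on the SMALLER side: CT would mislead, AVS is required
    right[idx] <- ifelse(apaSide == "right", small, big)
    left[idx] <- ifelse(apaSide == "left", small, big)
    apa[idx] <- apaSide
  }
  # medication-track: incidental non-functioning nodules, no APA
  med <- label == paTracks()[3L]
  for (side in c("right", "left")) {
    idx <- which(med & lat %in% c(side, "bilateral"))
    if (!length(idx)) next
    sz <- drawSize(length(idx), config$medNodule)
    if (side == "right") right[idx] <- sz else left[idx] <- sz
  }
  data.frame(right_size = right, left_size = left, apa_side = apa)
}

#' Generate a synthetic multicenter PA cohort
#'
#' Draws labels from the class mix, continuous and binary markers from the
#' class-conditional distributions, and CT tumor structure consistent with
#' the track definitions: every surgery-track patient has a visible tumor on
#' the APA side, AVS-recommended APAs are CT-negative or hidden behind the
#' wrong (smaller or contralateral) tumor, medication-track patients are IHA
#' with at most incidental nodules. The returned cohort is fully observed;
#' apply [applyMissingness()] for center-specific gaps. Identical config and
#' seed give identical output.
#'
#' @param config a [cohortConfig()].
#' @return list with elements \code{cohort} (\linkS4class{PACohort}) and
#'   \code{truth} (data.frame: per-patient true label, APA side, true tumor
#'   sizes).
#' @export
#' @examples
#' sim <- generateCohort(cohortConfig(nPatients = 50, seed = 7))
#' table(subtypeLabels(sim$cohort))
generateCohort <- function(config) {
  stopifnot(inherits(config, "cohortConfig"))
  n <- config$nPatients
  schema <- paSchema()
  enc <- encodedColumns(schema)

  label <- withSeed(config$seed + 1L, {
    lab <- sample(paTracks(), n, replace = TRUE, prob = config$classProb)
    ctr <- sample(config$centers, n, replace = TRUE,
                  prob = config$centerProb)
    list(lab, ctr)
  })
  center <- label[[2]]
  label <- factor(label[[1]], levels = paTracks())

  dist <- config$distributions
  contMarkers <- unique(dist$marker[dist$type != "binary"])
  binMarkers <- unique(dist$marker[dist$type == "binary"])
  vals <- matrix(NA_real_, nrow = n, ncol = nrow(enc),
                 dimnames = list(NULL, enc$column))

  withSeed(config$seed + 2L, {
    r <- config$latentRank
    rho <- config$latentShare
    U <- NULL
    f <- NULL
    if (r > 0L && rho > 0) {
      U <- matrix(stats::rnorm(length(contMarkers) * r), ncol = r,
                  dimnames = list(contMarkers, NULL))
      U <- U / sqrt(rowSums(U^2))
      f <- matrix(stats::rnorm(n * r), nrow = r)
    }
    for (mk in contMarkers) {
      zs <- stats::rnorm(n)
      if (!is.null(U))
        zs <- sqrt(rho) * as.numeric(U[mk, , drop = FALSE] %*% f) +
          sqrt(1 - rho) * zs
      x <- numeric(n)
      for (cls in paTracks()) {
        row <- dist[dist$marker == mk & dist$class == cls, ]
        idx <- which(label == cls)
        if (!length(idx)) next
        if (row$type == "normal") {
          x[idx] <- row$p1 + row$p2 * zs[idx]
        } else {
          lp <- lnormFromQuartiles(row$p1, row$p2, row$p3)
          x[idx] <- exp(lp["meanlog"] + lp["sdlog"] * zs[idx])
        }
        fl <- row$floor
        if (is.finite(fl)) x[idx] <- pmax(x[idx], fl)
      }
      vals[, mk] <- x
    }
    for (mk in binMarkers) {
      u <- stats::runif(n)
      x <- numeric(n)
      for (cls in paTracks()) {
        row <- dist[dist$marker == mk & dist$class == cls, ]
        idx <- which(label == cls)
        x[idx] <- as.numeric(u[idx] < row$p1)
      }
      vals[, mk] <- x
    }
  })

  ctStruct <- withSeed(config$seed + 3L, drawCTStructure(label, config))
  ct <- deriveCTFeatures(ctStruct$right_size, ctStruct$left_size)
  vals[, "right_tumor_mm"] <- ct$right_size
  vals[, "left_tumor_mm"] <- ct$left_size
  vals[, "larger_tumor_mm"] <- ct$larger_size
  vals[, "larger_side_right"] <- as.numeric(ct$larger_side == "right")
  vals[, "larger_side_left"] <- as.numeric(ct$larger_side == "left")
  for (lv in ctLateralityLevels())
    vals[, paste0("ct_laterality.", gsub("-", "_", lv))] <-
      as.numeric(ct$laterality == lv)

  # screening ARR is an arithmetic consequence of PAC and PRA
  vals[, "arr"] <- aldosteroneReninRatio(vals[, "pac"], vals[, "pra"])$arr

  cohort <- PACohort(vals, center = center, label = label, schema = schema,
                     byPatient = TRUE)
  truth <- data.frame(
    label = label, apa_side = ctStruct$apa_side,
    right_size = ctStruct$right_size, left_size = ctStruct$left_size
  )
  list(cohort = cohort, truth = truth)
}

#' Mask entries of a fully observed cohort
#'
#' Masks marker cells independently at the configured per-center per-marker
#' rates (MCAR; the MAR option modulates each patient's rate by age relative
#' to the center median, capped at 0.2). All indicator columns of a
#' categorical marker are masked jointly. Center and label are never masked.
#'
#' @param cohort a fully observed \linkS4class{PACohort}.
#' @param config a [cohortConfig()] carrying \code{missingRates} and
#'   \code{missingMode}.
#' @return A \linkS4class{PACohort} with masked entries.
#' @export
applyMissingness <- function(cohort, config) {
  stopifnot(inherits(config, "cohortConfig"))
  vals <- cohortValues(cohort)   # markers x patients
  ctr <- centerIds(cohort)
  schema <- markerSchemaOf(cohort)
  age <- vals["age", ]
  withSeed(config$seed + 4L, {
    for (cc in names(config$missingRates)) {
      inC <- which(ctr == cc)
      if (!length(inC)) next
      rates <- config$missingRates[[cc]]
      if (any(rates < 0 | rates > 0.2))
        stop("config error: missing rates must lie in [0, 0.2]")
      for (mk in names(rates)) {
        rate <- rep(rates[[mk]], length(inC))
        if (config$missingMode == "MAR") {
          older <- age[inC] > stats::median(age[inC])
          rate <- pmin(ifelse(older, 2 * rate, 0.5 * rate), 0.2)
        }
        hit <- inC[stats::runif(length(inC)) < rate]
        if (!length(hit)) next
        kind <- schema@markers$kind[schema@markers$name == mk]
        rows <- if (length(kind) && kind == "categorical")
          paste0(mk, ".", gsub("-", "_",  schema@levels[[mk]])) else mk
        vals[rows, hit] <- NA_real_
      }
    }
  })
  PACohort(vals, center = ctr, label = subtypeLabels(cohort),
           schema = schema)
}

#' Descriptive summary of a cohort
#'
#' Per-class descriptive statistics per marker (mean and SD plus median and
#' IQR over observed entries), class counts, and per-center missing
#' fractions -- the generator-validation mirror of a cohort characteristics
#' table.
#'
#' @param cohort a labeled \linkS4class{PACohort}.
#' @return list with \code{classCounts}, \code{markers} (data.frame) and
#'   \code{missing} (per-center per-column missing fractions).
#' @export
summarizeCohort <- function(cohort) {
  lab <- subtypeLabels(cohort)
  if (all(is.na(lab))) stop("cohort has no subtype labels")
  vals <- cohortValues(cohort)
  out <- list()
  for (cls in levels(droplevels(lab[!is.na(lab)]))) {
    sub <- vals[, which(lab == cls), drop = FALSE]
    for (mk in rownames(vals)) {
      x <- sub[mk, ]
      x <- x[is.finite(x)]
      out[[length(out) + 1L]] <- data.frame(
        class = cls, marker = mk, n = length(x),
        mean = if (length(x)) mean(x) else NA_real_,
        sd = if (length(x) > 1) stats::sd(x) else NA_real_,
        median = if (length(x)) stats::median(x) else NA_real_,
        q1 = if (length(x)) unname(stats::quantile(x, 0.25)) else NA_real_,
        q3 = if (length(x)) unname(stats::quantile(x, 0.75)) else NA_real_
      )
    }
  }
  list(
    classCounts = table(lab),
    markers = do.call(rbind, out),
    missing = missingFraction(cohort, byCenter = TRUE)
  )
}
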