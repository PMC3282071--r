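#' Read a growth reference table
#'
#' TSV with columns measure (height/ofc), sex (male/female/
#' sex-averaged), age_lo, age_hi (years, inclusive buckets), mean_cm and
#' sd_cm. Buckets must be sorted and non-overlapping within each
#' (measure, sex) stratum and every sd must be positive.
#'
#' @param path reference TSV.
#' @return data.frame.
#' @export
readGrowthReference <- function(path) {
  ref <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("measure", "sex", "age_lo", "age_hi", "mean_cm", "sd_cm")
  if (!all(need %in% names(ref)))
    stop("growth reference must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(ref$sd_cm <= 0)) stop("sd must be positive in every row", call. = FALSE)
  for (g in split(ref, paste(ref$measure, ref$sex))) {
    g <- g[order(g$age_lo), , drop = FALSE]
    if (nrow(g) > 1L && any(g$age_hi[-nrow(g)] > g$age_lo[-1]))
      stop("overlapping age buckets in growth reference", call. = FALSE)
  }
  ref
}

#' Path to the bundled synthetic growth reference
#'
#' A synthetic stand-in with the schema of sex-averaged growth-chart
#' data (the real UK1990 reference is licensed and not redistributed).
#'
#' @return file path inside the installed package.
#' @export
syntheticGrowthReferenceFile <- function() {
  system.file("extdata", "growth_reference_synthetic.tsv",
              package = "mendelseek", mustWork = TRUE)
}

#' Convert a raw measurement to an SD (z) score
#'
#' (value - reference mean) / reference sd for the matching (measure,
#' sex, age) bucket; "sex-averaged" reference rows match any sex.
#'
#' @param value measurement in cm (vectorised).
#' @param age age in years (recycled).
#' @param sex "male", "female" or "sex-averaged" (recycled).
#' @param reference data.frame from [readGrowthReference()].
#' @param measure "height" or "ofc".
#' @return numeric SD scores.
#' @export
toSdScore <- function(value, age, sex, reference, measure = "height") {
  n <- length(value)
  age <- rep_len(age, n); sex <- rep_len(sex, n)
  out <- numeric(n)
  for (k in seq_len(n)) {
    rows <- reference[reference$measure == measure &
                      (reference$sex == sex[k] | reference$sex == "sex-averaged") &
                      reference$age_lo <= age[k] & age[k] <= reference$age_hi, ,
                      drop = FALSE]
    if (!nrow(rows))
      stop(sprintf("no %s reference bucket for sex=%s age=%s",
                   measure, sex[k], age[k]), call. = FALSE)
    out[k] <- (value[k] - rows$mean_cm[1]) / rows$sd_cm[1]
  }
  out
}

#' Cohort phenotype summary
#'
#' Computes the counts behind overgrowth cohort descriptions. Threshold
#' comparisons follow the clinical wording exactly: "at least k SD"
#' counts with >=, "greater than k SD" with strict >. Records with an
#' absent ("nk") measurement are excluded from that statistic and the n
#' actually used is reported — missing values are never treated as 0.
#'
#' @param records data.frame from [readPhenotypeTable()].
#' @param thresholdsAtLeast SD thresholds counted with >=, default 2.
#' @param thresholdsGreater SD thresholds counted with >, default 4.
#' @param model optional [TranscriptModel-class]; when given, mutation
#'   classes are tallied by classifying each hgvs_c.
#' @return a `CohortSummary` list: n_total, n_height_used, n_ofc_used,
#'   n_height_at_least / n_height_greater (named by threshold; same for
#'   ofc), min_height_sd, n_by_inheritance, n_by_class, n_malignancy.
#' @export
summarizeCohort <- function(records, thresholdsAtLeast = 2,
                            thresholdsGreater = 4, model = NULL) {
  if (!nrow(records)) stop("empty record list", call. = FALSE)
  h <- records$height_sd[!is.na(records$height_sd)]
  o <- records$ofc_sd[!is.na(records$ofc_sd)]
  countGE <- function(x, ts) setNames(vapply(ts, function(t) sum(x >= t),
                                             integer(1)), ts)
  countGT <- function(x, ts) setNames(vapply(ts, function(t) sum(x > t),
                                             integer(1)), ts)
  byClass <- NULL
  if (!is.null(model)) {
    cls <- classifyTable(records$hgvs_c, model)$consequence_class
    byClass <- table(cls)
  }
  mal <- if (is.null(records$malignancy)) 0L
         else sum(!is.na(records$malignancy) & nzchar(records$malignancy))
  structure(list(
    n_total = nrow(records),
    n_height_used = length(h),
    n_ofc_used = length(o),
    n_height_at_least = countGE(h, thresholdsAtLeast),
    n_height_greater = countGT(h, thresholdsGreater),
    n_ofc_at_least = countGE(o, thresholdsAtLeast),
    n_ofc_greater = countGT(o, thresholdsGreater),
    min_height_sd = if (length(h)) min(h) else NA_real_,
    n_by_inheritance = table(records$inheritance),
    n_by_class = byClass,
    n_malignancy = mal
  ), class = "CohortSummary")
}

#' @export
print.CohortSummary <- function(x, ...) {
  cat(sprintf("Cohort of %d cases (height known for %d, OFC for %d)\n",
              x$n_total, x$n_height_used, x$n_ofc_used))
  for (t in names(x$n_height_at_least))
    cat(sprintf("  height >= +%s SD: %d\n", t, x$n_height_at_least[[t]]))
  for (t in names(x$n_height_greater))
    cat(sprintf("  height >  +%s SD: %d\n", t, x$n_height_greater[[t]]))
  cat(sprintf("  minimum height SD: %+.1f\n", x$min_height_sd))
  cat("  inheritance:", paste(sprintf("%s=%d", names(x$n_by_inheritance),
                                      x$n_by_inheritance), collapse = " "), "\n")
  if (!is.null(x$n_by_class))
    cat("  classes:", paste(sprintf("%s=%d", names(x$n_by_class), x$n_by_class),
                            collapse = " "), "\n")
  cat(sprintf("  malignancy reported: %d\n", x$n_malignancy))
  invisible(x)
}

#' Overgrowth study-eligibility category
#'
#' global: both height and OFC at least +2 SD; macrocephaly_only: OFC at
#' least +2 SD with height below; tall_only: height at least +2 SD with
#' OFC below; otherwise not_eligible. An absent measurement is treated
#' as "below +2" for category assignment and flagged via the
#' "flagged_missing" attribute; both absent is an error.
#'
#' @param heightSd,ofcSd SD scores (NA = not known).
#' @param threshold eligibility threshold, default +2 SD (>= boundary:
#'   exactly +2.0 is eligible).
#' @return one of "global", "macrocephaly_only", "tall_only",
#'   "not_eligible".
#' @export
overgrowthEligibility <- function(heightSd, ofcSd, threshold = 2) {
  if (is.na(heightSd) && is.na(ofcSd))
    stop("at least one of height and OFC SD must be present", call. = FALSE)
  flagged <- is.na(heightSd) || is.na(ofcSd)
  tallH <- !is.na(heightSd) && heightSd >= threshold
  tallO <- !is.na(ofcSd) && ofcSd >= threshold
  out <- if (tallH && tallO) "global"
    else if (tallO) "macrocephaly_only"
    else if (tallH) "tall_only"
    else "not_eligible"
  attr(out, "flagged_missing") <- flagged
  out
}
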