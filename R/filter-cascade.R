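#' Build a filter cascade configuration
#'
#' Defaults reproduce the discovery filters: keep only variants with
#' coverage of at least 15 reads, then exclude intronic and synonymous
#' calls, anything recorded in dbSNP, anything in a known pseudogene,
#' and anything seen in the in-house panel of normals (45 exomes in the
#' original design).
#'
#' @param minDepth minimum site read depth (reads), default 15.
#' @param excludedClasses consequence classes to drop, default
#'   intronic + synonymous.
#' @param knownSnpIds extra exclusion set: rs ids and/or
#'   `chrom:pos:ref:alt` keys, for VCFs lacking RSID tags.
#' @param pseudogeneGenes gene ids treated as pseudogenes.
#' @param panelOfNormals variant keys (`chrom:pos:ref:alt`) seen in the
#'   panel of normals; matching is at site level, not gene level.
#' @return a `FilterConfig` list (classed).
#' @export
filterConfig <- function(minDepth = 15L,
                         excludedClasses = c("intronic", "synonymous"),
                         knownSnpIds = character(),
                         pseudogeneGenes = character(),
                         panelOfNormals = character()) {
  if (minDepth < 0L) stop("minDepth must be >= 0", call. = FALSE)
  bad <- setdiff(excludedClasses, CONSEQUENCE_CLASSES)
  if (length(bad))
    stop("unknown consequence class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(minDepth = as.integer(minDepth),
                 excludedClasses = excludedClasses,
                 knownSnpIds = knownSnpIds,
                 pseudogeneGenes = pseudogeneGenes,
                 panelOfNormals = panelOfNormals),
            class = "FilterConfig")
}

## The five per-variant keep-predicates, in the fixed reporting order.
## Each is pure: order of application cannot change the surviving set.
filterPredicates <- function(variants, config) {
  csq <- variants$consequence
  csq[is.na(csq)] <- "other"  # absent class is never excluded by class
  key <- variantKey(variants)
  hasRs <- !is.na(variants$dbsnp_id) & nzchar(variants$dbsnp_id)
  list(
    depth = variants$depth >= config$minDepth,
    class = !(csq %in% config$excludedClasses),
    dbSNP = !(hasRs |                                    # any dbSNP record excludes
              (!is.na(variants$dbsnp_id) & variants$dbsnp_id %in% config$knownSnpIds) |
              key %in% config$knownSnpIds),
    pseudogene = is.na(variants$gene_id) |
      !(variants$gene_id %in% config$pseudogeneGenes),
    panel = !(key %in% config$panelOfNormals)
  )
}

#' Apply the variant filter cascade
#'
#' Keeps variants passing all five predicates (depth, class, dbSNP,
#' pseudogene, panel of normals) and reports per-filter attrition in
#' that fixed order. The report is sequential bookkeeping (each filter's
#' removals are counted among the variants still standing), but the
#' predicates are independent, so the surviving set does not depend on
#' order.
#'
#' @param variants variant table (see [readVariantVcf()]).
#' @param config a [filterConfig()].
#' @return list with `surviving` (variant table) and `report`
#'   (data.frame filter, n_before, n_removed, n_after).
#' @export
applyFilters <- function(variants, config = filterConfig()) {
  if (!inherits(config, "FilterConfig")) stop("config must come from filterConfig()")
  preds <- filterPredicates(variants, config)
  keep <- rep(TRUE, nrow(variants))
  rows <- vector("list", length(preds))
  for (i in seq_along(preds)) {
    before <- sum(keep)
    keep2 <- keep & preds[[i]]
    rows[[i]] <- data.frame(filter = names(preds)[i], n_before = before,
                            n_removed = before - sum(keep2),
                            n_after = sum(keep2), stringsAsFactors = FALSE)
    keep <- keep2
  }
  report <- do.call(rbind, rows)
  stopifnot(all(report$n_after == report$n_before - report$n_removed))
  list(surviving = variants[keep, , drop = FALSE], report = report)
}

#' Combine per-sample filter reports into an attrition table
#'
#' One row per (sample, filter) plus a TOTAL line per sample; returned
#' as TSV text ready to write.
#'
#' @param reports named list (sample id -> report data.frame from
#'   [applyFilters()]); all must share the same filter order.
#' @return single TSV character string.
#' @export
attritionTable <- function(reports) {
  if (!length(reports)) stop("no reports", call. = FALSE)
  ord <- reports[[1]]$filter
  for (r in reports)
    if (!identical(r$filter, ord))
      stop("inconsistent filter order across reports", call. = FALSE)
  rows <- lapply(names(reports), function(s) {
    r <- reports[[s]]
    tot <- data.frame(filter = "TOTAL", n_before = r$n_before[1],
                      n_removed = sum(r$n_removed),
                      n_after = r$n_after[nrow(r)], stringsAsFactors = FALSE)
    cbind(sample_id = s, rbind(r, tot))
  })
  df <- do.call(rbind, rows)
  paste0(paste(names(df), collapse = "\t"), "\n",
         paste(apply(df, 1, paste, collapse = "\t"), collapse = "\n"), "\n")
}
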