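#' Intersect hit genes across affected cases
#'
#' The discovery engine: a candidate gene must carry at least one
#' surviving variant in EVERY affected sample (not necessarily the same
#' variant — each case may carry a different mutation of the same gene).
#' Variants without a gene id are ignored and counted.
#'
#' @param cohort named list: sample id -> filtered variant table.
#' @param manifest cohort manifest (see [readCohortManifest()]); its
#'   affected rows define the intersection set.
#' @return a [GeneHitMatrix-class]; candidates via [candidateGenes()].
#' @export
intersectGenes <- function(cohort, manifest) {
  manifest <- validateManifest(manifest)
  affected <- manifest$sample_id[manifest$role == "affected"]
  if (!length(affected)) stop("zero affected samples", call. = FALSE)
  missing <- setdiff(affected, names(cohort))
  if (length(missing))
    stop("no variant table for affected sample(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  nNoGene <- 0L
  geneSets <- list()
  index <- list()
  for (s in affected) {
    v <- cohort[[s]]
    hasGene <- !is.na(v$gene_id) & nzchar(v$gene_id)
    nNoGene <- nNoGene + sum(!hasGene)
    v <- v[hasGene, , drop = FALSE]
    geneSets[[s]] <- unique(v$gene_id)
    keys <- variantKey(v)
    index[[s]] <- split(keys, v$gene_id)
  }
  candidates <- sort(Reduce(intersect, geneSets))
  allGenes <- sort(unique(unlist(geneSets)))
  hits <- matrix(FALSE, nrow = length(allGenes), ncol = length(affected),
                 dimnames = list(allGenes, affected))
  variantIndex <- setNames(vector("list", length(allGenes)), allGenes)
  for (g in allGenes) {
    variantIndex[[g]] <- setNames(vector("list", length(affected)), affected)
    for (s in affected) {
      k <- index[[s]][[g]]
      variantIndex[[g]][[s]] <- if (is.null(k)) character(0) else k
      hits[g, s] <- length(variantIndex[[g]][[s]]) > 0L
    }
  }
  if (nNoGene > 0L)
    message(nNoGene, " variant(s) without gene id ignored in intersection")
  new("GeneHitMatrix", hits = hits, variantIndex = variantIndex,
      candidates = candidates, nNoGene = nNoGene)
}

#' @describeIn intersectGenes genes hit in every affected sample.
#' @param x a GeneHitMatrix.
#' @export
candidateGenes <- function(x) x@candidates

#' @describeIn intersectGenes the gene-by-sample logical hit matrix.
#' @export
hitMatrix <- function(x) x@hits

setMethod("show", "GeneHitMatrix", function(object) {
  cat(sprintf("GeneHitMatrix: %d gene(s) x %d affected sample(s); %d candidate(s)\n",
              nrow(object@hits), ncol(object@hits), length(object@candidates)))
  if (length(object@candidates))
    cat("  candidates:", paste(head(object@candidates, 10), collapse = ", "), "\n")
})

#' Confirm de novo status of candidate variants against parents
#'
#' A parent counts as "absent" for a variant only when it lacks the
#' variant key AND its own site depth there reaches `minParentDepth`
#' (absence cannot be asserted from an unsequenced site). Both parents
#' absent gives de_novo; the key present in either parent gives
#' inherited; a missing parent or insufficient depth gives unresolved —
#' de_novo is never declared with a parent datum missing.
#'
#' @param childVariants variant table rows to test.
#' @param mother,father NULL (sample unavailable) or a list with
#'   `variants` (variant table or character keys) and `depths`
#'   (data.frame chrom, pos, depth of the parent's coverage at the
#'   tested sites).
#' @param minParentDepth site depth a parent needs before absence is
#'   believed; default 15, the discovery depth standard.
#' @return data.frame: one row per child variant with per-parent
#'   evidence (present / absent / insufficient_depth / missing) and
#'   verdict (de_novo / inherited / unresolved).
#' @export
confirmDeNovo <- function(childVariants, mother = NULL, father = NULL,
                          minParentDepth = 15L) {
  evid <- function(parent, chrom, pos, key) {
    if (is.null(parent)) return("missing")
    pkeys <- if (is.character(parent$variants)) parent$variants
             else variantKey(parent$variants)
    if (key %in% pkeys) return("present")
    d <- parent$depths
    dp <- if (is.null(d)) NA_integer_
          else d$depth[d$chrom == chrom & d$pos == pos][1]
    if (is.na(dp) || dp < minParentDepth) "insufficient_depth" else "absent"
  }
  keys <- variantKey(childVariants)
  me <- character(nrow(childVariants)); fe <- me; verdict <- me
  for (i in seq_len(nrow(childVariants))) {
    me[i] <- evid(mother, childVariants$chrom[i], childVariants$pos[i], keys[i])
    fe[i] <- evid(father, childVariants$chrom[i], childVariants$pos[i], keys[i])
    verdict[i] <- if (me[i] == "present" || fe[i] == "present") "inherited"
      else if (me[i] == "absent" && fe[i] == "absent") "de_novo"
      else "unresolved"
  }
  data.frame(sample_id = childVariants$sample_id, key = keys,
             chrom = childVariants$chrom, pos = childVariants$pos,
             ref = childVariants$ref, alt = childVariants$alt,
             mother_evidence = me, father_evidence = fe,
             verdict = verdict, stringsAsFactors = FALSE)
}

#' Check co-segregation of a variant with a phenotype in one family
#'
#' Co-segregation means carrier status equals affected status for every
#' family member with known status (vacuously true for an all-negative
#' family).
#'
#' @param presence named logical: does each member carry the variant?
#' @param affected named logical: is each member affected? Names must
#'   match `presence`.
#' @return "co_segregates" or "does_not_segregate".
#' @export
segregationCheck <- function(presence, affected) {
  if (!setequal(names(presence), names(affected)))
    stop("presence and affected must cover the same family members", call. = FALSE)
  affected <- affected[names(presence)]
  if (length(presence) < 2L)
    stop("need at least 2 family members with known status", call. = FALSE)
  if (all(presence == affected)) "co_segregates" else "does_not_segregate"
}
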