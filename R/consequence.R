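## Supported HGVS c. grammar:
##   c.POS[±OFF]REF>ALT
##   c.POS[±OFF][_POS[±OFF]]dup[SEQ]
##   c.POS[±OFF][_POS[±OFF]]del[SEQ]
##   c.POS[±OFF]_POS[±OFF]ins SEQ
##   c.POS[±OFF][_POS[±OFF]]delins SEQ
## Anything else (inversions, protein-level, genomic-level) errors out:
## never a silent misparse.

POSRX <- "([0-9]+)([+-][0-9]+)?"

parsePosTok <- function(pos, off) {
  c(pos = as.integer(pos),
    off = if (is.na(off) || off == "") 0L else as.integer(off))
}

#' Parse an HGVS coding-DNA description
#'
#' Supports substitutions, deletions, duplications, insertions and
#' deletion-insertions, with intronic offsets (c.2196-15) on the del and
#' splice-facing forms. Stated bases are validated against the stated
#' span where that is computable. Unsupported forms raise an explicit
#' "unsupported HGVS" error.
#'
#' @param text an HGVS string such as "c.2050C>T",
#'   "c.2204_2211dupAGGCTGAT" or "c.2196-15_2196-2delTTCCTGTTGTTTCA".
#' @return an [HgvsEdit-class].
#' @export
parseHgvsC <- function(text) {
  text <- trimws(text)
  mk <- function(kind, s, e, refBases = "", insBases = "") {
    new("HgvsEdit", kind = kind,
        startPos = s[["pos"]], startOff = s[["off"]],
        endPos = e[["pos"]], endOff = e[["off"]],
        refBases = toupper(refBases), insBases = toupper(insBases),
        text = text)
  }
  m <- regmatches(text, regexec(paste0("^c\\.", POSRX, "([ACGTacgt])>([ACGTacgt])$"), text))[[1]]
  if (length(m)) {
    p <- parsePosTok(m[2], m[3])
    return(mk("substitution", p, p, refBases = m[4], insBases = m[5]))
  }
  m <- regmatches(text, regexec(paste0("^c\\.", POSRX, "(?:_", POSRX, ")?dup([ACGTacgt]*)$"), text))[[1]]
  if (length(m)) {
    s <- parsePosTok(m[2], m[3])
    e <- if (m[4] == "") s else parsePosTok(m[4], m[5])
    return(mk("duplication", s, e, refBases = m[6], insBases = m[6]))
  }
  m <- regmatches(text, regexec(paste0("^c\\.", POSRX, "(?:_", POSRX, ")?delins([ACGTacgt]+)$"), text))[[1]]
  if (length(m)) {
    s <- parsePosTok(m[2], m[3])
    e <- if (m[4] == "") s else parsePosTok(m[4], m[5])
    return(mk("delins", s, e, insBases = m[6]))
  }
  m <- regmatches(text, regexec(paste0("^c\\.", POSRX, "(?:_", POSRX, ")?del([ACGTacgt]*)$"), text))[[1]]
  if (length(m)) {
    s <- parsePosTok(m[2], m[3])
    e <- if (m[4] == "") s else parsePosTok(m[4], m[5])
    return(mk("deletion", s, e, refBases = m[6]))
  }
  m <- regmatches(text, regexec(paste0("^c\\.", POSRX, "_", POSRX, "ins([ACGTacgt]+)$"), text))[[1]]
  if (length(m)) {
    s <- parsePosTok(m[2], m[3]); e <- parsePosTok(m[4], m[5])
    return(mk("insertion", s, e, insBases = m[6]))
  }
  stop("unsupported HGVS: ", text, call. = FALSE)
}

setMethod("show", "HgvsEdit", function(object) {
  cat(sprintf("HgvsEdit %s: %s\n", object@kind, object@text))
})

## Intron offsets covered by an edit (empty for purely exonic edits).
## For a span anchored on a single exon boundary (c.2196-15_2196-2) the
## covered offsets are the full stated range.
intronOffsetsCovered <- function(edit) {
  offs <- integer(0)
  if (edit@startPos == edit@endPos && (edit@startOff != 0L || edit@endOff != 0L)) {
    rng <- sort(c(edit@startOff, edit@endOff))
    offs <- setdiff(rng[1]:rng[2], 0L)
  } else {
    if (edit@startOff != 0L) offs <- c(offs, edit@startOff)
    if (edit@endOff != 0L) offs <- c(offs, edit@endOff)
  }
  offs
}

#' Classify the consequence of a parsed coding-level edit
#'
#' Substitutions are classified by translating the affected codon before
#' and after the edit (synonymous / missense / nonsense, with the
#' protein change in p.R684C style). Exonic indels are frameshift unless
#' the net length change is a multiple of 3 (inframe_indel). Edits
#' touching intronic offsets within the splice windows (acceptor
#' -12..-1, donor +1..+6 by default) are splice_region; deeper intronic
#' edits are intronic. A truncating call is nonsense, frameshift, or a
#' splice-region deletion removing at least one in-window base.
#' `nmdEscape` is TRUE for truncating edits in, or immediately adjacent
#' to, the last exon (such transcripts are predicted to escape
#' nonsense-mediated decay).
#'
#' @param edit an [HgvsEdit-class] or HGVS string.
#' @param model a [TranscriptModel-class].
#' @param alignment optional homolog alignment
#'   ([readHomologAlignment()]) for per-residue conservation.
#' @param acceptorWindow,donorWindow intronic offset ranges defining the
#'   splice region.
#' @return a [ConsequenceCall-class].
#' @export
classifyEdit <- function(edit, model, alignment = NULL,
                         acceptorWindow = c(-12L, -1L),
                         donorWindow = c(1L, 6L)) {
  if (is.character(edit)) edit <- parseHgvsC(edit)
  if (edit@startPos < 1L || edit@endPos > cdsLength(model))
    stop("coordinate outside transcript model", call. = FALSE)

  offs <- intronOffsetsCovered(edit)
  aa <- NA_integer_
  proteinChange <- NA_character_
  cpg <- NA
  exonNumber <- exonOfCoding(model, edit@startPos)
  inLast <- FALSE

  if (length(offs)) {
    inAcc <- any(offs >= acceptorWindow[1] & offs <= acceptorWindow[2])
    inDon <- any(offs >= donorWindow[1] & offs <= donorWindow[2])
    cls <- if (inAcc || inDon) "splice_region" else "intronic"
    truncating <- cls == "splice_region" &&
      edit@kind %in% c("deletion", "delins") && (inAcc || inDon)
    ## anchored-exon rule: an intronic edit is "adjacent to" the exon
    ## whose boundary anchors its offsets
    anchorExon <- exonOfCoding(model, if (edit@startOff < 0L || edit@endOff < 0L)
      max(edit@startPos, edit@endPos) else min(edit@startPos, edit@endPos))
    exonNumber <- anchorExon
    inLast <- anchorExon == lastExonNumber(model)
  } else if (edit@kind == "substitution") {
    cpos <- edit@startPos
    refInCds <- as.character(Biostrings::subseq(model@cds, cpos, cpos))
    if (refInCds != edit@refBases)
      stop(sprintf("HGVS ref base %s does not match CDS base %s at c.%d",
                   edit@refBases, refInCds, cpos), call. = FALSE)
    aa <- as.integer(ceiling(cpos / 3))
    wtCodon <- codonAt(model, aa)
    ic <- cpos - (aa - 1L) * 3L
    mutCodon <- wtCodon
    substr(mutCodon, ic, ic) <- edit@insBases
    wtAa <- as.character(Biostrings::translate(Biostrings::DNAString(wtCodon)))
    mutAa <- as.character(Biostrings::translate(Biostrings::DNAString(mutCodon)))
    cls <- if (wtAa == mutAa) "synonymous"
           else if (mutAa == "*") "nonsense" else "missense"
    if (cls != "synonymous")
      proteinChange <- sprintf("p.%s%d%s", wtAa, aa,
                               if (mutAa == "*") "X" else mutAa)
    cpg <- cpgContext(model@cds, cpos, edit@refBases)
    truncating <- cls == "nonsense"
    inLast <- exonOfCoding(model, cpos) == lastExonNumber(model)
    exonNumber <- exonOfCoding(model, cpos)
  } else {
    span <- hgvsSpanLength(edit)
    net <- switch(edit@kind,
      duplication = if (nzchar(edit@insBases)) nchar(edit@insBases) else span,
      insertion = nchar(edit@insBases),
      deletion = -span,
      delins = nchar(edit@insBases) - span)
    if (is.na(net)) stop("cannot size an indel spanning an exon/intron boundary",
                         call. = FALSE)
    cls <- if (abs(net) %% 3L == 0L) "inframe_indel" else "frameshift"
    aa <- as.integer(ceiling(edit@startPos / 3))
    truncating <- cls == "frameshift"
    exons <- exonOfCoding(model, c(edit@startPos, edit@endPos))
    exonNumber <- exons[1]
    inLast <- all(exons == lastExonNumber(model))
  }

  domainHit <- if (!is.na(aa)) annotateDomain(aa, model@domains) else NA_character_
  conservation <- if (!is.null(alignment) && !is.na(aa) &&
                      cls %in% c("missense", "nonsense"))
    conservationScore(aa, alignment) else NA_real_

  new("ConsequenceCall", hgvs = edit@text, consequenceClass = cls,
      proteinChange = proteinChange, exonNumber = exonNumber,
      inLastExon = inLast, truncating = truncating,
      nmdEscape = truncating && inLast,
      domainHit = domainHit %||% NA_character_,
      cpgSite = if (is.na(cpg)) NA else cpg,
      conservation = conservation)
}

setMethod("show", "ConsequenceCall", function(object) {
  cat(sprintf("ConsequenceCall %s: %s%s exon %d%s%s%s\n",
              object@hgvs, object@consequenceClass,
              if (!is.na(object@proteinChange)) paste0(" (", object@proteinChange, ")") else "",
              object@exonNumber,
              if (object@truncating) " truncating" else "",
              if (object@nmdEscape) " NMD-escape" else "",
              if (!is.na(object@domainHit)) paste0(" [", object@domainHit, "]") else ""))
})

#' @describeIn classifyEdit is the call truncating (nonsense, frameshift,
#'   or splice-ablating)?
#' @param call a ConsequenceCall.
#' @export
isTruncating <- function(call) call@truncating

#' Classify a vector of HGVS strings into a table
#'
#' @param hgvs character vector of HGVS c. descriptions.
#' @param model a [TranscriptModel-class].
#' @param alignment optional homolog alignment for conservation.
#' @return data.frame with one row per input string.
#' @export
classifyTable <- function(hgvs, model, alignment = NULL) {
  calls <- lapply(hgvs, classifyEdit, model = model, alignment = alignment)
  data.frame(
    hgvs_c = hgvs,
    consequence_class = vapply(calls, function(x) x@consequenceClass, character(1)),
    protein_change = vapply(calls, function(x) x@proteinChange, character(1)),
    exon_number = vapply(calls, function(x) x@exonNumber, integer(1)),
    in_last_exon = vapply(calls, function(x) x@inLastExon, logical(1)),
    truncating = vapply(calls, function(x) x@truncating, logical(1)),
    nmd_escape = vapply(calls, function(x) x@nmdEscape, logical(1)),
    domain_hit = vapply(calls, function(x) x@domainHit, character(1)),
    cpg_site = vapply(calls, function(x) if (is.na(x@cpgSite)) NA else x@cpgSite, logical(1)),
    conservation = vapply(calls, function(x) x@conservation, numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Which protein domain contains a residue?
#'
#' @param proteinPosition residue number (1-based).
#' @param domainTable data.frame (name, aa_start, aa_end), inclusive
#'   non-overlapping intervals.
#' @return domain name, or NA when no interval covers the residue.
#' @export
annotateDomain <- function(proteinPosition, domainTable) {
  if (is.null(domainTable) || !nrow(domainTable)) return(NA_character_)
  o <- order(domainTable$aa_start)
  if (nrow(domainTable) > 1L &&
      any(domainTable$aa_end[o][-nrow(domainTable)] >= domainTable$aa_start[o][-1]))
    stop("overlapping domain rows", call. = FALSE)
  hit <- which(domainTable$aa_start <= proteinPosition &
               proteinPosition <= domainTable$aa_end)
  if (length(hit)) domainTable$name[hit[1]] else NA_character_
}

#' Does a substitution hit a CpG dinucleotide?
#'
#' TRUE iff the mutated base participates in a CpG on either strand: a
#' reference C directly followed by G, or a reference G directly
#' preceded by C (the reverse-strand CpG). Methylated CpG cytosines
#' deaminate to T, making such sites mutational hotspots. At a sequence
#' edge with an undefined neighbour the answer is FALSE (logged).
#'
#' @param sequence the coding sequence (character or DNAString).
#' @param pos 1-based position of the substituted base.
#' @param ref the reference base at `pos`.
#' @return logical.
#' @export
cpgContext <- function(sequence, pos, ref) {
  s <- as.character(sequence)
  n <- nchar(s)
  if (substr(s, pos, pos) != ref)
    stop(sprintf("ref %s does not match sequence base %s at %d",
                 ref, substr(s, pos, pos), pos), call. = FALSE)
  if (ref == "C") {
    if (pos == n) { message("CpG check at sequence edge: no next base"); return(FALSE) }
    return(substr(s, pos + 1L, pos + 1L) == "G")
  }
  if (ref == "G") {
    if (pos == 1L) { message("CpG check at sequence edge: no previous base"); return(FALSE) }
    return(substr(s, pos - 1L, pos - 1L) == "C")
  }
  FALSE
}

#' Cross-species conservation of one residue
#'
#' Maps a human residue number to its alignment column (skipping gaps in
#' the human row, which must be first) and returns the fraction of
#' non-gap homolog residues identical to the human residue there.
#'
#' @param proteinPosition human residue number.
#' @param alignment an AAStringSet, human first, equal row lengths.
#' @return real in [0, 1]; NA if every homolog is gapped at the column.
#' @export
conservationScore <- function(proteinPosition, alignment) {
  rows <- as.character(alignment)
  human <- strsplit(rows[1], "")[[1]]
  nonGap <- which(human != "-")
  if (proteinPosition > length(nonGap))
    stop("position beyond human sequence length", call. = FALSE)
  col <- nonGap[proteinPosition]
  res <- vapply(rows[-1], function(r) substr(r, col, col), character(1))
  res <- res[res != "-"]
  if (!length(res)) return(NA_real_)
  mean(res == human[col])
}

#' Recurrence report over a phenotype table
#'
#' Groups cases by protein change (falling back to the cDNA description
#' for protein-silent entries) and counts cases and recorded de novo
#' events per mutation, sorted by case count then name. Flags recurrent
#' mutations such as the R684C CpG hotspot.
#'
#' @param records data.frame from [readPhenotypeTable()].
#' @return data.frame (protein_change, n_cases, n_de_novo).
#' @export
recurrenceReport <- function(records) {
  if (!nrow(records))
    return(data.frame(protein_change = character(0), n_cases = integer(0),
                      n_de_novo = integer(0), stringsAsFactors = FALSE))
  key <- ifelse(is.na(records$protein_change) | !nzchar(records$protein_change),
                records$hgvs_c, records$protein_change)
  sp <- split(records, key)
  out <- data.frame(
    protein_change = names(sp),
    n_cases = vapply(sp, nrow, integer(1)),
    n_de_novo = vapply(sp, function(d) sum(d$inheritance == "de_novo"), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$n_cases, out$protein_change), , drop = FALSE]
}
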