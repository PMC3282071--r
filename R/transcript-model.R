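#' Construct a TranscriptModel
#'
#' @param chrom contig name.
#' @param exonStarts,exonEnds genomic 1-based inclusive exon bounds in
#'   transcript 5'->3' order.
#' @param strand "+" or "-".
#' @param cds coding sequence (character or [Biostrings::DNAString]).
#' @param cdsStartTx transcript coordinate of the first CDS base.
#' @param locusSeq optional forward-strand genomic sequence of the locus.
#' @param locusStart genomic coordinate of the first locusSeq base.
#' @param domains data.frame (name, aa_start, aa_end) or NULL.
#' @return a validated [TranscriptModel-class].
#' @export
TranscriptModel <- function(chrom, exonStarts, exonEnds, strand, cds,
                            cdsStartTx, locusSeq = NULL, locusStart = NA_integer_,
                            domains = NULL) {
  if (is.character(cds)) cds <- Biostrings::DNAString(cds)
  if (is.null(locusSeq)) locusSeq <- Biostrings::DNAString("")
  if (is.character(locusSeq)) locusSeq <- Biostrings::DNAString(locusSeq)
  if (is.null(domains))
    domains <- data.frame(name = character(), aa_start = integer(),
                          aa_end = integer(), stringsAsFactors = FALSE)
  new("TranscriptModel", chrom = as.character(chrom),
      strand = strand, exonStarts = as.integer(exonStarts),
      exonEnds = as.integer(exonEnds), cds = cds,
      cdsStartTx = as.integer(cdsStartTx), locusSeq = locusSeq,
      locusStart = as.integer(locusStart), domains = domains)
}

#' @describeIn TranscriptModel number of exons.
#' @param model a TranscriptModel.
#' @export
exonCount <- function(model) length(model@exonStarts)

#' @describeIn TranscriptModel the last exon's number.
#' @export
lastExonNumber <- function(model) exonCount(model)

#' @describeIn TranscriptModel coding sequence as a DNAString.
#' @export
cdsSeq <- function(model) model@cds

#' @describeIn TranscriptModel total CDS length in bases.
#' @export
cdsLength <- function(model) length(model@cds)

#' @describeIn TranscriptModel domain interval table.
#' @export
domainTable <- function(model) model@domains

exonWidths <- function(model) model@exonEnds - model@exonStarts + 1L

txLength <- function(model) sum(exonWidths(model))

setMethod("show", "TranscriptModel", function(object) {
  cat(sprintf("TranscriptModel on %s(%s): %d exons, tx %d nt, CDS %d nt (%d aa + stop)\n",
              object@chrom, object@strand, exonCount(object),
              txLength(object), length(object@cds), length(object@cds) / 3L - 1L))
  if (nrow(object@domains))
    cat(sprintf("  domains: %s\n",
                paste(sprintf("%s[%d-%d]", object@domains$name,
                              object@domains$aa_start, object@domains$aa_end),
                      collapse = ", ")))
  if (length(object@locusSeq))
    cat(sprintf("  locus sequence: %d nt from %d\n",
                length(object@locusSeq), object@locusStart))
})

## exon index containing a transcript coordinate
exonOfTx <- function(model, txpos) {
  cw <- cumsum(exonWidths(model))
  i <- findInterval(txpos - 1L, c(0L, cw)) # 1-based exon index
  if (any(txpos < 1L | txpos > cw[length(cw)]))
    stop("transcript coordinate outside transcript", call. = FALSE)
  i
}

#' Convert transcript coordinates to genomic coordinates
#'
#' @param model a [TranscriptModel-class].
#' @param txpos transcript coordinates (1-based, vectorised).
#' @return integer genomic positions.
#' @export
txToGenomic <- function(model, txpos) {
  i <- exonOfTx(model, txpos)
  cw0 <- c(0L, cumsum(exonWidths(model)))
  o <- txpos - cw0[i]
  if (model@strand == "+") model@exonStarts[i] + o - 1L
  else model@exonEnds[i] - o + 1L
}

#' Convert genomic coordinates to transcript coordinates
#'
#' @param model a [TranscriptModel-class].
#' @param gpos genomic positions (must be exonic).
#' @return integer transcript coordinates.
#' @export
genomicToTx <- function(model, gpos) {
  cw0 <- c(0L, cumsum(exonWidths(model)))
  out <- integer(length(gpos))
  for (k in seq_along(gpos)) {
    g <- gpos[k]
    i <- which(model@exonStarts <= g & g <= model@exonEnds)
    if (length(i) != 1L)
      stop(sprintf("genomic position %d is not exonic", g), call. = FALSE)
    o <- if (model@strand == "+") g - model@exonStarts[i] + 1L
         else model@exonEnds[i] - g + 1L
    out[k] <- cw0[i] + o
  }
  out
}

#' Convert coding (HGVS c.) coordinates to genomic coordinates
#'
#' Exonic positions map through the exon structure; a non-zero `offset`
#' steps into the adjoining intron from the anchored exon boundary
#' (negative offsets anchor the first base of an exon, positive offsets
#' the last), as in HGVS c.2196-15.
#'
#' @param model a [TranscriptModel-class].
#' @param cpos coding positions (1..cdsLength), vectorised.
#' @param offset intron offsets (0 = exonic), recycled.
#' @return integer genomic positions.
#' @export
codingToGenomic <- function(model, cpos, offset = 0L) {
  n <- max(length(cpos), length(offset))
  cpos <- rep_len(as.integer(cpos), n)
  offset <- rep_len(as.integer(offset), n)
  if (any(cpos < 1L | cpos > cdsLength(model)))
    stop("coding position outside CDS", call. = FALSE)
  txpos <- model@cdsStartTx + cpos - 1L
  i <- exonOfTx(model, txpos)
  cw0 <- c(0L, cumsum(exonWidths(model)))
  o <- txpos - cw0[i]
  dirsign <- if (model@strand == "+") 1L else -1L
  out <- integer(n)
  for (k in seq_len(n)) {
    if (offset[k] == 0L) {
      out[k] <- if (model@strand == "+") model@exonStarts[i[k]] + o[k] - 1L
                else model@exonEnds[i[k]] - o[k] + 1L
    } else if (offset[k] < 0L) {
      if (o[k] != 1L)
        stop(sprintf("negative intron offset must anchor an exon's first base (c.%d)",
                     cpos[k]), call. = FALSE)
      b <- if (model@strand == "+") model@exonStarts[i[k]] else model@exonEnds[i[k]]
      out[k] <- b + offset[k] * dirsign
    } else {
      if (o[k] != exonWidths(model)[i[k]])
        stop(sprintf("positive intron offset must anchor an exon's last base (c.%d)",
                     cpos[k]), call. = FALSE)
      b <- if (model@strand == "+") model@exonEnds[i[k]] else model@exonStarts[i[k]]
      out[k] <- b + offset[k] * dirsign
    }
  }
  out
}

#' Convert genomic coordinates to coding coordinates
#'
#' Inverse of [codingToGenomic()] for exonic CDS bases.
#'
#' @param model a [TranscriptModel-class].
#' @param gpos genomic positions within the CDS.
#' @return integer coding positions.
#' @export
genomicToCoding <- function(model, gpos) {
  cpos <- genomicToTx(model, gpos) - model@cdsStartTx + 1L
  if (any(cpos < 1L | cpos > cdsLength(model)))
    stop("genomic position maps outside the CDS", call. = FALSE)
  cpos
}

#' Exon number containing a coding position
#'
#' @param model a [TranscriptModel-class].
#' @param cpos coding position(s).
#' @return integer exon numbers.
#' @export
exonOfCoding <- function(model, cpos) {
  exonOfTx(model, model@cdsStartTx + as.integer(cpos) - 1L)
}

## base of the locus sequence at genomic position g (forward strand)
locusBase <- function(model, g) {
  if (!length(model@locusSeq)) stop("model has no locus sequence", call. = FALSE)
  i <- g - model@locusStart + 1L
  if (any(i < 1L | i > length(model@locusSeq)))
    stop("position outside locus sequence", call. = FALSE)
  vapply(i, function(j) as.character(model@locusSeq[j]), character(1))
}

locusSubseq <- function(model, gstart, gend) {
  i <- gstart - model@locusStart + 1L
  j <- gend - model@locusStart + 1L
  if (i < 1L || j > length(model@locusSeq) || i > j)
    stop("window outside locus sequence", call. = FALSE)
  as.character(Biostrings::subseq(model@locusSeq, i, j))
}

#' Translate the CDS (or a codon range) of a model
#'
#' @param model a [TranscriptModel-class].
#' @return character protein sequence including the terminal "*".
#' @export
translateCds <- function(model) {
  as.character(Biostrings::translate(model@cds))
}

codonAt <- function(model, aa) {
  s <- (aa - 1L) * 3L + 1L
  as.character(Biostrings::subseq(model@cds, s, s + 2L))
}
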