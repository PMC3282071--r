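#' TranscriptModel: the coordinate engine for one transcript
#'
#' Holds exon structure (genomic, 1-based inclusive, in transcript
#' 5'->3' order), the coding sequence, the position of the CDS start in
#' transcript coordinates, an optional forward-strand locus sequence
#' (exons plus introns, needed for splice-site scoring), and a
#' protein-domain interval table. All conversions between genomic, transcript
#' and coding (HGVS c.) coordinates are centralised here: VCF and HGVS
#' are 1-based, internal arithmetic never leaks other conventions.
#'
#' @slot chrom single chromosome/contig name.
#' @slot strand "+" or "-".
#' @slot exonStarts,exonEnds integer vectors, genomic 1-based inclusive,
#'   ordered 5'->3' along the transcript (descending genomically on "-").
#' @slot cds a [Biostrings::DNAString] of the coding sequence, length a
#'   multiple of 3, ending in a stop codon.
#' @slot cdsStartTx transcript coordinate (1-based) of the first CDS base.
#' @slot locusSeq forward-strand genomic sequence of the locus
#'   (may be empty when splice scoring is not needed).
#' @slot locusStart genomic coordinate of `locusSeq[1]`.
#' @slot domains data.frame with columns name, aa_start, aa_end
#'   (1-based inclusive amino-acid intervals, non-overlapping).
#' @export
setClass("TranscriptModel",
  representation(
    chrom = "character",
    strand = "character",
    exonStarts = "integer",
    exonEnds = "integer",
    cds = "DNAString",
    cdsStartTx = "integer",
    locusSeq = "DNAString",
    locusStart = "integer",
    domains = "data.frame"
  )
)

setValidity("TranscriptModel", function(object) {
  msg <- character()
  if (length(object@chrom) != 1L) msg <- c(msg, "chrom must be length 1")
  if (!object@strand %in% c("+", "-")) msg <- c(msg, "strand must be '+' or '-'")
  ns <- length(object@exonStarts)
  if (ns != length(object@exonEnds) || ns < 1L)
    msg <- c(msg, "exonStarts/exonEnds must be equal-length, non-empty")
  if (any(object@exonEnds < object@exonStarts))
    msg <- c(msg, "each exon must have start <= end")
  if (ns > 1L) {
    ## non-overlap and correct transcript order
    if (object@strand == "+") {
      if (any(diff(object@exonStarts) <= 0) ||
          any(object@exonStarts[-1] <= object@exonEnds[-ns]))
        msg <- c(msg, "exons must be non-overlapping and 5'->3' on '+'")
    } else {
      if (any(diff(object@exonStarts) >= 0) ||
          any(object@exonEnds[-1] >= object@exonStarts[-ns]))
        msg <- c(msg, "exons must be non-overlapping and 5'->3' on '-'")
    }
  }
  cl <- length(object@cds)
  if (cl %% 3L != 0L) msg <- c(msg, "CDS length must be divisible by 3")
  txlen <- sum(object@exonEnds - object@exonStarts + 1L)
  if (object@cdsStartTx < 1L || object@cdsStartTx + cl - 1L > txlen)
    msg <- c(msg, "CDS does not fit inside the transcript")
  dom <- object@domains
  if (nrow(dom)) {
    if (!all(c("name", "aa_start", "aa_end") %in% names(dom)))
      msg <- c(msg, "domains must have columns name, aa_start, aa_end")
    else {
      o <- order(dom$aa_start)
      if (any(dom$aa_end[o][-nrow(dom)] >= dom$aa_start[o][-1]))
        msg <- c(msg, "domain intervals must be non-overlapping")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Position-weight-matrix splice-site scorer
#'
#' A log2-odds PWM over a fixed window: score(w) = sum_i
#' log2(f[base_i, i] / 0.25). Trained from example site sequences with a
#' per-cell pseudocount. Deterministic: the same window always yields
#' the same score.
#'
#' @slot name scorer name.
#' @slot siteType "acceptor" or "donor".
#' @slot pwm 4 x L numeric matrix of log2 odds, rownames A,C,G,T.
#' @slot intronBases,exonBases how the window straddles the exon
#'   boundary (acceptor windows end `exonBases` into the exon; donor
#'   windows start `exonBases` before its end).
#' @export
setClass("PwmScorer",
  representation(
    name = "character",
    siteType = "character",
    pwm = "matrix",
    intronBases = "integer",
    exonBases = "integer"
  )
)

setValidity("PwmScorer", function(object) {
  msg <- character()
  if (!object@siteType %in% c("acceptor", "donor"))
    msg <- c(msg, "siteType must be 'acceptor' or 'donor'")
  if (!identical(rownames(object@pwm), DNA_BASES))
    msg <- c(msg, "pwm rownames must be A,C,G,T")
  if (ncol(object@pwm) != object@intronBases + object@exonBases)
    msg <- c(msg, "pwm width must equal intronBases + exonBases")
  if (length(msg)) msg else TRUE
})

#' A named splice scorer holding one acceptor and one donor PWM
#'
#' The unit handed to [assessSpliceVariant()]: five of these (two
#' primary, three confirmatory) make up the consensus procedure.
#'
#' @slot name scorer name.
#' @slot acceptor,donor [PwmScorer-class] objects.
#' @export
setClass("SpliceScorer",
  representation(name = "character", acceptor = "PwmScorer", donor = "PwmScorer"))

#' Per-variant record of the two-tier splice consensus
#'
#' @slot hgvs the assessed edit as given.
#' @slot siteType,sitePos the annotated site assessed ("acceptor"/"donor",
#'   genomic position of the exon-side boundary base).
#' @slot mode "wildtype_loss" or "cryptic_gain" (mode that triggered, or
#'   the stronger candidate mode when not triggered).
#' @slot tier1 data.frame (scorer, wt_score, var_score, pct_change) for
#'   the two primary scorers in the reported mode.
#' @slot triggered did both primary scorers exceed the threshold in a
#'   consistent direction?
#' @slot tier2 data.frame of the three confirmatory scorers (0 rows when
#'   not triggered).
#' @slot verdict "disruptive", "not_disruptive" or "indeterminate".
#' @export
setClass("SpliceVerdict",
  representation(
    hgvs = "character",
    siteType = "character",
    sitePos = "integer",
    mode = "character",
    tier1 = "data.frame",
    triggered = "logical",
    tier2 = "data.frame",
    verdict = "character"
  )
)

setValidity("SpliceVerdict", function(object) {
  msg <- character()
  if (!object@verdict %in% c("disruptive", "not_disruptive", "indeterminate"))
    msg <- c(msg, "invalid verdict")
  if (object@triggered && nrow(object@tier2) == 0L)
    msg <- c(msg, "tier2 scores must be present when triggered")
  if (!object@triggered && nrow(object@tier2) > 0L)
    msg <- c(msg, "tier2 scores must be absent when not triggered")
  if (object@verdict == "disruptive" && !object@triggered)
    msg <- c(msg, "disruptive verdict requires trigger")
  if (length(msg)) msg else TRUE
})

#' Gene-by-affected-sample hit matrix
#'
#' @slot hits logical matrix, genes x affected samples; `hits[g, s]` is
#'   TRUE iff sample s carries >= 1 surviving variant in gene g.
#' @slot variantIndex nested list gene -> sample -> character vector of
#'   variant keys.
#' @slot candidates genes hit in every affected sample, sorted.
#' @slot nNoGene variants ignored for lacking a gene id.
#' @export
setClass("GeneHitMatrix",
  representation(
    hits = "matrix",
    variantIndex = "list",
    candidates = "character",
    nNoGene = "integer"
  )
)

setValidity("GeneHitMatrix", function(object) {
  msg <- character()
  if (!is.logical(object@hits)) msg <- c(msg, "hits must be a logical matrix")
  for (g in rownames(object@hits)) {
    for (s in colnames(object@hits)) {
      nonempty <- length(object@variantIndex[[g]][[s]]) > 0L
      if (object@hits[g, s] != nonempty) {
        msg <- c(msg, "hits[g,s] must mirror non-emptiness of variantIndex")
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Parsed HGVS coding-level edit
#'
#' Coding positions are (base, offset) pairs: offset 0 for exonic bases,
#' negative for intronic bases counted back from the first base of the
#' anchored exon (c.2196-15), positive for bases after the last base of
#' the anchored exon (c.123+4).
#'
#' @slot kind "substitution", "deletion", "duplication", "insertion" or
#'   "delins".
#' @slot startPos,startOff,endPos,endOff coding anchor and intron offset
#'   of the edit's first and last affected base.
#' @slot refBases bases stated in the HGVS string (may be "").
#' @slot insBases inserted/duplicated bases (may be "").
#' @slot text the original string.
#' @export
setClass("HgvsEdit",
  representation(
    kind = "character",
    startPos = "integer", startOff = "integer",
    endPos = "integer", endOff = "integer",
    refBases = "character",
    insBases = "character",
    text = "character"
  )
)

setValidity("HgvsEdit", function(object) {
  msg <- character()
  kinds <- c("substitution", "deletion", "duplication", "insertion", "delins")
  if (!object@kind %in% kinds) msg <- c(msg, "invalid kind")
  if (object@kind == "substitution") {
    if (object@startPos != object@endPos || object@startOff != object@endOff)
      msg <- c(msg, "substitution must span one base")
    if (nchar(object@refBases) != 1L || nchar(object@insBases) != 1L)
      msg <- c(msg, "substitution needs 1-base ref and alt")
  }
  ## span-length consistency when computable without a transcript model
  span <- hgvsSpanLength(object)
  if (!is.na(span) && object@kind %in% c("deletion", "duplication") &&
      nzchar(object@refBases) && nchar(object@refBases) != span)
    msg <- c(msg, sprintf("stated bases (%d) do not match span (%d)",
                          nchar(object@refBases), span))
  if (length(msg)) msg else TRUE
})

## Span length in bases; NA when the span crosses an exon/intron boundary
## and cannot be computed without a model.
hgvsSpanLength <- function(edit) {
  if (edit@startPos == edit@endPos)
    return(edit@endOff - edit@startOff + 1L)
  if (edit@startOff == 0L && edit@endOff == 0L)
    return(edit@endPos - edit@startPos + 1L)
  NA_integer_
}

#' Classified consequence of one coding-level edit
#'
#' @slot hgvs the input HGVS string.
#' @slot consequenceClass one of missense, nonsense, frameshift,
#'   inframe_indel, splice_region, intronic, synonymous.
#' @slot proteinChange e.g. "p.R684C", "p.Y733X"; NA for non-substitutions.
#' @slot exonNumber exon containing (or anchoring) the edit.
#' @slot inLastExon edit lies in, or in the intron flank immediately
#'   adjacent to, the last exon.
#' @slot truncating nonsense, frameshift, or a splice-region deletion
#'   ablating an acceptor/donor window.
#' @slot nmdEscape truncating AND last-exon: predicted to escape
#'   nonsense-mediated decay.
#' @slot domainHit protein domain containing the affected residue, or NA.
#' @slot cpgSite substitution hits a CpG dinucleotide (either strand).
#' @slot conservation column identity of the affected residue across
#'   homologs, in [0, 1]; NA when no alignment was supplied.
#' @export
setClass("ConsequenceCall",
  representation(
    hgvs = "character",
    consequenceClass = "character",
    proteinChange = "character",
    exonNumber = "integer",
    inLastExon = "logical",
    truncating = "logical",
    nmdEscape = "logical",
    domainHit = "character",
    cpgSite = "logical",
    conservation = "numeric"
  )
)

setValidity("ConsequenceCall", function(object) {
  msg <- character()
  if (!object@consequenceClass %in% setdiff(CONSEQUENCE_CLASSES, "other"))
    msg <- c(msg, "invalid consequence class")
  if (object@nmdEscape && !(object@truncating && object@inLastExon))
    msg <- c(msg, "nmdEscape requires a truncating, last-exon edit")
  if (isTRUE(object@cpgSite) && object@consequenceClass %in%
        c("frameshift", "inframe_indel"))
    msg <- c(msg, "cpgSite is defined only for substitutions")
  if (length(msg)) msg else TRUE
})

#' Simulation configuration for synthetic exome cohorts
#'
#' Defaults emulate the discovery design: four affected, unrelated
#' cases, ~5,000 candidate variants per exome after calling, a planted
#' causal gene carrying a different mutation in each case, parental
#' samples for de novo confirmation with one of the eight parents
#' unavailable, and a 115-sample control panel.
#'
#' @slot seed integer; fully determines every output.
#' @slot nAffected number of affected cases (default 4).
#' @slot nBackground background variants per affected exome (default 5000).
#' @slot fracDbsnp,fracLowDepth,fracExcludedClass independent per-variant
#'   probabilities of a dbSNP tag, depth < 15, and an intronic/synonymous
#'   class (defaults 0.4 / 0.1 / 0.2).
#' @slot nGenes background gene universe size (default 1000).
#' @slot plantedGene causal gene id (default "EZH2").
#' @slot plantedHgvs per-case causal mutations, HGVS c. strings, recycled
#'   to nAffected; defaults are the four exome-discovery mutations.
#' @slot nControls control panel size (default 115).
#' @slot parentMissing ids (e.g. "CASE4_F") of unavailable parents;
#'   default drops one father, leaving 7 of 8 parental samples.
#' @slot enforceUniqueCandidate resample background gene assignments so
#'   that no background gene survives filtering in every case (default
#'   TRUE); FALSE gives honest stochastic backgrounds.
#' @export
setClass("SimulationConfig",
  representation(
    seed = "integer",
    nAffected = "integer",
    nBackground = "integer",
    fracDbsnp = "numeric",
    fracLowDepth = "numeric",
    fracExcludedClass = "numeric",
    nGenes = "integer",
    plantedGene = "character",
    plantedHgvs = "character",
    nControls = "integer",
    parentMissing = "character",
    enforceUniqueCandidate = "logical"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  fr <- c(object@fracDbsnp, object@fracLowDepth, object@fracExcludedClass)
  if (any(fr < 0 | fr > 1)) msg <- c(msg, "fractions must lie in [0, 1]")
  if (object@nAffected < 1L) msg <- c(msg, "nAffected must be >= 1")
  if (object@nGenes < 2L) msg <- c(msg, "nGenes must be >= 2")
  if (object@nBackground < 0L || object@nControls < 0L)
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})
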