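## The EZH2-like transcript fixture.
##
## The real EZH2 genomic sequence is not bundled. Instead a synthetic
## 20-exon transcript (19 coding exons; the CDS starts in exon 2) is
## CONSTRUCTED so that every codon/base claim of the 19-mutation table
## holds: codon 684 is CGC (so c.2050C>T gives p.R684C and sits in a CpG),
## codon 639 is AAG, codon 733 is TAC (c.2199C>G gives p.Y733X),
## c.2204-2211 spell AGGCTGAT, c.2230-2232 spell ATC, the last coding
## exon starts at c.2196, and the intron before it ends in the
## polypyrimidine tract TTCCTGTTGTTTCA at offsets -15..-2 followed by the
## canonical AG. The builder asserts each constraint and fails loudly
## rather than ship a silently wrong fixture.

FIXTURE_SEED <- 20111221L
FIXTURE_LOCUS_START <- 1000001L
FIXTURE_CHROM <- "chrSim"

STOP_CODONS <- c("TAA", "TAG", "TGA")

fixtureConstrainedCodons <- function() {
  c(`1` = "ATG",     # start
    `134` = "ATG",   # M134 (c.401 mid-codon T>C -> T)
    `156` = "AAG",   # K156 (c.466 A>G -> E)
    `279` = "CAC",   # H279 (c.836 A>G -> R)
    `626` = "GTG",   # V626 (c.1876 G>A -> M)
    `639` = "AAG",   # K639 (c.1915 A>G -> E)
    `663` = "TAC",   # Y663 (c.1987 T>A -> N)
    `664` = "GAC",   # D664 (c.1991 A>T -> V)
    `682` = "GCC",   # A682 (c.2044 G>A -> T)
    `684` = "CGC",   # R684 (c.2050 C>T -> C; CpG at 2050/2051)
    `695` = "TCA",   # S695 (c.2084 mid-codon C>T -> TTA, L)
    `733` = "TAC",   # Y733 (c.2199 C>G -> TAG stop)
    `735` = "CAG",   # c.2204-2205 = A,G
    `736` = "GCT",   # c.2206-2208
    `737` = "GAT",   # c.2209-2211 (dup target AGGCTGAT)
    `741` = "TAC",   # Y741 (c.2222 A>G -> C)
    `744` = "ATC",   # c.2230-2232 (dupATC target)
    `745` = "GAG",   # E745 (c.2233 G>A -> K)
    `747` = "TAA")   # stop
}

randBases <- function(n, prob = NULL) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = prob), collapse = "")
}

#' Build the EZH2-like transcript fixture
#'
#' Deterministically constructs the 20-exon synthetic transcript model
#' (CDS, exon table, SET/post-SET domain table, full locus sequence with
#' introns) satisfying every codon/base constraint of the 19-mutation
#' table, runs the constraint checks, and optionally writes the model to
#' disk in the formats [readTranscriptModel()] consumes.
#'
#' @param dir optional output directory for exons.tsv, cds.fa,
#'   domains.tsv, locus.fa and constraints.tsv.
#' @return list with `model` (a [TranscriptModel-class]) and `report`
#'   (data.frame constraint/ok). Errors if any constraint fails.
#' @export
buildTranscriptFixture <- function(dir = NULL) {
  model <- withFixedSeed(FIXTURE_SEED, function() {
    nCodon <- 747L
    nonStop <- setdiff(mkAllCodons(), STOP_CODONS)
    codons <- sample(nonStop, nCodon, replace = TRUE)
    fixed <- fixtureConstrainedCodons()
    codons[as.integer(names(fixed))] <- unname(fixed)
    cds <- paste(codons, collapse = "")

    utr5 <- randBases(100L)
    utr3 <- randBases(100L)
    txSeq <- paste0(utr5, cds, utr3)

    exonWidths <- c(100L, rep(122L, 17L), 121L, 146L)
    stopifnot(sum(exonWidths) == nchar(txSeq))
    txEnds <- cumsum(exonWidths)
    txStarts <- txEnds - exonWidths + 1L
    exonSeqs <- substring(txSeq, txStarts, txEnds)

    intronLen <- 300L
    mkIntron <- function(purineMiddle = FALSE, tail = NULL) {
      donor <- "GTAAGT"
      if (is.null(tail)) tail <- paste0(randBases(12L, c(.06, .44, .06, .44)), "AG")
      midLen <- intronLen - nchar(donor) - nchar(tail)
      mid <- if (purineMiddle) randBases(midLen, c(.40, .10, .40, .10))
             else randBases(midLen)
      paste0(donor, mid, tail)
    }
    introns <- vapply(seq_len(19L), function(j)
      mkIntron(purineMiddle = (j == 19L),
               tail = if (j == 19L) paste0("TTCCTGTTGTTTCA", "G") else NULL),
      character(1))

    locusParts <- character(0)
    gStarts <- integer(20L); gEnds <- integer(20L)
    g <- FIXTURE_LOCUS_START
    for (k in seq_len(20L)) {
      gStarts[k] <- g
      gEnds[k] <- g + exonWidths[k] - 1L
      locusParts <- c(locusParts, exonSeqs[k])
      g <- gEnds[k] + 1L
      if (k < 20L) {
        locusParts <- c(locusParts, introns[k])
        g <- g + intronLen
      }
    }
    TranscriptModel(chrom = FIXTURE_CHROM, exonStarts = gStarts,
                    exonEnds = gEnds, strand = "+", cds = cds,
                    cdsStartTx = 101L,
                    locusSeq = paste(locusParts, collapse = ""),
                    locusStart = FIXTURE_LOCUS_START,
                    domains = data.frame(
                      name = c("SET", "post-SET"),
                      aa_start = c(612L, 728L), aa_end = c(727L, 746L),
                      stringsAsFactors = FALSE))
  })

  report <- fixtureConstraintReport(model)
  if (!all(report$ok))
    stop("transcript fixture constraint(s) violated: ",
         paste(report$constraint[!report$ok], collapse = "; "), call. = FALSE)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    ex <- data.frame(chrom = model@chrom, start = model@exonStarts,
                     end = model@exonEnds, exon_number = seq_len(exonCount(model)),
                     strand = model@strand, cds_start_tx = model@cdsStartTx)
    write.table(ex, file.path(dir, "exons.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    writeLines(c(">cds synthetic EZH2-like coding sequence",
                 as.character(model@cds)), file.path(dir, "cds.fa"))
    write.table(model@domains, file.path(dir, "domains.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeLines(c(sprintf(">locus start=%d synthetic EZH2-like locus", model@locusStart),
                 as.character(model@locusSeq)), file.path(dir, "locus.fa"))
    write.table(report, file.path(dir, "constraints.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(model = model, report = report)
}

mkAllCodons <- function() {
  g <- expand.grid(DNA_BASES, DNA_BASES, DNA_BASES, stringsAsFactors = FALSE)
  paste0(g[[3]], g[[2]], g[[1]])
}

fixtureConstraintReport <- function(model) {
  cds <- as.character(model@cds)
  prot <- translateCds(model)
  sub2 <- function(a, b) substr(cds, a, b)
  acceptorTail <- function() {
    b <- model@exonStarts[20L]
    locusSubseq(model, b - 15L, b - 1L)
  }
  checks <- c(
    "20 exons" = exonCount(model) == 20L,
    "CDS length 2241, divisible by 3" =
      cdsLength(model) == 2241L && cdsLength(model) %% 3L == 0L,
    "ORF: starts M, single terminal stop" =
      startsWith(prot, "M") && endsWith(prot, "*") &&
      !grepl("\\*", substr(prot, 1L, nchar(prot) - 1L)),
    "codon 684 is CGC (R) in CpG context" =
      codonAt(model, 684L) == "CGC" && sub2(2051L, 2051L) == "G",
    "codon 639 is AAG (K)" = codonAt(model, 639L) == "AAG",
    "codon 733 is TAC (Y)" = codonAt(model, 733L) == "TAC",
    "c.2204-2211 spell AGGCTGAT" = sub2(2204L, 2211L) == "AGGCTGAT",
    "c.2230-2232 spell ATC" = sub2(2230L, 2232L) == "ATC",
    "last exon starts at c.2196" =
      exonOfCoding(model, 2196L) == 20L && exonOfCoding(model, 2195L) == 19L,
    "intron 19 ends ...TTCCTGTTGTTTCA+G (polypyrimidine tract, AG acceptor)" =
      acceptorTail() == paste0("TTCCTGTTGTTTCA", "G"),
    "SET domain [612,727], post-SET [728,746]" =
      identical(model@domains$aa_start, c(612L, 728L)) &&
      identical(model@domains$aa_end, c(727L, 746L))
  )
  data.frame(constraint = names(checks), ok = unname(checks),
             stringsAsFactors = FALSE)
}
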