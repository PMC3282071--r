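## Shared fixture model, built once per test run.
.fixtureCache <- new.env(parent = emptyenv())

fixtureModel <- function() {
  if (is.null(.fixtureCache$model))
    .fixtureCache$model <- buildTranscriptFixture()$model
  .fixtureCache$model
}

builtinScorersCached <- function() {
  if (is.null(.fixtureCache$scorers))
    .fixtureCache$scorers <- builtinSpliceScorers()
  .fixtureCache$scorers
}

phenotypeTable <- function() {
  if (is.null(.fixtureCache$t1))
    .fixtureCache$t1 <- readPhenotypeTable(ezh2PhenotypeFile())
  .fixtureCache$t1
}

## toy single-exon plus-strand gene: CDS == exon
singleExonModel <- function() {
  TranscriptModel(chrom = "chrToy", exonStarts = 501L, exonEnds = 512L,
                  strand = "+", cds = "ATGGCTAAATAA", cdsStartTx = 1L)
}

## toy two-exon minus-strand gene
minusToyModel <- function() {
  ## transcript order 5'->3' means descending genomic coordinates
  TranscriptModel(chrom = "chrToy", exonStarts = c(901L, 101L),
                  exonEnds = c(906L, 106L), strand = "-",
                  cds = "ATGAAATTTTAA", cdsStartTx = 1L)
}

## one hand-written VCF body for parser tests
writeTestVcf <- function(path, bodyLines, sample = "S1") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrSim>",
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Site read depth">',
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene id">',
    '##INFO=<ID=CSQCLS,Number=1,Type=String,Description="Consequence class">',
    '##INFO=<ID=RSID,Number=1,Type=String,Description="dbSNP id">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"))
  writeLines(c(hdr, bodyLines), path)
  path
}
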