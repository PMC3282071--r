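## Independent oracles, deliberately written as plain per-item loops so
## they share no code path with the implementation under test.

## brute-force re-application of the five filter predicates
oracleFilterKeep <- function(v, minDepth = 15L,
                             excluded = c("intronic", "synonymous"),
                             knownIds = character(), pseudo = character(),
                             pon = character()) {
  keep <- logical(nrow(v))
  for (i in seq_len(nrow(v))) {
    cls <- v$consequence[i]
    if (is.na(cls)) cls <- "other"
    key <- paste(v$chrom[i], v$pos[i], v$ref[i], v$alt[i], sep = ":")
    hasRs <- !is.na(v$dbsnp_id[i]) && nzchar(v$dbsnp_id[i])
    keep[i] <- v$depth[i] >= minDepth &&
      !(cls %in% excluded) &&
      !hasRs && !(key %in% knownIds) &&
      (is.na(v$gene_id[i]) || !(v$gene_id[i] %in% pseudo)) &&
      !(key %in% pon)
  }
  keep
}

## brute-force gene intersection: count, per gene, how many samples hit it
oracleIntersect <- function(variantTables) {
  counts <- list()
  for (v in variantTables) {
    genes <- unique(v$gene_id[!is.na(v$gene_id) & nzchar(v$gene_id)])
    for (g in genes) counts[[g]] <- (counts[[g]] %||% 0L) + 1L
  }
  sort(names(counts)[vapply(counts, identical, logical(1),
                            length(variantTables))])
}
`%||%` <- function(a, b) if (is.null(a)) b else a

## independent codon translation via the standard genetic code table
oracleProteinChange <- function(cds, cpos, alt) {
  cds <- as.character(cds)
  aa <- ceiling(cpos / 3)
  s <- (aa - 1) * 3 + 1
  wtCodon <- substr(cds, s, s + 2)
  mutCodon <- wtCodon
  substr(mutCodon, cpos - s + 1, cpos - s + 1) <- alt
  code <- Biostrings::GENETIC_CODE
  wtAa <- unname(code[[wtCodon]])
  mutAa <- unname(code[[mutCodon]])
  if (wtAa == mutAa) return(NA_character_)
  sprintf("p.%s%d%s", wtAa, aa, if (mutAa == "*") "X" else mutAa)
}

## independent text scan of a VCF: data lines plus extra ALT alleles
oracleVcfAlleleCount <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  total <- 0L
  for (ln in body) {
    altField <- strsplit(ln, "\t", fixed = TRUE)[[1]][5]
    total <- total + length(strsplit(altField, ",", fixed = TRUE)[[1]])
  }
  total
}
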