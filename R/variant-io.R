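#' Read a per-sample VCF into a variant table
#'
#' Parses a VCF 4.x file (via [VariantAnnotation::readVcf]) into the
#' package's variant table: one row per ALT allele per record, with
#' multi-allelic records decomposed. Depth is taken from INFO/DP (then
#' FORMAT/DP), missing depth becomes 0. Gene, consequence class and
#' dbSNP id come from the custom INFO tags GENE, CSQCLS and RSID (the ID
#' column is also honoured when it looks like an rs id). Unknown CSQCLS
#' values map to "other" with a warning.
#'
#' @param path VCF file.
#' @param sampleId sample id to stamp on rows; defaults to the VCF's
#'   sample column name (or the file stem for site-only VCFs).
#' @return data.frame with columns sample_id, chrom, pos, ref, alt,
#'   depth, genotype, gene_id, consequence, dbsnp_id.
#' @export
readVariantVcf <- function(path, sampleId = NULL) {
  if (!file.exists(path)) stop("no such VCF: ", path, call. = FALSE)
  preflightVcf(path)
  vcf <- VariantAnnotation::readVcf(path, genome = "synthetic")
  rr <- SummarizedExperiment::rowRanges(vcf)
  n <- length(rr)
  samples <- colnames(vcf)
  if (is.null(sampleId))
    sampleId <- if (length(samples)) samples[1] else
      sub("\\.vcf(\\.gz)?$", "", basename(path))
  if (n == 0L) return(emptyVariantTable(sampleId))

  altList <- VariantAnnotation::alt(vcf)
  nAlt <- S4Vectors::elementNROWS(altList)
  rowIdx <- rep.int(seq_len(n), nAlt)
  altIdx <- sequence(nAlt)

  info <- VariantAnnotation::info(vcf)
  dp <- if ("DP" %in% names(info)) info$DP else rep(NA_integer_, n)
  if (length(samples) && "DP" %in% rownames(VariantAnnotation::geno(VariantAnnotation::header(vcf)))) {
    gdp <- VariantAnnotation::geno(vcf)$DP[, 1]
    dp <- ifelse(is.na(dp), gdp, dp)
  }
  dp[is.na(dp)] <- 0L
  gene <- infoChar(info, "GENE", n)
  csq <- infoChar(info, "CSQCLS", n)
  rsid <- infoChar(info, "RSID", n)
  ids <- names(rr)
  idRs <- ifelse(grepl("^rs[0-9]+$", ids), ids, NA_character_)
  rsid <- ifelse(is.na(rsid), idRs, rsid)

  unknown <- !is.na(csq) & !(csq %in% CONSEQUENCE_CLASSES)
  if (any(unknown)) {
    warning(sprintf("%d record(s) with unknown CSQCLS value(s) (%s) mapped to 'other'",
                    sum(unknown), paste(unique(csq[unknown]), collapse = ",")))
    csq[unknown] <- "other"
  }

  gt <- if (length(samples) && "GT" %in% rownames(VariantAnnotation::geno(VariantAnnotation::header(vcf))))
    VariantAnnotation::geno(vcf)$GT[, 1] else rep(NA_character_, n)
  genotype <- mapply(gtForAlt, gt[rowIdx], altIdx, USE.NAMES = FALSE)

  df <- data.frame(
    sample_id = sampleId,
    chrom = as.character(GenomeInfoDb::seqnames(rr))[rowIdx],
    pos = BiocGenerics::start(rr)[rowIdx],
    ref = as.character(VariantAnnotation::ref(vcf))[rowIdx],
    alt = as.character(unlist(altList)),
    depth = as.integer(dp[rowIdx]),
    genotype = genotype,
    gene_id = gene[rowIdx],
    consequence = csq[rowIdx],
    dbsnp_id = rsid[rowIdx],
    stringsAsFactors = FALSE
  )
  validateVariantTable(df)
  df
}

## cheap structural scan so malformed lines are reported by number
preflightVcf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#"))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- body[nf < 8L]
  if (length(bad))
    stop(sprintf("malformed VCF line %d in %s (fewer than 8 fields)",
                 bad[1], basename(path)), call. = FALSE)
  invisible(TRUE)
}

infoChar <- function(info, tag, n) {
  if (!tag %in% names(info)) return(rep(NA_character_, n))
  v <- info[[tag]]
  if (is(v, "CharacterList") || is.list(v))
    v <- vapply(v, function(x) if (length(x)) as.character(x[1]) else NA_character_,
                character(1))
  as.character(v)
}

gtForAlt <- function(gt, altIdx) {
  if (is.na(gt) || gt %in% c("./.", ".", ".|.")) return("missing")
  alleles <- suppressWarnings(as.integer(strsplit(gt, "[/|]")[[1]]))
  if (anyNA(alleles)) return("missing")
  k <- sum(alleles == altIdx)
  if (k >= 2L) "hom_alt" else if (k == 1L) "het" else "hom_ref"
}

emptyVariantTable <- function(sampleId = character(0)) {
  data.frame(sample_id = character(0), chrom = character(0), pos = integer(0),
             ref = character(0), alt = character(0), depth = integer(0),
             genotype = character(0), gene_id = character(0),
             consequence = character(0), dbsnp_id = character(0),
             stringsAsFactors = FALSE)
}

validateVariantTable <- function(df) {
  assertDna(df$ref, "ref"); assertDna(df$alt, "alt")
  if (any(df$ref == df$alt)) stop("ref must differ from alt", call. = FALSE)
  if (any(df$depth < 0L)) stop("depth must be non-negative", call. = FALSE)
  if (any(df$pos < 1L)) stop("pos must be >= 1", call. = FALSE)
  if (anyDuplicated(variantKey(df)))
    stop("duplicate variant key within one sample's set", call. = FALSE)
  invisible(df)
}

#' Write a variant table to VCF
#'
#' Emits a deterministic VCF 4.2 file (fixed header, no date stamp) with
#' the package's INFO tags (DP, GENE, CSQCLS, RSID) and a single GT
#' sample column, sorted by position. Round-trips through
#' [readVariantVcf()] preserving variant keys and depths.
#'
#' @param variants a variant table (see [readVariantVcf()]).
#' @param path output file.
#' @param sampleName sample column name; default the table's sample_id.
#' @return invisibly, the path.
#' @export
writeVariantVcf <- function(variants, path, sampleName = NULL) {
  if (is.null(sampleName))
    sampleName <- if (nrow(variants)) variants$sample_id[1] else "SAMPLE"
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrSim>",
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Site read depth">',
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene id">',
    '##INFO=<ID=CSQCLS,Number=1,Type=String,Description="Consequence class">',
    '##INFO=<ID=RSID,Number=1,Type=String,Description="dbSNP id">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sampleName, sep = "\t"))
  v <- variants[order(variants$chrom, variants$pos, variants$ref, variants$alt), ,
                drop = FALSE]
  info <- paste0("DP=", v$depth,
                 ifelse(is.na(v$gene_id), "", paste0(";GENE=", v$gene_id)),
                 ifelse(is.na(v$consequence), "", paste0(";CSQCLS=", v$consequence)),
                 ifelse(is.na(v$dbsnp_id), "", paste0(";RSID=", v$dbsnp_id)))
  gt <- c(het = "0/1", hom_alt = "1/1", hom_ref = "0/0",
          missing = "./.")[v$genotype]
  rows <- paste(v$chrom, v$pos, ifelse(is.na(v$dbsnp_id), ".", v$dbsnp_id),
                v$ref, v$alt, ".", "PASS", info, "GT", gt, sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a cohort manifest
#'
#' TSV with columns sample_id, family_id, role (affected / mother /
#' father / control) and discovery_case (TRUE/FALSE). Sample ids must be
#' unique; every parent's family must contain an affected case.
#'
#' @param path manifest TSV.
#' @return data.frame.
#' @export
readCohortManifest <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "family_id", "role", "discovery_case")
  if (!all(need %in% names(m)))
    stop("manifest must have columns ", paste(need, collapse = ", "), call. = FALSE)
  validateManifest(m)
}

validateManifest <- function(m) {
  if (anyDuplicated(m$sample_id)) stop("duplicate sample ids in manifest", call. = FALSE)
  bad <- setdiff(m$role, c("affected", "mother", "father", "control"))
  if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "), call. = FALSE)
  m$discovery_case <- as.logical(m$discovery_case)
  affFam <- m$family_id[m$role == "affected"]
  parFam <- m$family_id[m$role %in% c("mother", "father")]
  if (!all(parFam %in% affFam))
    stop("every mother/father must share a family with an affected case", call. = FALSE)
  m
}

#' Read the genotype-phenotype table
#'
#' TSV with columns case_id, hgvs_c, protein_change, inheritance,
#' height_sd, ofc_sd, learning_disability, malignancy and (optionally)
#' ascertainment. Clinical cells may contain "nk" (not known): these
#' become NA and are never silently treated as zero. Signed values such
#' as "+2.2" parse as reals. Every hgvs_c must be parseable by
#' [parseHgvsC()].
#'
#' @param path phenotype TSV.
#' @return data.frame, one row per case.
#' @export
readPhenotypeTable <- function(path) {
  t1 <- read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
  need <- c("case_id", "hgvs_c", "inheritance", "height_sd", "ofc_sd",
            "learning_disability")
  if (!all(need %in% names(t1)))
    stop("phenotype table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(t1$case_id)) stop("duplicate case ids", call. = FALSE)
  parseSd <- function(x, col) {
    x <- trimws(as.character(x))
    out <- rep(NA_real_, length(x))
    known <- !(x %in% c("nk", "", "NA"))
    val <- suppressWarnings(as.numeric(x[known]))
    if (anyNA(val)) {
      bad <- t1$case_id[known][is.na(val)]
      stop(sprintf("unparseable %s value for case(s): %s", col,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    out[known] <- val
    out
  }
  t1$height_sd <- parseSd(t1$height_sd, "height_sd")
  t1$ofc_sd <- parseSd(t1$ofc_sd, "ofc_sd")
  t1$inheritance <- ifelse(t1$inheritance %in% c("nk", "", "NA"),
                           "unknown", t1$inheritance)
  bad <- setdiff(t1$inheritance, c("de_novo", "familial", "unknown"))
  if (length(bad)) stop("unknown inheritance value(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  t1$learning_disability <- ifelse(t1$learning_disability %in% c("nk", ""),
                                   "unknown", t1$learning_disability)
  if (!is.null(t1$protein_change))
    t1$protein_change[t1$protein_change %in% c("", "nk", "NA")] <- NA_character_
  if (!is.null(t1$malignancy))
    t1$malignancy[t1$malignancy %in% c("", "nk", "NA")] <- NA_character_
  for (h in t1$hgvs_c) parseHgvsC(h)  # grammar check; errors are informative
  t1
}

#' Path to the bundled 19-case EZH2 genotype-phenotype table
#'
#' @return file path inside the installed package.
#' @export
ezh2PhenotypeFile <- function() {
  system.file("extdata", "ezh2_weaver_phenotypes.tsv", package = "mendelseek",
              mustWork = TRUE)
}

#' Read a transcript model from its on-disk parts
#'
#' @param exonTablePath TSV with columns chrom, start, end, exon_number,
#'   strand (1-based inclusive genomic coordinates).
#' @param cdsFastaPath FASTA holding the coding sequence (length must be
#'   a multiple of 3).
#' @param domainTablePath optional TSV with columns name, aa_start, aa_end.
#' @param locusFastaPath optional FASTA of the forward-strand locus
#'   sequence; its header must carry `start=<genomic coordinate>`.
#' @return a [TranscriptModel-class].
#' @export
readTranscriptModel <- function(exonTablePath, cdsFastaPath,
                                domainTablePath = NULL, locusFastaPath = NULL) {
  ex <- read.delim(exonTablePath, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "exon_number", "strand")
  if (!all(need %in% names(ex)))
    stop("exon table must have columns ", paste(need, collapse = ", "), call. = FALSE)
  if (length(unique(ex$strand)) != 1L) stop("inconsistent exon strands", call. = FALSE)
  ex <- ex[order(ex$exon_number), , drop = FALSE]
  cds <- Biostrings::readDNAStringSet(cdsFastaPath)[[1]]
  dom <- NULL
  if (!is.null(domainTablePath)) {
    dom <- read.delim(domainTablePath, stringsAsFactors = FALSE)
    o <- order(dom$aa_start)
    if (nrow(dom) > 1L && any(dom$aa_end[o][-nrow(dom)] >= dom$aa_start[o][-1]))
      stop("overlapping domain rows", call. = FALSE)
  }
  locus <- NULL; locusStart <- NA_integer_
  if (!is.null(locusFastaPath)) {
    ls <- Biostrings::readDNAStringSet(locusFastaPath)
    locus <- ls[[1]]
    m <- regmatches(names(ls)[1], regexpr("start=[0-9]+", names(ls)[1]))
    if (!length(m)) stop("locus FASTA header must carry start=<pos>", call. = FALSE)
    locusStart <- as.integer(sub("start=", "", m))
  }
  ## cdsStartTx: distance from transcript start to the CDS, derived from
  ## total transcript length and any annotated UTR is not stored in the
  ## exon table; the table may carry an optional cds_start_tx attribute
  ## line, else the CDS is assumed to start where a `cds_start_tx`
  ## column of the first row says.
  cst <- if ("cds_start_tx" %in% names(ex)) ex$cds_start_tx[1] else 1L
  TranscriptModel(chrom = ex$chrom[1], exonStarts = ex$start, exonEnds = ex$end,
                  strand = ex$strand[1], cds = cds, cdsStartTx = cst,
                  locusSeq = locus, locusStart = locusStart, domains = dom)
}

#' Read a homolog multiple alignment
#'
#' FASTA of aligned protein sequences, human first, all rows of equal
#' length; gaps as "-".
#'
#' @param path alignment FASTA.
#' @return an [Biostrings::AAStringSet].
#' @export
readHomologAlignment <- function(path) {
  aln <- Biostrings::readAAStringSet(path)
  if (length(unique(Biostrings::width(aln))) != 1L)
    stop("alignment rows must have equal length", call. = FALSE)
  aln
}
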