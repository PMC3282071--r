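#' Build a simulation configuration
#'
#' See [SimulationConfig-class] for the meaning and defaults of every
#' knob. The defaults are the study conditions the simulator emulates:
#' 4 affected unrelated cases each carrying a different causal mutation
#' of one planted gene, 5,000 background variants per exome (40%
#' dbSNP-tagged, 10% below the 15-read depth floor, 20% of an excluded
#' class, independently drawn), a 1,000-gene background universe, 7 of 8
#' parental samples available, and a 115-sample control panel.
#'
#' @param seed integer seed; fully determines every output.
#' @param nAffected,nBackground,fracDbsnp,fracLowDepth,fracExcludedClass
#'   see [SimulationConfig-class].
#' @param nGenes,plantedGene,plantedHgvs,nControls,parentMissing,enforceUniqueCandidate
#'   see [SimulationConfig-class].
#' @return a validated [SimulationConfig-class].
#' @export
simConfig <- function(seed, nAffected = 4L, nBackground = 5000L,
                      fracDbsnp = 0.4, fracLowDepth = 0.1,
                      fracExcludedClass = 0.2, nGenes = 1000L,
                      plantedGene = "EZH2",
                      plantedHgvs = c("c.836A>G", "c.2050C>T", "c.2199C>G",
                                      "c.2204_2211dupAGGCTGAT"),
                      nControls = 115L,
                      parentMissing = paste0("CASE", nAffected, "_F"),
                      enforceUniqueCandidate = TRUE) {
  new("SimulationConfig", seed = as.integer(seed),
      nAffected = as.integer(nAffected), nBackground = as.integer(nBackground),
      fracDbsnp = fracDbsnp, fracLowDepth = fracLowDepth,
      fracExcludedClass = fracExcludedClass, nGenes = as.integer(nGenes),
      plantedGene = plantedGene,
      plantedHgvs = rep_len(plantedHgvs, nAffected),
      nControls = as.integer(nControls), parentMissing = parentMissing,
      enforceUniqueCandidate = enforceUniqueCandidate)
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0("SimulationConfig(seed=%d): %d affected x %d background ",
                     "variants, %d genes, planted '%s', %d controls\n"),
              object@seed, object@nAffected, object@nBackground, object@nGenes,
              object@plantedGene, object@nControls))
})

BG_POS_MIN <- 10000000L
BG_POS_RANGE <- 40000000L

drawBackground <- function(sampleId, cfg) {
  n <- cfg@nBackground
  pos <- BG_POS_MIN + sample.int(BG_POS_RANGE, n)
  ref <- sample(DNA_BASES, n, replace = TRUE)
  alt <- DNA_BASES[(match(ref, DNA_BASES) + sample.int(3L, n, replace = TRUE) - 1L) %% 4L + 1L]
  isLow <- runif(n) < cfg@fracLowDepth
  depth <- ifelse(isLow, sample(0:14, n, replace = TRUE),
                  15L + rnbinom(n, size = 5, mu = 45))
  isDb <- runif(n) < cfg@fracDbsnp
  dbsnp <- ifelse(isDb, sprintf("rs%08d", sample.int(99999999L, n, replace = TRUE)),
                  NA_character_)
  isExc <- runif(n) < cfg@fracExcludedClass
  cls <- character(n)
  cls[isExc] <- sample(c("intronic", "synonymous"), sum(isExc), replace = TRUE)
  cls[!isExc] <- sample(c("missense", "other", "inframe_indel", "splice_region",
                          "nonsense", "frameshift"), sum(!isExc), replace = TRUE,
                        prob = c(.5, .2, .1, .1, .05, .05))
  data.frame(sample_id = sampleId, chrom = FIXTURE_CHROM, pos = pos,
             ref = ref, alt = alt, depth = as.integer(depth),
             genotype = sample(c("het", "hom_alt"), n, replace = TRUE,
                               prob = c(.9, .1)),
             gene_id = sample(sprintf("BG%04d", seq_len(cfg@nGenes)), n,
                              replace = TRUE),
             consequence = cls, dbsnp_id = dbsnp, stringsAsFactors = FALSE)
}

## genes with >= 1 variant surviving the default discovery predicates
survivingGenes <- function(df) {
  keep <- df$depth >= 15L &
    !(df$consequence %in% c("intronic", "synonymous")) &
    is.na(df$dbsnp_id)
  unique(df$gene_id[keep])
}

#' Simulate a discovery exome cohort with a planted causal gene
#'
#' Each affected case receives independent background variants plus
#' exactly one planted, filter-clean variant (depth >= 15, non-excluded
#' class, no dbSNP tag) of the planted gene, realising one of the
#' configured HGVS mutations through the transcript fixture's
#' coordinates. Parents carry a random half of their child's background
#' plus private variants — never the planted variant. By default the
#' generator enforces (by resampling gene assignments) that no
#' background gene survives filtering in every case, so the candidate
#' list is exactly the planted gene; `enforceUniqueCandidate = FALSE`
#' gives honest stochastic backgrounds. Fully deterministic under the
#' config seed, including byte-identical VCFs.
#'
#' @param config a [simConfig()].
#' @param model the transcript fixture model (defaults to
#'   [buildTranscriptFixture()]'s).
#' @param dir optional directory: writes `<sample>.vcf` per sample plus
#'   manifest.tsv, truth.tsv and parent_depths.tsv.
#' @return list: `variants` (named list of per-sample tables),
#'   `manifest`, `truth` (planted-variant table), `parentDepths`.
#' @export
simulateCohort <- function(config, model = NULL, dir = NULL) {
  if (is.null(model)) model <- buildTranscriptFixture()$model
  out <- withFixedSeed(config@seed, function() {
    nA <- config@nAffected
    affectedIds <- sprintf("CASE%d", seq_len(nA))
    variants <- list()
    truthRows <- list()
    for (i in seq_len(nA)) {
      sid <- affectedIds[i]
      bg <- drawBackground(sid, config)
      edit <- parseHgvsC(config@plantedHgvs[i])
      rep_ <- hgvsToVcf(edit, model)
      cls <- classifyEdit(edit, model)@consequenceClass
      planted <- data.frame(sample_id = sid, chrom = model@chrom,
                            pos = rep_$pos, ref = rep_$ref, alt = rep_$alt,
                            depth = 15L + as.integer(rnbinom(1L, size = 5, mu = 45)),
                            genotype = "het", gene_id = config@plantedGene,
                            consequence = cls, dbsnp_id = NA_character_,
                            stringsAsFactors = FALSE)
      variants[[sid]] <- rbind(bg, planted)
      truthRows[[sid]] <- cbind(planted[, c("sample_id", "chrom", "pos",
                                            "ref", "alt")],
                                gene = config@plantedGene,
                                hgvs_c = config@plantedHgvs[i])
    }

    ## with a single affected case the candidate list is its whole gene
    ## set by definition; uniqueness enforcement only applies to >= 2
    if (config@enforceUniqueCandidate && nA > 1L) {
      if (config@nGenes < 50L)
        stop("nGenes too small to avoid full-intersection background collisions",
             call. = FALSE)
      genes <- sprintf("BG%04d", seq_len(config@nGenes))
      for (iter in seq_len(100L)) {
        sets <- lapply(variants[affectedIds], function(v)
          setdiff(survivingGenes(v), config@plantedGene))
        common <- Reduce(intersect, sets)
        if (!length(common)) break
        if (iter == 100L)
          stop("could not break background gene collisions; increase nGenes",
               call. = FALSE)
        v1 <- variants[[affectedIds[1]]]
        hit <- v1$gene_id %in% common & v1$gene_id != config@plantedGene
        v1$gene_id[hit] <- sample(genes, sum(hit), replace = TRUE)
        variants[[affectedIds[1]]] <- v1
      }
    }

    manifestRows <- list()
    parentDepthRows <- list()
    for (i in seq_len(nA)) {
      sid <- affectedIds[i]
      fam <- sprintf("F%d", i)
      manifestRows[[sid]] <- data.frame(sample_id = sid, family_id = fam,
                                        role = "affected", discovery_case = TRUE,
                                        stringsAsFactors = FALSE)
      for (role in c("mother", "father")) {
        pid <- sprintf("%s_%s", sid, if (role == "mother") "M" else "F")
        if (pid %in% config@parentMissing) next
        child <- variants[[sid]]
        childBg <- child[child$gene_id != config@plantedGene |
                           is.na(child$gene_id), , drop = FALSE]
        inherit <- childBg[runif(nrow(childBg)) < 0.5, , drop = FALSE]
        if (nrow(inherit)) {
          inherit$sample_id <- pid
          inherit$depth <- 15L + as.integer(rnbinom(nrow(inherit), size = 5, mu = 45))
        }
        priv <- drawBackground(pid, config)
        priv <- priv[seq_len(min(1000L, nrow(priv))), , drop = FALSE]
        pv <- rbind(inherit, priv)
        pv <- pv[!duplicated(variantKey(pv)), , drop = FALSE]
        variants[[pid]] <- pv
        manifestRows[[pid]] <- data.frame(sample_id = pid, family_id = fam,
                                          role = role, discovery_case = FALSE,
                                          stringsAsFactors = FALSE)
        tr <- truthRows[[sid]]
        ## ample parental coverage at the confirmed site so absence calls
        ## are decisive; availability, not depth, drives "unresolved"
        parentDepthRows[[pid]] <- data.frame(sample_id = pid, chrom = tr$chrom,
                                             pos = tr$pos,
                                             depth = 20L + as.integer(
                                               rnbinom(1L, size = 5, mu = 40)),
                                             stringsAsFactors = FALSE)
      }
    }
    list(variants = variants,
         manifest = do.call(rbind, unname(manifestRows)),
         truth = do.call(rbind, unname(truthRows)),
         parentDepths = do.call(rbind, unname(parentDepthRows)))
  })
  rownames(out$truth) <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (sid in names(out$variants))
      writeVariantVcf(out$variants[[sid]], file.path(dir, paste0(sid, ".vcf")), sid)
    write.table(out$manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(out$truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(out$parentDepths, file.path(dir, "parent_depths.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  out
}

#' Simulate a population control panel
#'
#' Controls carry variants only in the planted gene's locus, all either
#' dbSNP-tagged or of an excluded class — never a planted pathogenic
#' variant key, which is asserted against the truth table.
#'
#' @param config a [simConfig()].
#' @param model the transcript fixture model.
#' @param truth truth table from [simulateCohort()] (used to guarantee
#'   zero pathogenic keys); NULL derives it from `config`.
#' @param dir optional output directory for per-control VCFs.
#' @param variantsPerControl variants drawn per control (default 30).
#' @return named list of per-control variant tables.
#' @export
simulateControls <- function(config, model = NULL, truth = NULL, dir = NULL,
                             variantsPerControl = 30L) {
  if (is.null(model)) model <- buildTranscriptFixture()$model
  if (is.null(truth)) {
    truthKeys <- withFixedSeed(config@seed, function() {
      vapply(config@plantedHgvs, function(h) {
        r <- hgvsToVcf(parseHgvsC(h), model)
        variantKey(model@chrom, r$pos, r$ref, r$alt)
      }, character(1))
    })
  } else truthKeys <- variantKey(truth)
  locusEnd <- model@locusStart + length(model@locusSeq) - 1L
  out <- withFixedSeed(config@seed + 77003L, function() {
    ctrls <- list()
    for (j in seq_len(config@nControls)) {
      cid <- sprintf("CTRL%03d", j)
      pos <- model@locusStart +
        sample.int(length(model@locusSeq), variantsPerControl) - 1L
      ref <- locusBase(model, pos)
      alt <- DNA_BASES[(match(ref, DNA_BASES) +
                        sample.int(3L, variantsPerControl, replace = TRUE) - 1L) %% 4L + 1L]
      tagged <- runif(variantsPerControl) < 0.5
      cls <- ifelse(tagged,
                    sample(c("missense", "synonymous", "intronic", "other"),
                           variantsPerControl, replace = TRUE),
                    sample(c("intronic", "synonymous"), variantsPerControl,
                           replace = TRUE))
      dbsnp <- ifelse(tagged,
                      sprintf("rs%08d", sample.int(99999999L, variantsPerControl,
                                                   replace = TRUE)),
                      NA_character_)
      df <- data.frame(sample_id = cid, chrom = model@chrom, pos = pos,
                       ref = ref, alt = alt,
                       depth = 15L + as.integer(rnbinom(variantsPerControl,
                                                        size = 5, mu = 45)),
                       genotype = "het", gene_id = config@plantedGene,
                       consequence = cls, dbsnp_id = dbsnp,
                       stringsAsFactors = FALSE)
      ## never emit a planted pathogenic key
      clash <- variantKey(df) %in% truthKeys
      if (any(clash)) {
        df$alt[clash] <- DNA_BASES[(match(df$alt[clash], DNA_BASES)) %% 4L + 1L]
        df <- df[!(variantKey(df) %in% truthKeys) & df$ref != df$alt, , drop = FALSE]
      }
      df <- df[!duplicated(variantKey(df)), , drop = FALSE]
      ctrls[[cid]] <- df
    }
    ctrls
  })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (cid in names(out))
      writeVariantVcf(out[[cid]], file.path(dir, paste0(cid, ".vcf")), cid)
  }
  out
}

#' Simulate a homolog protein alignment
#'
#' Builds a gap-free multiple alignment of the fixture protein (human
#' first) in which each homolog matches the human residue independently
#' with probability `identity` per column; listed positions are forced
#' fully conserved (the fixture's mutated residues, mirroring missense
#' mutations targeting conserved residues).
#'
#' @param model transcript fixture model (protein source).
#' @param nHomologs homolog rows, default 5 (6 species total).
#' @param identity per-column per-homolog identity probability.
#' @param seed RNG seed.
#' @param conservedPositions residue numbers forced identical in all rows.
#' @return an [Biostrings::AAStringSet], human row first.
#' @export
simulateHomologAlignment <- function(model, nHomologs = 5L, identity = 0.8,
                                     seed = 1L, conservedPositions = integer(0)) {
  prot <- sub("\\*$", "", translateCds(model))
  aas <- strsplit(prot, "")[[1]]
  alphabet <- setdiff(unique(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]), NULL)
  rows <- withFixedSeed(seed, function() {
    lapply(seq_len(nHomologs), function(s) {
      same <- runif(length(aas)) < identity
      same[conservedPositions] <- TRUE
      vapply(seq_along(aas), function(i) {
        if (same[i]) aas[i]
        else sample(setdiff(alphabet, aas[i]), 1L)
      }, character(1))
    })
  })
  seqs <- c(prot, vapply(rows, paste, character(1), collapse = ""))
  aln <- Biostrings::AAStringSet(seqs)
  names(aln) <- c("human", sprintf("homolog%d", seq_len(nHomologs)))
  aln
}
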