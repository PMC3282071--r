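test_that("a biallelic SNP record becomes one het VariantCall with its depth", {
  p <- writeTestVcf(tempfile(fileext = ".vcf"),
                    "chrSim\t1000\t.\tA\tG\t.\tPASS\tDP=20;GENE=BG0001;CSQCLS=missense\tGT\t0/1")
  v <- readVariantVcf(p)
  expect_equal(nrow(v), 1L)
  expect_equal(v$depth, 20L)
  expect_equal(v$genotype, "het")
  expect_equal(v$gene_id, "BG0001")
  expect_equal(v$consequence, "missense")
  expect_true(is.na(v$dbsnp_id))
})

test_that("multi-allelic records decompose into one call per ALT allele", {
  p <- writeTestVcf(tempfile(fileext = ".vcf"),
                    "chrSim\t1000\t.\tA\tT,G\t.\tPASS\tDP=30\tGT\t1/2")
  v <- readVariantVcf(p)
  expect_equal(nrow(v), 2L)
  expect_equal(v$chrom, rep("chrSim", 2))
  expect_equal(v$pos, rep(1000L, 2))
  expect_equal(v$ref, rep("A", 2))
  expect_setequal(v$alt, c("T", "G"))
  expect_equal(v$genotype, rep("het", 2))  # 1/2: one copy of each alt
})

test_that("missing depth becomes 0 and unknown consequence tags map to 'other'", {
  p <- writeTestVcf(tempfile(fileext = ".vcf"),
                    "chrSim\t1000\t.\tA\tG\t.\tPASS\tCSQCLS=exotic\tGT\t1/1")
  expect_warning(v <- readVariantVcf(p), "other")
  expect_equal(v$depth, 0L)
  expect_equal(v$consequence, "other")
  expect_equal(v$genotype, "hom_alt")
})

test_that("malformed VCF lines raise an error naming the line number", {
  p <- writeTestVcf(tempfile(fileext = ".vcf"),
                    c("chrSim\t1000\t.\tA\tG\t.\tPASS\tDP=20\tGT\t0/1",
                      "only three\tfields\there"))
  expect_error(readVariantVcf(p), "line 10")
})

test_that("dbSNP ids are picked up from both the RSID tag and the ID column", {
  p <- writeTestVcf(tempfile(fileext = ".vcf"),
                    c("chrSim\t1000\trs123\tA\tG\t.\tPASS\tDP=20\tGT\t0/1",
                      "chrSim\t2000\t.\tC\tT\t.\tPASS\tDP=20;RSID=rs456\tGT\t0/1"))
  v <- readVariantVcf(p)
  expect_setequal(v$dbsnp_id, c("rs123", "rs456"))
})

test_that("a generated exome yields one call per record plus extra ALT alleles", {
  d <- withr::local_tempdir()
  sim <- simulateCohort(simConfig(seed = 1), model = fixtureModel(), dir = d)
  p <- file.path(d, "CASE1.vcf")
  v <- readVariantVcf(p)
  ## independent text scan of the file
  expect_equal(nrow(v), oracleVcfAlleleCount(p))
  expect_equal(nrow(v), 5001L)  # 5000 background + 1 planted, all biallelic
})

test_that("writing and re-reading a variant set preserves keys, depths and annotations", {
  sim <- simulateCohort(simConfig(seed = 3, nBackground = 300L),
                        model = fixtureModel())
  for (s in c("CASE1", "CASE2")) {
    p <- tempfile(fileext = ".vcf")
    writeVariantVcf(sim$variants[[s]], p)
    back <- readVariantVcf(p)
    a <- back[order(variantKey(back)), ]
    b <- sim$variants[[s]][order(variantKey(sim$variants[[s]])), ]
    expect_setequal(variantKey(a), variantKey(b))
    expect_equal(a$depth, b$depth)
    expect_equal(a$genotype, b$genotype)
    expect_equal(a$gene_id, b$gene_id)
    expect_equal(a$consequence, b$consequence)
    expect_equal(a$dbsnp_id, b$dbsnp_id)
  }
})

test_that("the bundled 19-case table parses with signed SDs and nk handling", {
  t1 <- phenotypeTable()
  expect_equal(nrow(t1), 19L)
  ## row count equals the number of data lines in the TSV
  expect_equal(nrow(t1), length(readLines(ezh2PhenotypeFile())) - 1L)
  r1 <- t1[t1$case_id == 1, ]
  expect_equal(r1$hgvs_c, "c.401T>C")
  expect_equal(r1$height_sd, 2.2)
  expect_equal(r1$inheritance, "de_novo")
  ## "nk" cells become NA, the record is still returned
  r9 <- t1[t1$case_id == 9, ]
  expect_true(is.na(r9$ofc_sd))
  expect_equal(r9$height_sd, 2.9)
  expect_equal(sum(t1$inheritance == "unknown"), 6L)
})

test_that("unparseable SD values raise a row-level error naming the case", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("case_id\thgvs_c\tinheritance\theight_sd\tofc_sd\tlearning_disability",
               "X7\tc.401T>C\tde_novo\ttall\t+1\tno"), p)
  expect_error(readPhenotypeTable(p), "X7")
})

test_that("transcript models round-trip through their on-disk formats", {
  d <- withr::local_tempdir()
  fx <- buildTranscriptFixture(dir = d)
  m <- readTranscriptModel(file.path(d, "exons.tsv"), file.path(d, "cds.fa"),
                           file.path(d, "domains.tsv"), file.path(d, "locus.fa"))
  expect_equal(exonCount(m), 20L)
  expect_equal(lastExonNumber(m), 20L)
  expect_equal(as.character(cdsSeq(m)), as.character(cdsSeq(fx$model)))
  expect_equal(m@exonStarts, fx$model@exonStarts)
  expect_equal(domainTable(m)$name, c("SET", "post-SET"))
})

test_that("genomic<->coding mapping is bijective over every CDS base", {
  m <- fixtureModel()
  cpos <- seq_len(cdsLength(m))
  g <- codingToGenomic(m, cpos)
  expect_equal(genomicToCoding(m, g), cpos)
  expect_equal(anyDuplicated(g), 0L)
})

test_that("a single-exon toy gene maps coding position to offset + start - 1", {
  m <- singleExonModel()
  expect_equal(codingToGenomic(m, 1L), 501L)
  expect_equal(codingToGenomic(m, 12L), 512L)
  expect_equal(genomicToCoding(m, 505L), 5L)
})

test_that("minus-strand coding coordinates increase as genomic decrease", {
  m <- minusToyModel()
  g <- codingToGenomic(m, 1:12)
  expect_equal(g[1:6], 906:901)   # exon 1, descending
  expect_equal(g[7:12], 106:101)  # exon 2
  expect_true(all(diff(g) < 0))
  expect_equal(genomicToCoding(m, g), 1:12)
})

test_that("invalid transcript structures are rejected at construction", {
  expect_error(TranscriptModel("c", c(1L, 50L), c(60L, 80L), "+",
                               "ATGTAA", 1L), "non-overlapping")
  expect_error(TranscriptModel("c", 1L, 10L, "+", "ATGTA", 1L), "divisible by 3")
})

test_that("manifests validate roles and family structure", {
  m <- data.frame(sample_id = c("A", "A_M"), family_id = c("F1", "F1"),
                  role = c("affected", "mother"), discovery_case = c(TRUE, FALSE))
  expect_silent(readOk <- mendelseek:::validateManifest(m))
  bad <- m; bad$family_id[2] <- "F9"
  expect_error(mendelseek:::validateManifest(bad), "family")
  dup <- rbind(m, m[1, ])
  expect_error(mendelseek:::validateManifest(dup), "duplicate")
})
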