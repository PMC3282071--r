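mkVariants <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    defaults <- list(sample_id = "S1", chrom = "chrSim", pos = 100L, ref = "A",
                     alt = "G", depth = 30L, genotype = "het",
                     gene_id = NA_character_, consequence = NA_character_,
                     dbsnp_id = NA_character_)
    defaults[names(r)] <- r
    as.data.frame(defaults, stringsAsFactors = FALSE)
  }))
}

test_that("the 15-read depth boundary is inclusive: 14 fails, 15 survives", {
  v <- mkVariants(list(pos = 1L, depth = 14L), list(pos = 2L, depth = 15L))
  res <- applyFilters(v, filterConfig())
  expect_equal(res$surviving$pos, 2L)
  expect_equal(res$report$filter,
               c("depth", "class", "dbSNP", "pseudogene", "panel"))
  expect_equal(res$report$n_removed, c(1L, 0L, 0L, 0L, 0L))
  expect_true(all(res$report$n_after == res$report$n_before - res$report$n_removed))
})

test_that("each exclusion rule removes exactly its targets", {
  v <- mkVariants(
    list(pos = 1L),                                              # clean
    list(pos = 2L, consequence = "intronic"),
    list(pos = 3L, consequence = "synonymous"),
    list(pos = 4L, dbsnp_id = "rs1"),                            # any dbSNP record
    list(pos = 5L, gene_id = "PSEUDO1"),
    list(pos = 6L))                                              # panel hit below
  cfg <- filterConfig(pseudogeneGenes = "PSEUDO1",
                      panelOfNormals = "chrSim:6:A:G")
  res <- applyFilters(v, cfg)
  expect_equal(res$surviving$pos, 1L)
  expect_equal(res$report$n_removed, c(0L, 2L, 1L, 1L, 1L))
  ## absent consequence class is never excluded by class
  expect_true(1L %in% res$surviving$pos)
})

test_that("knownSnpIds excludes by rs id or by variant key when RSID tags are absent", {
  v <- mkVariants(list(pos = 1L, dbsnp_id = NA), list(pos = 2L, dbsnp_id = NA))
  cfg <- filterConfig(knownSnpIds = "chrSim:2:A:G")
  expect_equal(applyFilters(v, cfg)$surviving$pos, 1L)
})

test_that("empty input gives empty output and an all-zero report", {
  res <- applyFilters(mkVariants(list(pos = 1L))[0, ], filterConfig())
  expect_equal(nrow(res$surviving), 0L)
  expect_true(all(res$report$n_before == 0L))
})

test_that("filters are order-independent, monotone and idempotent", {
  sim <- simulateCohort(simConfig(seed = 42, nBackground = 800L),
                        model = fixtureModel())
  v <- sim$variants$CASE1
  cfg <- filterConfig()
  surv <- applyFilters(v, cfg)$surviving
  ## order-independence: surviving set equals the plain AND of predicates
  preds <- mendelseek:::filterPredicates(v, cfg)
  expect_setequal(variantKey(surv), variantKey(v[Reduce(`&`, preds), ]))
  ## monotonicity in depth
  survLow <- applyFilters(v, filterConfig(minDepth = 5L))$surviving
  expect_true(all(variantKey(surv) %in% variantKey(survLow)))
  ## adding exclusions never grows the set
  survPon <- applyFilters(v, filterConfig(panelOfNormals = variantKey(v)[1:50]))$surviving
  expect_true(all(variantKey(survPon) %in% variantKey(surv)))
  ## idempotence
  again <- applyFilters(surv, cfg)$surviving
  expect_equal(again, surv)
})

test_that("surviving sets match an independent brute-force predicate scan", {
  sim <- simulateCohort(simConfig(seed = 7, nBackground = 1000L),
                        model = fixtureModel())
  v <- sim$variants$CASE1
  res <- applyFilters(v, filterConfig())
  expect_setequal(variantKey(res$surviving),
                  variantKey(v[oracleFilterKeep(v), ]))
  ## the planted clean variant survives
  expect_true(variantKey(sim$truth)[1] %in% variantKey(res$surviving))
})

test_that("attrition tables aggregate per-sample reports consistently", {
  empty <- applyFilters(mkVariants(list(pos = 1L))[0, ], filterConfig())$report
  txt <- attritionTable(list(S0 = empty))
  expect_match(txt, "TOTAL\t0\t0\t0")

  v <- mkVariants(list(pos = 1L, depth = 10L), list(pos = 2L))
  r <- applyFilters(v, filterConfig())$report
  txt2 <- attritionTable(list(A = r, B = r))
  linesA <- grep("^A\t", strsplit(txt2, "\n")[[1]], value = TRUE)
  linesB <- grep("^B\t", strsplit(txt2, "\n")[[1]], value = TRUE)
  expect_equal(sub("^A", "", linesA), sub("^B", "", linesB))

  r2 <- r[c(2, 1, 3, 4, 5), ]
  expect_error(attritionTable(list(A = r, B = r2)), "order")
})
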