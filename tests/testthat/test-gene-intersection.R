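mkCohort <- function(geneSets) {
  i <- 0L
  lapply(geneSets, function(gs) {
    i <<- i + 1L
    n <- length(gs)
    data.frame(sample_id = sprintf("S%d", i), chrom = "chrSim",
               pos = seq_len(n) + i * 1000L, ref = "A", alt = "G",
               depth = 30L, genotype = "het", gene_id = gs,
               consequence = "missense", dbsnp_id = NA_character_,
               stringsAsFactors = FALSE)
  })
}

mkManifest <- function(n) {
  data.frame(sample_id = sprintf("S%d", seq_len(n)),
             family_id = sprintf("F%d", seq_len(n)),
             role = "affected", discovery_case = TRUE, stringsAsFactors = FALSE)
}

test_that("only genes hit in every affected case become candidates", {
  cohort <- setNames(mkCohort(list(c("G1", "G2"), c("G1", "G3"), c("G1", "G4"))),
                     c("S1", "S2", "S3"))
  ghm <- intersectGenes(cohort, mkManifest(3))
  expect_equal(candidateGenes(ghm), "G1")
  expect_true(all(hitMatrix(ghm)["G1", ]))
  ## matrix mirrors the variant index
  expect_equal(hitMatrix(ghm)["G2", "S2"], FALSE)
  expect_length(ghm@variantIndex[["G2"]][["S2"]], 0L)
})

test_that("one affected sample yields all of its hit genes; disjoint sets yield none", {
  one <- setNames(mkCohort(list(c("G2", "G1"))), "S1")
  expect_equal(candidateGenes(intersectGenes(one, mkManifest(1))), c("G1", "G2"))
  two <- setNames(mkCohort(list(c("G1"), c("G2"))), c("S1", "S2"))
  expect_equal(candidateGenes(intersectGenes(two, mkManifest(2))), character(0))
  expect_error(intersectGenes(one, mkManifest(1)[0, ]), "zero affected")
})

test_that("the planted gene is the unique candidate in a simulated cohort", {
  sim <- simulateCohort(simConfig(seed = 11), model = fixtureModel())
  aff <- sim$manifest$sample_id[sim$manifest$role == "affected"]
  filtered <- lapply(sim$variants[aff], function(v) applyFilters(v)$surviving)
  ghm <- suppressMessages(intersectGenes(filtered, sim$manifest))
  expect_equal(candidateGenes(ghm), "EZH2")
  ## agrees with a brute-force set intersection over the same tables
  expect_equal(candidateGenes(ghm), oracleIntersect(filtered))
})

test_that("adding an affected sample can only shrink the candidate list", {
  sim <- simulateCohort(simConfig(seed = 23, nBackground = 1500L,
                                  enforceUniqueCandidate = FALSE),
                        model = fixtureModel())
  aff <- sim$manifest$sample_id[sim$manifest$role == "affected"]
  filtered <- lapply(sim$variants[aff], function(v) applyFilters(v)$surviving)
  man <- function(ids) data.frame(sample_id = ids, family_id = ids,
                                  role = "affected", discovery_case = TRUE,
                                  stringsAsFactors = FALSE)
  c3 <- candidateGenes(suppressMessages(intersectGenes(filtered[1:3], man(aff[1:3]))))
  c4 <- candidateGenes(suppressMessages(intersectGenes(filtered, man(aff))))
  expect_true(all(c4 %in% c3))
})

test_that("de novo calls follow the parental-evidence rules", {
  child <- mkCohort(list("EZH2"))[[1]]
  key <- variantKey(child)
  depths <- data.frame(chrom = child$chrom, pos = child$pos, depth = 30L)
  absent <- list(variants = character(0), depths = depths)
  shallow <- list(variants = character(0),
                  depths = transform(depths, depth = 5L))
  carrier <- list(variants = key, depths = depths)

  expect_equal(confirmDeNovo(child, absent, absent)$verdict, "de_novo")
  expect_equal(confirmDeNovo(child, carrier, absent)$verdict, "inherited")
  expect_equal(confirmDeNovo(child, NULL, absent)$verdict, "unresolved")
  dn <- confirmDeNovo(child, shallow, absent)
  expect_equal(dn$verdict, "unresolved")
  expect_equal(dn$mother_evidence, "insufficient_depth")
})

test_that("de_novo is never returned when any parent datum is missing", {
  child <- mkCohort(list(c("G1", "G2", "G3")))[[1]]
  depths <- data.frame(chrom = child$chrom, pos = child$pos, depth = 40L)
  ok <- list(variants = character(0), depths = depths)
  for (parents in list(list(NULL, NULL), list(ok, NULL), list(NULL, ok))) {
    dn <- confirmDeNovo(child, parents[[1]], parents[[2]])
    expect_false(any(dn$verdict == "de_novo"))
  }
})

test_that("segregation requires carrier status to equal affected status", {
  fam <- c(P = TRUE, M = FALSE, C1 = TRUE, C2 = FALSE)
  expect_equal(segregationCheck(fam, fam), "co_segregates")
  expect_equal(segregationCheck(fam, c(P = TRUE, M = FALSE, C1 = TRUE, C2 = TRUE)),
               "does_not_segregate")
  ## vacuous edge case: all-negative family co-segregates
  none <- c(A = FALSE, B = FALSE)
  expect_equal(segregationCheck(none, none), "co_segregates")
  expect_error(segregationCheck(c(A = TRUE), c(A = TRUE)), "at least 2")
})
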