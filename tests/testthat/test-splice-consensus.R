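noopEdit <- function(m, cpos = 2199L) {
  ref <- substr(as.character(cdsSeq(m)), cpos, cpos)
  new("HgvsEdit", kind = "substitution", startPos = cpos, startOff = 0L,
      endPos = cpos, endOff = 0L, refBases = ref, insBases = ref,
      text = "no-op")
}

uniformScorer <- function(L = 17L, siteType = "acceptor") {
  pwm <- matrix(0, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  new("PwmScorer", name = "uniform", siteType = siteType, pwm = pwm,
      intronBases = if (siteType == "acceptor") L - 3L else L - 3L,
      exonBases = 3L)
}

test_that("percent change carries direction and exceeds the 20% trigger as stated", {
  expect_equal(pctChange(10, 7.9), -21)
  expect_equal(pctChange(10, 10), 0)
  expect_equal(pctChange(5, 6.5), 30)
  ## eps guard keeps a zero wildtype defined
  expect_true(is.finite(pctChange(0, 1)))
})

test_that("a uniform PWM scores every window zero", {
  sc <- uniformScorer()
  expect_equal(scoreSite(sc, paste(rep("A", 17), collapse = "")), 0)
  expect_equal(scoreSite(sc, paste(rep("G", 17), collapse = "")), 0)
})

test_that("a PWM trained on one repeated sequence maximises that sequence", {
  ## small window so every one of the 4^4 windows can be enumerated
  sc <- trainPwmScorer("solo", "donor", rep("GTAA", 30), intronBases = 2L,
                       exonBases = 2L, pseudocount = 0.5)
  all4 <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), 4)), 1, paste,
                collapse = "")
  scores <- vapply(all4, function(w) scoreSite(sc, w), numeric(1))
  expect_equal(names(which.max(scores)), "GTAA")
  expect_equal(max(scores), scoreSite(sc, "GTAA"))
})

test_that("a GT-trained donor PWM prefers GT over GC at +1,+2", {
  don <- builtinScorersCached()[[1]]@donor
  gt <- "CAGGTAAGT"; gc <- "CAGGCAAGT"
  expect_gt(scoreSite(don, gt), scoreSite(don, gc))
})

test_that("window-length and alphabet violations error", {
  sc <- uniformScorer()
  expect_error(scoreSite(sc, "ACGT"), "length")
  expect_error(scoreSite(sc, paste(rep("N", 17), collapse = "")), "non-ACGT")
  expect_error(trainPwmScorer("x", "acceptor", c("ACGT", "ACGTT"), 2L, 2L),
               "length")
})

test_that("the acceptor-tract deletion triggers wildtype loss and a disruptive consensus", {
  m <- fixtureModel()
  v <- assessSpliceVariant("c.2196-15_2196-2delTTCCTGTTGTTTCA", m,
                           scorers = builtinScorersCached())
  expect_true(v@triggered)
  expect_equal(v@mode, "wildtype_loss")
  expect_equal(v@siteType, "acceptor")
  expect_equal(spliceVerdict(v), "disruptive")
  expect_true(all(v@tier1$pct_change < -20))
  expect_equal(nrow(v@tier2), 3L)
})

test_that("a deep-exon substitution far from any site does not trigger", {
  v <- assessSpliceVariant("c.2044G>A", fixtureModel(),
                           scorers = builtinScorersCached())
  expect_false(v@triggered)
  expect_equal(spliceVerdict(v), "not_disruptive")
  expect_equal(nrow(v@tier2), 0L)
})

test_that("a no-op edit scores zero change everywhere and is not disruptive", {
  m <- fixtureModel()
  v <- assessSpliceVariant(noopEdit(m), m, scorers = builtinScorersCached())
  expect_equal(v@tier1$pct_change, c(0, 0))
  expect_equal(spliceVerdict(v), "not_disruptive")
})

test_that("threshold extremes behave as bounds", {
  m <- fixtureModel()
  del <- "c.2196-15_2196-2delTTCCTGTTGTTTCA"
  expect_equal(spliceVerdict(assessSpliceVariant(del, m,
                 scorers = builtinScorersCached(), threshold = Inf)),
               "not_disruptive")
  ## threshold 0: any concordant non-zero change triggers
  v0 <- assessSpliceVariant(del, m, scorers = builtinScorersCached(),
                            threshold = 0)
  expect_true(v0@triggered)
})

test_that("verdicts are invariant to confirmatory scorer order", {
  m <- fixtureModel()
  sc <- builtinScorersCached()
  v1 <- assessSpliceVariant("c.2196-15_2196-2delTTCCTGTTGTTTCA", m, sc)
  v2 <- assessSpliceVariant("c.2196-15_2196-2delTTCCTGTTGTTTCA", m,
                            sc[c(1, 2, 5, 4, 3)])
  expect_equal(spliceVerdict(v1), spliceVerdict(v2))
  expect_setequal(v1@tier2$pct_change, v2@tier2$pct_change)
})

test_that("five copies of one scorer make every trigger disruptive", {
  m <- fixtureModel()
  sc <- builtinScorersCached()
  clone5 <- rep(sc[1], 5)
  v <- assessSpliceVariant("c.2196-15_2196-2delTTCCTGTTGTTTCA", m, clone5)
  expect_true(v@triggered)
  expect_equal(spliceVerdict(v), "disruptive")
})

test_that("discordant primary directions do not trigger", {
  m <- fixtureModel()
  sc <- builtinScorersCached()
  flip <- sc[[2]]
  flip@acceptor@pwm <- -flip@acceptor@pwm   # inverted scale: same edit, opposite sign
  flip@donor@pwm <- -flip@donor@pwm
  v <- assessSpliceVariant("c.2196-15_2196-2delTTCCTGTTGTTTCA", m,
                           list(sc[[1]], flip, sc[[3]], sc[[4]], sc[[5]]))
  expect_false(v@triggered)
  expect_equal(spliceVerdict(v), "not_disruptive")
})

test_that("assessment demands a locus sequence and a nearby site", {
  noLocus <- TranscriptModel("chrToy", c(1L, 501L), c(100L, 600L), "+",
                             paste(c("ATG", rep("AAA", 64), "TAA"), collapse = ""),
                             1L)
  expect_error(assessSpliceVariant("c.50A>G", noLocus,
                                   scorers = builtinScorersCached()),
               "locus sequence")
})
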