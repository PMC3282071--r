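test_that("the HGVS grammar covers the mutation table's forms", {
  e <- parseHgvsC("c.2050C>T")
  expect_equal(e@kind, "substitution")
  expect_equal(c(e@startPos, e@startOff), c(2050L, 0L))
  expect_equal(e@refBases, "C"); expect_equal(e@insBases, "T")

  d <- parseHgvsC("c.2204_2211dupAGGCTGAT")
  expect_equal(d@kind, "duplication")
  expect_equal(c(d@startPos, d@endPos), c(2204L, 2211L))
  expect_equal(nchar(d@insBases), 8L)

  i <- parseHgvsC("c.2196-15_2196-2delTTCCTGTTGTTTCA")
  expect_equal(i@kind, "deletion")
  expect_equal(c(i@startPos, i@startOff), c(2196L, -15L))
  expect_equal(c(i@endPos, i@endOff), c(2196L, -2L))
  expect_equal(nchar(i@refBases), 14L)
})

test_that("unsupported or inconsistent HGVS raises explicit errors", {
  expect_error(parseHgvsC("c.100_101inv"), "unsupported HGVS")
  expect_error(parseHgvsC("p.R684C"), "unsupported HGVS")
  expect_error(parseHgvsC("c.10_12delAAAA"), "span")   # 4 bases over a 3-base span
})

test_that("substitutions classify by codon translation", {
  m <- fixtureModel()
  r <- classifyEdit("c.2050C>T", m)
  expect_equal(r@consequenceClass, "missense")
  expect_equal(r@proteinChange, "p.R684C")
  expect_equal(r@domainHit, "SET")
  expect_true(r@cpgSite)

  stop14 <- classifyEdit("c.2199C>G", m)
  expect_equal(stop14@consequenceClass, "nonsense")
  expect_equal(stop14@proteinChange, "p.Y733X")
  expect_true(stop14@inLastExon)
  expect_true(stop14@nmdEscape)

  ## a synonymous edit: codon 684 CGC -> CGT both code R
  syn <- classifyEdit("c.2052C>T", m)
  expect_equal(syn@consequenceClass, "synonymous")
  expect_true(is.na(syn@proteinChange))

  ## mismatched reference base is an error, never a silent call
  expect_error(classifyEdit("c.2050G>T", m), "does not match")
  expect_error(classifyEdit("c.9999A>T", m), "outside")
})

test_that("indels classify by net length: 3n in-frame, else frameshift", {
  m <- fixtureModel()
  dup3 <- classifyEdit("c.2230_2232dupATC", m)
  expect_equal(dup3@consequenceClass, "inframe_indel")
  expect_false(dup3@truncating)

  dup8 <- classifyEdit("c.2204_2211dupAGGCTGAT", m)
  expect_equal(dup8@consequenceClass, "frameshift")
  expect_true(dup8@truncating)
  expect_true(dup8@inLastExon && dup8@nmdEscape)
})

test_that("intronic edits split into splice_region and deep intronic", {
  m <- fixtureModel()
  del <- classifyEdit("c.2196-15_2196-2delTTCCTGTTGTTTCA", m)
  expect_equal(del@consequenceClass, "splice_region")
  expect_true(del@truncating)      # ablates the acceptor window
  expect_true(del@inLastExon)      # anchored on the last exon's boundary
  expect_true(del@nmdEscape)

  deep <- classifyEdit("c.2196-40A>G", m)
  expect_equal(deep@consequenceClass, "intronic")
  expect_false(deep@truncating)

  ## an in-window substitution is splice_region but not truncating
  sub <- classifyEdit("c.2196-3C>T", m)
  expect_equal(sub@consequenceClass, "splice_region")
  expect_false(sub@truncating)
})

test_that("every table mutation classifies, with exactly the three truncating calls", {
  t1 <- phenotypeTable()
  cls <- classifyTable(t1$hgvs_c, fixtureModel())
  expect_equal(nrow(cls), 19L)
  trunc <- unique(cls$hgvs_c[cls$truncating])
  expect_setequal(trunc, c("c.2199C>G", "c.2196-15_2196-2delTTCCTGTTGTTTCA",
                           "c.2204_2211dupAGGCTGAT"))
  expect_true(all(cls$in_last_exon[cls$truncating]))
  expect_true(all(cls$nmd_escape[cls$truncating]))
})

test_that("reported protein changes match an independent codon-table oracle", {
  t1 <- phenotypeTable()
  m <- fixtureModel()
  subs <- t1[grepl(">", t1$hgvs_c), ]
  expect_equal(nrow(subs), 16L)
  for (i in seq_len(nrow(subs))) {
    e <- parseHgvsC(subs$hgvs_c[i])
    expected <- oracleProteinChange(cdsSeq(m), e@startPos, e@insBases)
    got <- classifyEdit(e, m)@proteinChange
    expect_equal(got, expected, info = subs$hgvs_c[i])
    expect_equal(got, subs$protein_change[i], info = subs$hgvs_c[i])
  }
})

test_that("domain lookup honours inclusive bounds and rejects overlaps", {
  dom <- domainTable(fixtureModel())
  expect_equal(annotateDomain(682, dom), "SET")
  expect_equal(annotateDomain(727, dom), "SET")
  expect_equal(annotateDomain(728, dom), "post-SET")
  expect_equal(annotateDomain(745, dom), "post-SET")
  expect_true(is.na(annotateDomain(1, dom)))
  bad <- data.frame(name = c("A", "B"), aa_start = c(1, 5), aa_end = c(10, 20))
  expect_error(annotateDomain(7, bad), "overlapping")
})

test_that("CpG context sees both strands and is reverse-complement symmetric", {
  s <- "AACGTTGCAT"
  expect_true(cpgContext(s, 3, "C"))    # C followed by G
  expect_true(cpgContext(s, 4, "G"))    # G preceded by C (reverse-strand CpG)
  expect_false(cpgContext(s, 6, "T"))
  expect_false(cpgContext("AAC", 3, "C"))  # edge: no next base
  ## symmetry: C>T at p on s == G>A at the mirrored position on revcomp(s)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  for (p in which(strsplit(s, "")[[1]] == "C")) {
    q <- nchar(s) - p + 1
    expect_equal(cpgContext(s, p, "C"), cpgContext(rc, q, "G"), info = p)
  }
  ## the recurrent-mutation site sits in a CpG in the fixture
  m <- fixtureModel()
  expect_true(cpgContext(cdsSeq(m), 2050, "C"))
})

test_that("conservation is the homolog column identity fraction", {
  aln <- Biostrings::AAStringSet(c(human = "MKR", a = "MKR", b = "MKR",
                                   c = "MAR", d = "MAR", e = "M-R"))
  expect_equal(conservationScore(1, aln), 1.0)
  expect_equal(conservationScore(2, aln), 0.5)   # 2 of 4 non-gap homologs
  expect_equal(conservationScore(3, aln), 1.0)
  expect_error(conservationScore(9, aln), "beyond")
  ## invariant to reordering of non-human rows
  expect_equal(conservationScore(2, aln[c(1, 5, 3, 2, 4, 6)]),
               conservationScore(2, aln))
})

test_that("simulated alignments recover the generating identity", {
  m <- fixtureModel()
  aln <- simulateHomologAlignment(m, nHomologs = 5, identity = 0.8, seed = 3)
  scores <- vapply(1:200, conservationScore, numeric(1), alignment = aln)
  se <- sqrt(0.8 * 0.2 / (200 * 5))
  expect_lt(abs(mean(scores) - 0.8), 3 * se)
  ## forced-conserved positions score 1
  aln2 <- simulateHomologAlignment(m, seed = 4, identity = 0.5,
                                   conservedPositions = c(684L, 733L))
  expect_equal(conservationScore(684, aln2), 1.0)
  expect_equal(conservationScore(733, aln2), 1.0)
})

test_that("recurrence grouping finds the CpG hotspot", {
  rr <- recurrenceReport(phenotypeTable())
  expect_equal(rr$protein_change[1], "p.R684C")
  expect_equal(rr$n_cases[1], 4L)
  expect_equal(rr$n_de_novo[1], 2L)
  ## all-unique input and empty input edge cases
  uniq <- data.frame(hgvs_c = c("c.1A>G", "c.2A>G"),
                     protein_change = c("p.X1Y", "p.X2Y"),
                     inheritance = c("de_novo", "unknown"))
  expect_true(all(recurrenceReport(uniq)$n_cases == 1L))
  expect_equal(nrow(recurrenceReport(uniq[0, ])), 0L)
})
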