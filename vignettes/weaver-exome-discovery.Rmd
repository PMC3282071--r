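---
title: "Exome-intersection gene discovery: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exome-intersection gene discovery: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mendelseek)
```

# The problem and the procedure

Weaver syndrome is a dominant overgrowth condition; its cause was found
by a now-classic strategy for rare Mendelian disease: sequence the
exomes of a handful of unrelated affected individuals, discard variant
calls that are unlikely to be causal, and ask which gene still carries
a qualifying variant in *every* case. mendelseek implements that
strategy as a reusable pipeline, together with the mutation
interpretation and cohort statistics that turn a candidate gene into a
characterised disease gene.

The pipeline's stages, and the assumptions each makes:

1. **Filter cascade** (`applyFilters`). Five per-variant predicates:
   depth ≥ 15 reads; class not intronic/synonymous; not in dbSNP; not
   in a pseudogene; not in the panel of normals. The assumptions are a
   dominant model (causal variants are heterozygous and *absent* from
   population resources) and a fully penetrant, protein-altering
   mechanism. The predicates are pure, so filter order cannot change
   the result — a property the tests assert.
2. **Gene intersection** (`intersectGenes`). The candidate criterion is
   "≥ 1 surviving variant per affected case", not "the same variant":
   under a dominant de novo model unrelated cases carry *different*
   mutations of the same gene. Intersection is anti-monotone in cohort
   size: adding a case can only shrink the candidate list.
3. **De novo confirmation** (`confirmDeNovo`). Absence in a parent is
   only evidence when the parent's own coverage at the site reaches
   `minParentDepth` (default 15, reusing the discovery standard — the
   source analysis does not state a parental threshold). A missing
   parent gives "unresolved"; de novo is never declared from missing
   data.
4. **Consequence engine** (`classifyEdit`). HGVS c. edits are mapped
   through a `TranscriptModel`, the single choke-point for coordinate
   conversions (VCF and HGVS are 1-based; all internal interval
   arithmetic stays inside the class, preventing off-by-one drift).
5. **Splice consensus** (`assessSpliceVariant`). A two-tier procedure:
   two primary scorers must both move by more than 20% in a consistent
   direction to trigger three confirmatory scorers; only a unanimous
   directional panel is called disruptive.
6. **Phenotype statistics** (`summarizeCohort`). Counts over SD (z)
   scores with comparison operators matching the clinical wording: "at
   least +2 SD" uses ≥ (so exactly +2.0 qualifies), "greater than +4
   SD" uses strict >.

# Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `minDepth` | 15 | reads | the discovery depth floor; applied to site depth (DP), not per-allele depth, since callers report DP and the source rule is stated per site |
| `excludedClasses` | intronic, synonymous | — | protein-altering dominant model |
| `minParentDepth` | 15 | reads | absence evidence needs coverage; reuses the discovery floor |
| splice acceptor window | −12…−1 | nt | common annotation practice for the 3'ss (branch/pyrimidine tract + AG); configurable |
| splice donor window | +1…+6 | nt | the 5'ss consensus footprint |
| splice trigger threshold | 20 | % | the consensus procedure's stated trigger |
| `crypticRange` | ±25 | nt | local search for novel sites around an edit; ties broken leftmost |
| PWM pseudocount | 0.25–1.0 | counts/cell | varied across the five built-in scorers so they are not clones |

# Design choices where the design was open

**dbSNP exclusion is by presence.** Any rs id excludes a variant,
matching the blanket historical rule; `knownSnpIds` additionally
accepts rs ids or variant keys for VCFs lacking RSID tags. Modern
pipelines would frequency-filter instead; the historical rule is the
default and the set is exposed.

**Truncating and NMD escape.** Truncating = nonsense ∪ frameshift ∪
splice-region deletions that remove at least one base of an
acceptor/donor window. The NMD-escape rule is "truncating and in (or
immediately adjacent to) the last exon": an intronic deletion anchored
on the last exon's acceptor can only disturb the terminal exon, so its
transcript is expected to escape nonsense-mediated decay exactly like a
last-exon stop. This "anchored-exon adjacency" is why the 14-bp
acceptor deletion counts as the third truncating, NMD-escaping
mutation alongside the last-exon nonsense and frameshift changes — the
interpretation under which the three truncating mutations all affect
the final exon. The stricter 50-nt-boundary NMD rule was considered
and not implemented: with all relevant variants deep inside the final
exon it changes nothing here, and the simple last-exon rule matches
the biological argument being modelled.

**Duplications classify by inserted length.** dup of k bases ≡
insertion of k bases: dupATC is in-frame, an 8-bp dup is a frameshift.

**Percent change for splice scores.** Scores are log-odds and can pass
through zero, where a relative change is ill-posed. The implementation
uses 100·(var−wt)/max(|wt|, 1e−9); the ε guard keeps the quantity
defined, and an absolute-difference mode (`changeMode = "absolute"`)
is available when wildtype scores sit near zero. "Both altered by
>20%" is read directionally: two primary scorers moving >20% in
*opposite* directions do not trigger, because the consensus being
sought is itself directional (a decrease in a wildtype site, or an
increase in a cryptic site).

**The five scorers are the package's own PWMs.** The named external
splice predictors are deliberately not reproduced; five independently
trained log₂-odds PWMs (different training draws, sizes and
pseudocounts) satisfy the scorer protocol, and `scoreSite()` is the
seam where real external tools can be adapted in.

**Gene identity is the gene_id string.** No symbol aliasing: all
inputs must share one gene namespace.

# The transcript fixture

The real EZH2 sequence is not bundled. `buildTranscriptFixture()`
*constructs* a 20-exon transcript (19 coding exons; the CDS starts in
exon 2) on a synthetic contig such that every codon/base claim of the
19-mutation table holds: codon 684 is CGC inside a CpG (making the
recurrent R684C a deamination hotspot), codon 733 is TAC (so c.2199C>G
creates a stop), c.2204–2211 spell AGGCTGAT, the final coding exon
starts at c.2196, and the preceding intron ends in the polypyrimidine
tract TTCCTGTTGTTTCA at offsets −15…−2 followed by the canonical AG.
The builder asserts each constraint and errors rather than ship a
silently wrong fixture; the exon-numbering convention is transcript
numbering, which is also what the table's intronic deletion uses.
Deep intron 19 is purine-biased so that deleting the pyrimidine tract
slides visibly weaker sequence into the acceptor window — the
behaviour the splice stage exists to detect.

# What the simulator emulates — and what it does not

`simulateCohort()` reproduces the *statistical shape* of the discovery
design: 4 affected unrelated cases; 5,000 candidate variants per exome
after calling, with 40% dbSNP-tagged, 10% under the depth floor and
20% intronic/synonymous (independent draws); background depths
15 + NB(mean 45, size 5) ≈ mean 60; a 1,000-gene background universe;
one planted, filter-clean causal mutation per case (the four
exome-discovery mutations by default); 7 of 8 parents available; 115
controls whose locus variants are all dbSNP-tagged or excluded-class.
These proportions are invented where the source gives none; they are
all exposed in `simConfig()`.

By default the generator *enforces* the unique-candidate property by
resampling background gene assignments that would otherwise survive in
every case, so discovery acceptance is deterministic rather than
probabilistic; `enforceUniqueCandidate = FALSE` gives honest stochastic
backgrounds for power experiments. What the simulator does **not**
emulate: linkage disequilibrium, realistic allele-frequency spectra,
mapping artefacts, batch effects between capture kits, or read-level
errors (no FASTQ/BAM). A pipeline that passes these tests is correct
*given* honest upstream calls; the tests say nothing about caller
quality on real data.

# Numerical and degenerate-input conventions

* Missing clinical values ("nk") become NA, never 0; every statistic
  reports the n actually used.
* An absent consequence class is treated as "other" and is never
  excluded by the class filter.
* CpG context at a sequence edge (no neighbour) is FALSE, logged.
* Empty variant sets filter to empty sets with an all-zero report; an
  empty phenotype table is an error.
* A family segregation check on an all-negative family co-segregates
  (vacuously); fewer than two members is an error.
* Cryptic-site scans break score ties leftmost; verdicts are invariant
  to confirmatory-scorer order.
* All generator output is byte-identical under a fixed seed (VCFs are
  written with a fixed header and no date stamp for this reason).

# Problem sizes used by the test suite

The suite exercises full-size cohorts (4 × 5,000 variants) for the
headline discovery checks — 100 seeds for planted-gene recovery, 10
seeds for the brute-force filter oracle, the full 115-control panel —
and scales down to a few hundred background variants where the
property under test (round-trips, determinism, monotonicity) does not
depend on cohort size.

# Known limitations

* Dominant/de novo intersection only: no compound-heterozygous or
  X-linked modes.
* The splice assessor requires a plus-strand locus sequence (the
  coordinate engine itself handles both strands).
* Missense deleteriousness prediction is out of scope by design; the
  conservation score (homolog column identity) is the only
  residue-level evidence computed.
* Raw SD scores are consumed as-is; no age/sex LMS centile modelling.
* HGVS support covers substitutions, deletions, duplications,
  insertions and delins — not inversions or protein-level notation.
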