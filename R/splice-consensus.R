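#' Percent change between wildtype and variant site scores
#'
#' 100 * (var - wt) / max(|wt|, eps). The sign carries direction:
#' negative means the site weakened (wildtype loss), positive means it
#' strengthened (cryptic gain). The eps guard keeps the ratio defined
#' for near-zero wildtype scores, where a relative change is otherwise
#' ill-posed for log-odds scales; see [assessSpliceVariant()] for the
#' alternative absolute mode.
#'
#' @param wt,var wildtype and variant scores.
#' @param eps denominator guard, default 1e-9.
#' @return percent change (vectorised).
#' @export
pctChange <- function(wt, var, eps = 1e-9) {
  100 * (var - wt) / pmax(abs(wt), eps)
}

#' Train a log2-odds PWM splice scorer
#'
#' score(window) = sum_i log2(f[base_i, i] / 0.25), with per-cell
#' frequencies f estimated from example site sequences plus a
#' pseudocount: f = (count + pc) / (n + 4 pc).
#'
#' @param name scorer name.
#' @param siteType "acceptor" or "donor".
#' @param examples character vector (or DNAStringSet) of aligned example
#'   sites, all the same length.
#' @param intronBases,exonBases window composition (see
#'   [PwmScorer-class]); must sum to the example length.
#' @param pseudocount per-cell pseudocount, default 0.5.
#' @return a [PwmScorer-class].
#' @export
trainPwmScorer <- function(name, siteType, examples, intronBases, exonBases,
                           pseudocount = 0.5) {
  examples <- toupper(as.character(examples))
  L <- unique(nchar(examples))
  if (length(L) != 1L) stop("training examples must share one length", call. = FALSE)
  assertDna(examples, "training example")
  if (L != intronBases + exonBases)
    stop("example length must equal intronBases + exonBases", call. = FALSE)
  mat <- do.call(rbind, strsplit(examples, ""))
  counts <- vapply(seq_len(L), function(j) {
    tab <- table(factor(mat[, j], levels = DNA_BASES))
    as.integer(tab)
  }, integer(4))
  rownames(counts) <- DNA_BASES
  f <- (counts + pseudocount) / (length(examples) + 4 * pseudocount)
  new("PwmScorer", name = name, siteType = siteType,
      pwm = log2(f / 0.25), intronBases = as.integer(intronBases),
      exonBases = as.integer(exonBases))
}

#' Score a sequence window with a PWM scorer
#'
#' @param scorer a [PwmScorer-class].
#' @param window character of exactly the scorer's window length, ACGT only.
#' @return finite numeric score (higher = stronger site).
#' @export
setGeneric("scoreSite", function(scorer, window) standardGeneric("scoreSite"))

#' @rdname scoreSite
#' @export
setMethod("scoreSite", "PwmScorer", function(scorer, window) {
  window <- toupper(as.character(window))
  L <- ncol(scorer@pwm)
  if (nchar(window) != L)
    stop(sprintf("window length %d does not match scorer length %d",
                 nchar(window), L), call. = FALSE)
  assertDna(window, "window")
  b <- strsplit(window, "")[[1]]
  sum(scorer@pwm[cbind(match(b, DNA_BASES), seq_len(L))])
})

setMethod("show", "PwmScorer", function(object) {
  cat(sprintf("PwmScorer '%s' (%s): %d-nt window (%d intron + %d exon)\n",
              object@name, object@siteType, ncol(object@pwm),
              object@intronBases, object@exonBases))
})

setMethod("show", "SpliceScorer", function(object) {
  cat(sprintf("SpliceScorer '%s': acceptor %d nt, donor %d nt\n", object@name,
              ncol(object@acceptor@pwm), ncol(object@donor@pwm)))
})

## Window geometry shared by all built-in scorers: acceptor windows span
## the final 14 intronic bases (polypyrimidine tract + AG) plus the
## first 3 exonic bases; donor windows the last 3 exonic plus first 6
## intronic bases.
ACCEPTOR_INTRON <- 14L
ACCEPTOR_EXON <- 3L
DONOR_EXON <- 3L
DONOR_INTRON <- 6L

## Synthetic splice-site training examples: consensus-shaped draws from
## per-column base frequencies (acceptor: pyrimidine tract then AG then
## G-biased exon start; donor: MAG|GTAAGT-like).
synthSpliceExamples <- function(siteType, n, seed) {
  withFixedSeed(seed, function() {
    drawCols <- function(probs, n) {
      vapply(seq_len(n), function(i)
        paste(vapply(probs, function(p) sample(DNA_BASES, 1L, prob = p),
                     character(1)), collapse = ""), character(1))
    }
    if (siteType == "acceptor") {
      probs <- c(
        rep(list(c(A = .08, C = .42, G = .08, T = .42)), 12),  # pyrimidine tract
        list(c(A = .94, C = .02, G = .02, T = .02)),           # -2 A
        list(c(A = .01, C = .01, G = .97, T = .01)),           # -1 G
        rep(list(c(A = .25, C = .15, G = .45, T = .15)), ACCEPTOR_EXON))
    } else {
      probs <- list(
        c(A = .35, C = .35, G = .15, T = .15),
        c(A = .60, C = .12, G = .14, T = .14),
        c(A = .08, C = .04, G = .80, T = .08),
        c(A = .003, C = .003, G = .99, T = .004),              # +1 G
        c(A = .003, C = .003, G = .004, T = .99),              # +2 T
        c(A = .60, C = .10, G = .20, T = .10),
        c(A = .70, C = .08, G = .12, T = .10),
        c(A = .08, C = .06, G = .80, T = .06),
        c(A = .17, C = .16, G = .22, T = .45))
    }
    drawCols(probs, n)
  })
}

#' The five built-in splice scorers
#'
#' Five independently trained PWM scorer pairs (each with an acceptor
#' and a donor PWM) standing in for the two primary and three
#' confirmatory predictors of the consensus procedure. They differ in
#' training sample, training size and pseudocount, but share window
#' geometry. Deterministic: repeated calls return identical scorers.
#' Real external predictors can be wired in instead by supplying any
#' list of objects honouring the [scoreSite()] protocol.
#'
#' @return list of five [SpliceScorer-class] objects; the first two are
#'   the primary tier.
#' @export
builtinSpliceScorers <- function() {
  seeds <- c(101L, 102L, 103L, 104L, 105L)
  pcs <- c(0.5, 1.0, 0.25, 0.75, 0.5)
  ns <- c(200L, 300L, 150L, 250L, 200L)
  lapply(seq_len(5), function(i) {
    acc <- trainPwmScorer(sprintf("pwm%d.acc", i), "acceptor",
                          synthSpliceExamples("acceptor", ns[i], seeds[i]),
                          ACCEPTOR_INTRON, ACCEPTOR_EXON, pcs[i])
    don <- trainPwmScorer(sprintf("pwm%d.don", i), "donor",
                          synthSpliceExamples("donor", ns[i], seeds[i] + 50L),
                          DONOR_EXON, DONOR_INTRON, pcs[i])
    new("SpliceScorer", name = sprintf("pwm%d", i), acceptor = acc, donor = don)
  })
}

## Normalise an HgvsEdit to a genomic replacement on the forward strand:
## locus[gstart..gend] -> repl. Plus-strand models only.
hgvsToGenomicEdit <- function(edit, model) {
  if (model@strand != "+")
    stop("genomic edit application requires a plus-strand model", call. = FALSE)
  g1 <- codingToGenomic(model, edit@startPos, edit@startOff)
  g2 <- codingToGenomic(model, edit@endPos, edit@endOff)
  lo <- min(g1, g2); hi <- max(g1, g2)
  switch(edit@kind,
    substitution = list(gstart = lo, gend = hi, repl = edit@insBases),
    deletion = list(gstart = lo, gend = hi, repl = ""),
    delins = list(gstart = lo, gend = hi, repl = edit@insBases),
    duplication = {
      span <- locusSubseq(model, lo, hi)
      if (nzchar(edit@insBases) && !identical(span, edit@insBases))
        stop(sprintf("duplicated bases %s do not match locus span %s",
                     edit@insBases, span), call. = FALSE)
      list(gstart = lo, gend = hi, repl = paste0(span, span))
    },
    insertion = {
      b <- locusBase(model, lo)
      list(gstart = lo, gend = lo, repl = paste0(b, edit@insBases))
    },
    stop("unsupported edit kind", call. = FALSE))
}

## VCF-style (pos, ref, alt) for an HgvsEdit, left-anchored for indels.
hgvsToVcf <- function(edit, model) {
  ge <- hgvsToGenomicEdit(edit, model)
  if (edit@kind == "substitution")
    return(list(pos = ge$gstart, ref = locusBase(model, ge$gstart),
                alt = ge$repl))
  if (edit@kind == "duplication") {
    span <- locusSubseq(model, ge$gstart, ge$gend)
    b <- locusBase(model, ge$gend)
    return(list(pos = ge$gend, ref = b, alt = paste0(b, span)))
  }
  ## deletion / delins / insertion: anchor on the base before the span
  a <- ge$gstart - 1L
  anchor <- locusBase(model, a)
  refSpan <- locusSubseq(model, ge$gstart, ge$gend)
  if (edit@kind == "insertion")
    return(list(pos = ge$gstart, ref = locusBase(model, ge$gstart),
                alt = ge$repl))
  list(pos = a, ref = paste0(anchor, refSpan),
       alt = paste0(anchor, if (edit@kind == "delins") edit@insBases else ""))
}

#' Two-tier splice-disruption consensus assessment
#'
#' Tier 1 scores the nearest annotated splice site (wildtype-loss mode)
#' and the best local novel site (cryptic-gain mode) with the two
#' primary scorers; the procedure triggers when BOTH primary scores
#' change by more than `threshold` percent in a consistent direction
#' (both down for loss, both up for gain). On trigger, the three
#' confirmatory scorers run in the triggering mode: a unanimous
#' directional change across all five gives "disruptive"; a
#' non-unanimous panel gives "indeterminate"; no trigger gives
#' "not_disruptive".
#'
#' @param edit an [HgvsEdit-class] or HGVS c. string.
#' @param model a plus-strand [TranscriptModel-class] carrying a locus
#'   sequence.
#' @param scorers list of five [SpliceScorer-class] (2 primary + 3
#'   confirmatory); default [builtinSpliceScorers()].
#' @param threshold trigger threshold in percent, default 20.
#' @param crypticRange novel-site search half-width around the edit in
#'   bases, default 25 (ties broken leftmost).
#' @param maxDist farthest annotated site considered assessable, default
#'   200 bases.
#' @param changeMode "relative" (eps-guarded percent change, default) or
#'   "absolute" (score difference reported on a 100x scale).
#' @return a [SpliceVerdict-class].
#' @export
assessSpliceVariant <- function(edit, model, scorers = builtinSpliceScorers(),
                                threshold = 20, crypticRange = 25L,
                                maxDist = 200L, changeMode = c("relative", "absolute")) {
  changeMode <- match.arg(changeMode)
  if (is.character(edit)) edit <- parseHgvsC(edit)
  if (length(scorers) != 5L)
    stop("need exactly five scorers (2 primary + 3 confirmatory)", call. = FALSE)
  if (!length(model@locusSeq))
    stop("splice assessment needs a model with a locus sequence", call. = FALSE)

  ge <- hgvsToGenomicEdit(edit, model)
  delta <- nchar(ge$repl) - (ge$gend - ge$gstart + 1L)

  ## nearest annotated site
  nEx <- exonCount(model)
  sites <- rbind(
    if (nEx > 1L) data.frame(type = "acceptor", pos = model@exonStarts[-1]),
    if (nEx > 1L) data.frame(type = "donor", pos = model@exonEnds[-nEx]))
  d <- ifelse(sites$pos >= ge$gstart & sites$pos <= ge$gend, 0L,
              pmin(abs(sites$pos - ge$gstart), abs(sites$pos - ge$gend)))
  i <- which.min(d)
  if (d[i] > maxDist) stop("no assessable site within range", call. = FALSE)
  siteType <- sites$type[i]; sitePos <- as.integer(sites$pos[i])

  wtSeq <- as.character(model@locusSeq)
  i1 <- ge$gstart - model@locusStart + 1L
  i2 <- ge$gend - model@locusStart + 1L
  varSeq <- paste0(substr(wtSeq, 1L, i1 - 1L), ge$repl,
                   substr(wtSeq, i2 + 1L, nchar(wtSeq)))

  ## index of a wildtype genomic position in the edited string
  varIndex <- function(g) {
    j <- g - model@locusStart + 1L
    if (g > ge$gend) j + delta
    else if (g >= ge$gstart) i1 - 1L + max(1L, nchar(ge$repl)) # boundary consumed
    else j
  }
  wtIndex <- function(g) g - model@locusStart + 1L

  sitePwm <- function(sc) if (siteType == "acceptor") sc@acceptor else sc@donor
  windowAt <- function(s, anchorIdx, pwm) {
    if (pwm@siteType == "acceptor")
      substr(s, anchorIdx - pwm@intronBases, anchorIdx + pwm@exonBases - 1L)
    else
      substr(s, anchorIdx - pwm@exonBases + 1L, anchorIdx + pwm@intronBases)
  }
  change <- function(wt, var) {
    if (changeMode == "relative") pctChange(wt, var) else 100 * (var - wt)
  }

  lossFor <- function(sc) {
    pwm <- sitePwm(sc)
    wt <- scoreSite(pwm, windowAt(wtSeq, wtIndex(sitePos), pwm))
    var <- scoreSite(pwm, windowAt(varSeq, varIndex(sitePos), pwm))
    c(wt = wt, var = var, pct = change(wt, var))
  }
  gainFor <- function(sc) {
    pwm <- sitePwm(sc)
    L <- ncol(pwm@pwm)
    center <- (ge$gstart + ge$gend) %/% 2L
    scan <- function(s, centerIdx) {
      starts <- (centerIdx - crypticRange):(centerIdx + crypticRange)
      starts <- starts[starts >= 1L & starts + L - 1L <= nchar(s)]
      best <- -Inf
      for (st in starts) {
        sc0 <- scoreSite(pwm, substr(s, st, st + L - 1L))
        if (sc0 > best) best <- sc0   # strict '>' keeps leftmost tie
      }
      best
    }
    wt <- scan(wtSeq, wtIndex(center))
    var <- scan(varSeq, varIndex(center))
    c(wt = wt, var = var, pct = change(wt, var))
  }

  prim <- scorers[1:2]
  lossP <- lapply(prim, lossFor)
  gainP <- lapply(prim, gainFor)
  lossPct <- vapply(lossP, `[[`, numeric(1), "pct")
  gainPct <- vapply(gainP, `[[`, numeric(1), "pct")
  lossTrig <- all(lossPct < -threshold)
  gainTrig <- all(gainPct > threshold)
  mode <- if (lossTrig && gainTrig) {
    if (min(abs(lossPct)) >= min(gainPct)) "wildtype_loss" else "cryptic_gain"
  } else if (lossTrig) "wildtype_loss"
    else if (gainTrig) "cryptic_gain"
    else if (max(abs(lossPct)) >= max(abs(gainPct))) "wildtype_loss"
    else "cryptic_gain"
  triggered <- lossTrig || gainTrig

  rowsOf <- function(scs, vals) data.frame(
    scorer = vapply(scs, function(s) s@name, character(1)),
    wt_score = vapply(vals, `[[`, numeric(1), "wt"),
    var_score = vapply(vals, `[[`, numeric(1), "var"),
    pct_change = vapply(vals, `[[`, numeric(1), "pct"),
    stringsAsFactors = FALSE)
  tier1 <- rowsOf(prim, if (mode == "wildtype_loss") lossP else gainP)

  tier2 <- tier1[0, ]
  verdict <- "not_disruptive"
  if (triggered) {
    conf <- scorers[3:5]
    vals <- lapply(conf, if (mode == "wildtype_loss") lossFor else gainFor)
    tier2 <- rowsOf(conf, vals)
    allPct <- c(tier1$pct_change, tier2$pct_change)
    unanimous <- if (mode == "wildtype_loss") all(allPct < 0) else all(allPct > 0)
    verdict <- if (unanimous) "disruptive" else "indeterminate"
  }

  new("SpliceVerdict", hgvs = edit@text, siteType = siteType,
      sitePos = sitePos, mode = mode, tier1 = tier1,
      triggered = triggered, tier2 = tier2, verdict = verdict)
}

setMethod("show", "SpliceVerdict", function(object) {
  cat(sprintf("SpliceVerdict %s: %s at %s site (pos %d), %s%s\n",
              object@hgvs, object@verdict, object@siteType, object@sitePos,
              object@mode,
              if (object@triggered) " [triggered]" else ""))
  print(object@tier1)
  if (nrow(object@tier2)) print(object@tier2)
})

#' @describeIn assessSpliceVariant the verdict string of a SpliceVerdict.
#' @param x a SpliceVerdict.
#' @export
spliceVerdict <- function(x) x@verdict
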