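#' @importFrom methods new validObject is slot setValidity show
#' @importFrom stats rnbinom runif setNames
#' @importFrom utils read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run code under a fixed RNG state without disturbing the caller's stream.
withFixedSeed <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  fn()
}

#' Canonical variant key
#'
#' Builds the `chrom:pos:ref:alt` key used throughout the package to
#' identify a variant at site level (panel-of-normals matching, truth
#' tables, de novo lookups).
#'
#' @param chrom,pos,ref,alt vectors of equal length (or a data.frame in
#'   `chrom` with those columns and the rest missing).
#' @return character vector of keys.
#' @export
variantKey <- function(chrom, pos = NULL, ref = NULL, alt = NULL) {
  if (is.data.frame(chrom)) {
    df <- chrom
    return(paste(df$chrom, df$pos, df$ref, df$alt, sep = ":"))
  }
  paste(chrom, pos, ref, alt, sep = ":")
}

DNA_BASES <- c("A", "C", "G", "T")

assertDna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad))
    stop(sprintf("%s contains non-ACGT characters: %s", what,
                 paste(head(x[bad], 3L), collapse = ", ")), call. = FALSE)
  invisible(x)
}

CONSEQUENCE_CLASSES <- c("intronic", "synonymous", "missense", "nonsense",
                         "frameshift", "inframe_indel", "splice_region",
                         "other")
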