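#' Run the discovery pipeline end to end
#'
#' Orchestrates simulate -> filter -> intersect -> de novo confirmation
#' under one configuration, writing a reproducibility record
#' (run_record.json: command, config snapshot, seed, input checksums,
#' timestamp) atomically before any stage output is finalised. Any stage
#' failure aborts with a message naming the stage; a missing input fails
#' pre-flight before any stage runs.
#'
#' Config (list or YAML file) fields: `out_dir` (required), `seed`
#' (required unless `inputs` given), optional `simulation` (arguments to
#' [simConfig()] other than seed), optional `inputs` with `vcf_dir` and
#' `manifest` to run on real per-sample VCFs instead of simulating, and
#' optional `filters` (arguments to [filterConfig()]).
#'
#' @param config list or path to a YAML file.
#' @return invisibly, a list with candidates, the hit matrix, attrition
#'   TSV text, de novo calls (simulated runs) and output paths.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  ## pre-flight: validate before any stage runs or output appears
  if (is.null(config$out_dir)) stop("pre-flight: config needs out_dir", call. = FALSE)
  useInputs <- !is.null(config$inputs)
  if (useInputs) {
    if (is.null(config$inputs$vcf_dir) || is.null(config$inputs$manifest))
      stop("pre-flight: inputs need vcf_dir and manifest", call. = FALSE)
    if (!dir.exists(config$inputs$vcf_dir))
      stop("pre-flight: missing input vcf_dir ", config$inputs$vcf_dir, call. = FALSE)
    if (!file.exists(config$inputs$manifest))
      stop("pre-flight: missing input manifest ", config$inputs$manifest, call. = FALSE)
  } else if (is.null(config$seed)) {
    stop("pre-flight: config needs seed (or inputs)", call. = FALSE)
  }
  outDir <- config$out_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  checksums <- if (useInputs) {
    files <- c(list.files(config$inputs$vcf_dir, "\\.vcf$", full.names = TRUE),
               config$inputs$manifest)
    as.list(tools::md5sum(files))
  } else list()
  record <- list(command = "mendelseek::runPipeline",
                 config = config,
                 seed = config$seed %||% NA,
                 input_checksums = checksums,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  tmp <- file.path(outDir, ".run_record.json.tmp")
  jsonlite::write_json(record, tmp, auto_unbox = TRUE, pretty = TRUE)
  file.rename(tmp, file.path(outDir, "run_record.json"))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  sim <- NULL
  if (useInputs) {
    manifest <- stage("read", readCohortManifest(config$inputs$manifest))
    cohort <- stage("read", {
      ids <- manifest$sample_id
      setNames(lapply(ids, function(s)
        readVariantVcf(file.path(config$inputs$vcf_dir, paste0(s, ".vcf")), s)),
        ids)
    })
  } else {
    simArgs <- c(list(seed = config$seed), config$simulation %||% list())
    sim <- stage("simulate", {
      cfg <- do.call(simConfig, simArgs)
      simulateCohort(cfg, dir = file.path(outDir, "sim"))
    })
    manifest <- sim$manifest
    cohort <- sim$variants
  }

  fcfg <- do.call(filterConfig, config$filters %||% list())
  filtered <- list(); reports <- list()
  stage("filter", for (s in names(cohort)) {
    res <- applyFilters(cohort[[s]], fcfg)
    filtered[[s]] <- res$surviving
    reports[[s]] <- res$report
    message(sprintf("filter %-10s: %d -> %d variants", s,
                    res$report$n_before[1], res$report$n_after[nrow(res$report)]))
  })
  attrition <- attritionTable(reports)
  cat(attrition, file = file.path(outDir, "attrition.tsv"))

  ghm <- stage("intersect", intersectGenes(filtered, manifest))
  writeLines(c("gene", candidateGenes(ghm)), file.path(outDir, "candidates.tsv"))
  hm <- hitMatrix(ghm)
  write.table(data.frame(gene = rownames(hm), hm, check.names = FALSE),
              file.path(outDir, "genehits.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  denovo <- NULL
  if (!is.null(sim)) {
    denovo <- stage("denovo", do.call(rbind, lapply(
      manifest$sample_id[manifest$role == "affected"], function(sid) {
        tr <- sim$truth[sim$truth$sample_id == sid, , drop = FALSE]
        child <- filtered[[sid]]
        child <- child[variantKey(child) %in% variantKey(tr), , drop = FALSE]
        mkParent <- function(suffix) {
          pid <- paste0(sid, "_", suffix)
          if (!pid %in% names(cohort)) return(NULL)
          list(variants = cohort[[pid]],
               depths = sim$parentDepths[sim$parentDepths$sample_id == pid, ,
                                         drop = FALSE])
        }
        confirmDeNovo(child, mother = mkParent("M"), father = mkParent("F"))
      })))
    write.table(denovo, file.path(outDir, "denovo.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  invisible(list(candidates = candidateGenes(ghm), hits = ghm,
                 attrition = attrition, denovo = denovo, out_dir = outDir))
}
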