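#' Configuration for an end-to-end pipeline run
#'
#' Collects the inputs, comparisons and flags for [runPipeline()].  Either
#' a generator config (simulation mode) or paths to a clone FASTA and
#' sample sheet must be given; a seed is mandatory whenever any stochastic
#' stage (simulation or permutation testing) is involved.
#'
#' @param assay a [PromoterAssay-class].
#' @param outputDir output directory for stage TSVs and the report.
#' @param generator optional `GeneratorConfig` (simulation mode).
#' @param cloneFasta,sampleSheetPath input paths (data mode).
#' @param ctTable optional Ct data.frame or TSV path for the expression
#'   stage.
#' @param comparisons list of class-label pairs for the Fst grid.
#' @param nPerm permutations per Fst test.
#' @param seed integer seed (required for simulation / permutations).
#' @param minConversion clone conversion-efficiency filter (default 0,
#'   report-only).
#' @param clusterBy grouping for presumptive sexing (default temperature).
#' @param force overwrite an existing output directory.
#' @return a `PipelineConfig` list.
#' @export
pipelineConfig <- function(assay, outputDir, generator = NULL,
                           cloneFasta = NULL, sampleSheetPath = NULL,
                           ctTable = NULL,
                           comparisons = list(c("MLT", "FLT"),
                                              c("FLT", "FHT")),
                           nPerm = 999L, seed = NULL,
                           minConversion = 0, clusterBy = "temperature",
                           force = FALSE) {
  if (is.null(generator) && (is.null(cloneFasta) || is.null(sampleSheetPath))) {
    stop("config error: need a generator or cloneFasta + sampleSheetPath")
  }
  if (is.null(seed) && (!is.null(generator) || nPerm > 0L)) {
    stop("config error: seed is required for stochastic stages")
  }
  structure(list(assay = assay, outputDir = outputDir, generator = generator,
                 cloneFasta = cloneFasta, sampleSheetPath = sampleSheetPath,
                 ctTable = ctTable, comparisons = comparisons,
                 nPerm = as.integer(nPerm),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 minConversion = minConversion, clusterBy = clusterBy,
                 force = force),
            class = "PipelineConfig")
}

.writeTsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (or load) clones -> methylation calling + QC ->
#' per-fish summaries and group means -> epiallele table with tests ->
#' Fst grid (whole promoter and per CpG) -> group statistics (two-way
#' ANOVA, t-test, sex threshold, classifications) -> expression (RQ +
#' presumptive sexing, if Ct data present) -> Markdown report.  Every
#' number in the report is rendered from a stage TSV; reruns with the
#' same config and seed produce byte-identical stage files.
#'
#' @param config a `PipelineConfig` from [pipelineConfig()].
#' @return invisibly, a list with the stage objects and file paths.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  out <- config$outputDir
  if (dir.exists(out) && length(list.files(out)) && !config$force) {
    stop("config error: output directory exists (use force = TRUE)")
  }
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(out, "pipeline.log")
  logLine <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    cat(msg, "\n", file = logFile, append = TRUE, sep = "")
    message(msg)
  }
  logLine("epiclone ", as.character(utils::packageVersion("epiclone")),
          " | seed ", config$seed, " | n_perm ", config$nPerm)
  files <- list()
  stage <- "simulate"
  res <- tryCatch({
    if (!is.null(config$generator)) {
      sim <- simulateCloneDataset(config$generator)
      files$fasta <- writeCloneFasta(sim$sequences, file.path(out, "clones.fa"))
      files$sample_sheet <- .writeTsv(sim$sampleSheet,
                                      file.path(out, "sample_sheet.tsv"))
      seqs <- sim$sequences
      sheet <- sim$sampleSheet
      logLine("simulated ", length(seqs), " clones from ",
              nrow(sheet), " fish")
    } else {
      seqs <- config$cloneFasta
      sheet <- readSampleSheet(config$sampleSheetPath)
    }

    stage <- "call"
    set <- buildCallMatrix(config$assay, seqs, sheet,
                           minConversion = config$minConversion)
    files$calls <- writeCallsTable(set, file.path(out, "calls.tsv"))
    qc <- qcReport(set)
    files$qc <- .writeTsv(qc, file.path(out, "qc.tsv"))
    logLine("called ", nrow(cloneData(set)), " clones; mean conversion ",
            sprintf("%.2f%%",
                    100 * mean(cloneData(set)$conversion_efficiency,
                               na.rm = TRUE)))

    stage <- "summaries"
    fs <- fishSummaries(set)
    files$fish <- .writeTsv(fs, file.path(out, "fish_summaries.tsv"))
    gm <- groupMeanMethylation(set)
    files$groups <- .writeTsv(gm, file.path(out, "group_means.tsv"))

    stage <- "epialleles"
    ep <- epialleleTests(set)
    files$epialleles <- .writeTsv(ep, file.path(out, "epialleles.tsv"))
    div <- patternDiversity(set)
    files$diversity <- .writeTsv(div, file.path(out, "pattern_diversity.tsv"))

    stage <- "amova"
    fst <- fstTable(set, config$comparisons, nPerm = config$nPerm,
                    seed = config$seed)
    files$fst <- .writeTsv(fst, file.path(out, "fst.tsv"))
    logLine("amova: ", nrow(fst), " comparisons at n_perm ", config$nPerm)

    stage <- "stats"
    an <- twoWayAnova(fs)
    files$anova <- .writeTsv(an, file.path(out, "anova.tsv"))
    fMeans <- fs$mean_methylation[fs$sex == "F"]
    mMeans <- fs$mean_methylation[fs$sex == "M"]
    statsTxt <- c(sprintf("sex F = %.3f; P = %.4g",
                          an$statistic[an$term == "sex"],
                          an$p_value[an$term == "sex"]),
                  sprintf("temperature F = %.3f; P = %.4g",
                          an$statistic[an$term == "temperature"],
                          an$p_value[an$term == "temperature"]))
    thr <- NULL
    if (length(fMeans) >= 3L && length(mMeans) >= 3L) {
      tt <- pooledTTest(arcsinSqrt(mMeans), arcsinSqrt(fMeans))
      thr <- sexThreshold(fMeans, mMeans)
      fs$presumptive_sex <- classifySex(fs$mean_methylation, thr$threshold)
      files$fish <- .writeTsv(fs, file.path(out, "fish_summaries.tsv"))
      statsTxt <- c(statsTxt,
                    sprintf("M vs F: t = %.3f; df = %d; P = %.4g",
                            tt$t, as.integer(tt$df), tt$p),
                    sprintf("sex threshold = %.1f%%%s",
                            100 * thr$threshold,
                            if (thr$overlap) " (CI overlap)" else ""))
    }
    writeLines(statsTxt, file.path(out, "stats.txt"))
    files$stats <- file.path(out, "stats.txt")

    stage <- "expression"
    expr <- NULL
    if (!is.null(config$ctTable)) {
      ct <- config$ctTable
      if (is.character(ct)) ct <- utils::read.delim(ct, sep = "\t")
      expr <- clusterPresumptiveSex(computeRQ(ct), by = config$clusterBy)
      files$expression <- .writeTsv(expr, file.path(out, "expression.tsv"))
      logLine("expression: ", nrow(expr), " fish quantified")
    }

    stage <- "report"
    files$report <- .writeReport(out, files)
    logLine("report written to ", files$report)
    list(set = set, summaries = fs, groupMeans = gm, epialleles = ep,
         fst = fst, anova = an, threshold = thr, expression = expr,
         files = files)
  }, error = function(e) {
    logLine("FAILED at stage '", stage, "': ", conditionMessage(e))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

# Render the Markdown report purely from the stage files already written.
.writeReport <- function(out, files) {
  rd <- function(p) utils::read.delim(p, sep = "\t", check.names = FALSE)
  md <- c("# epiclone pipeline report", "")
  fmt <- function(d) {
    num <- vapply(d, is.numeric, TRUE)
    d[num] <- lapply(d[num], function(x) signif(x, 4))
    c(paste(names(d), collapse = " | "),
      paste(rep("---", ncol(d)), collapse = " | "),
      apply(d, 1L, paste, collapse = " | "))
  }
  md <- c(md, "## Group methylation means", "", fmt(rd(files$groups)), "")
  ep <- rd(files$epialleles)
  md <- c(md, "## Epiallele table (top 10 patterns)", "",
          fmt(utils::head(ep, 10)), "")
  md <- c(md, "## Fst grid", "", fmt(rd(files$fst)), "")
  md <- c(md, "## Group statistics", "", readLines(files$stats), "")
  if (!is.null(files$expression)) {
    md <- c(md, "## Expression (RQ and presumptive sex)", "",
            fmt(rd(files$expression)), "")
  }
  path <- file.path(out, "report.md")
  writeLines(md, path)
  path
}
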