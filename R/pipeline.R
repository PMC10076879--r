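#' Pipeline configuration
#'
#' Bundles all file paths, thresholds and flags for [runPipeline()]. Only
#' `beta`, `samples`, `manifest` and `counts` are required; gene sets,
#' Ct table and exclusion list are optional stages.
#'
#' @param beta path to the beta-matrix TSV (probes x samples).
#' @param samples path to the sample sheet TSV (`sample_id`, `group`,
#'   `pair_id`).
#' @param manifest path to the probe manifest TSV.
#' @param counts path to the count-matrix TSV (genes x samples).
#' @param gmt optional GMT gene-set collection path.
#' @param ct optional qPCR Ct table path.
#' @param exclude optional plain-text file of previously reported gene
#'   symbols (one per line) to drop from candidate tables.
#' @param deltaBeta,dmP DM gates (defaults 0.2 and 0.05 raw p).
#' @param lfc,padj DE gates (defaults 1 and 0.05).
#' @param topK candidate-table size (default 15).
#' @param paired use the paired Wilcoxon signed-rank DM test.
#' @param quantileNormalize quantile-normalize the beta matrix first.
#' @param enrichUniverse `"counts"` (expression universe) or `"manifest"`.
#' @param seed integer seed recorded in provenance.
#' @return A `PipelineConfig` list.
#' @export
pipelineConfig <- function(beta, samples, manifest, counts, gmt = NULL,
                           ct = NULL, exclude = NULL, deltaBeta = 0.2,
                           dmP = 0.05, lfc = 1, padj = 0.05, topK = 15,
                           paired = FALSE, quantileNormalize = FALSE,
                           enrichUniverse = c("counts", "manifest"),
                           seed = 1) {
  if (deltaBeta <= 0 || dmP <= 0 || lfc <= 0 || padj <= 0 || topK <= 0)
    stop("thresholds must be positive")
  cfg <- list(beta = beta, samples = samples, manifest = manifest,
              counts = counts, gmt = gmt, ct = ct, exclude = exclude,
              deltaBeta = deltaBeta, dmP = dmP, lfc = lfc, padj = padj,
              topK = as.integer(topK), paired = isTRUE(paired),
              quantileNormalize = isTRUE(quantileNormalize),
              enrichUniverse = match.arg(enrichUniverse),
              seed = as.integer(seed))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipelineConfig()]
#'   arguments; relative input paths are resolved against the YAML file's
#'   directory.
#' @return A `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (f in c("beta", "samples", "manifest", "counts", "gmt", "ct",
              "exclude"))
    if (!is.null(y[[f]]) && !grepl("^/", y[[f]]))
      y[[f]] <- file.path(base, y[[f]])
  do.call(pipelineConfig, y)
}

.requireFile <- function(path, stage) {
  if (is.null(path) || !file.exists(path))
    stop(sprintf("[%s] input file not found: %s", stage,
                 if (is.null(path)) "<unset>" else path), call. = FALSE)
}

#' Run the integrated methylation-expression pipeline
#'
#' Executes all stages in order — differential methylation, probe
#' annotation, differential expression, gene-level integration, candidate
#' ranking, optional enrichment and qPCR — and writes every result table
#' atomically to `outdir` together with a JSON provenance record (config
#' hash, seed, package version).
#'
#' @param config a [pipelineConfig()].
#' @param outdir output directory.
#' @return Invisibly, the in-memory result bundle (list of all tables).
#' @export
runPipeline <- function(config, outdir) {
  stopifnot(inherits(config, "PipelineConfig"))
  .requireFile(config$beta, "dm")
  .requireFile(config$samples, "dm")
  .requireFile(config$manifest, "annotate")
  .requireFile(config$counts, "de")
  if (!is.null(config$gmt)) .requireFile(config$gmt, "enrich")
  if (!is.null(config$ct)) .requireFile(config$ct, "qpcr")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  ss <- stage("dm", read.delim(config$samples, stringsAsFactors = FALSE))
  bundle <- list()

  bundle$dml <- stage("dm", {
    b <- readBetaMatrix(config$beta)
    b <- b[, ss$sample_id, drop = FALSE]
    if (config$quantileNormalize) b <- quantileNormalizeBeta(b)
    ms <- MethylationSet(b, ss$group, ss$pair_id, sampleIds = ss$sample_id)
    bundle$qc <- sampleCorrelationQC(b)
    callDML(ms, deltaThreshold = config$deltaBeta,
            pThreshold = config$dmP, paired = config$paired)
  })
  sig <- bundle$dml[bundle$dml$significant, , drop = FALSE]

  man <- stage("annotate", readManifest(config$manifest))
  bundle$dm_distribution <- stage("annotate",
    if (nrow(sig) > 0) dmlRegionDistribution(sig, man) else NULL)

  bundle$de <- stage("de", {
    cnt <- readCountMatrix(config$counts)
    cnt <- cnt[, ss$sample_id, drop = FALSE]
    rs <- RnaCountSet(cnt, ss$group, ss$pair_id, sampleIds = ss$sample_id)
    bundle$pca <- pcaQC(rs)
    nbWaldTest(rs)
  })
  degs <- callDEGs(bundle$de, lfcThreshold = config$lfc,
                   padjThreshold = config$padj)

  bundle$integrated <- stage("integrate",
    suppressWarnings(joinDmDe(sig, man, bundle$de)))
  if (nrow(bundle$integrated) > 0) {
    bundle$correlation <- stage("integrate",
                                regionCorrelation(bundle$integrated))
    bundle$dmg_counts <- stage("integrate",
                               classifyDMGs(bundle$integrated))
    bundle$candidates <- stage("rank",
      rankCandidates(bundle$integrated, k = config$topK,
                     padjThreshold = config$padj,
                     lfcThreshold = config$lfc))
    if (!is.null(config$exclude)) {
      excl <- .readLinesOpt(config$exclude)
      bundle$candidates$hyperDown <-
        filterReported(bundle$candidates$hyperDown, excl)
      bundle$candidates$hypoUp <-
        filterReported(bundle$candidates$hypoUp, excl)
    }
  }

  if (!is.null(config$gmt)) {
    bundle$enrichment <- stage("enrich", {
      sets <- readGMT(config$gmt)
      universe <- if (config$enrichUniverse == "counts") bundle$de$gene
                  else unique(unlist(parseGeneAnnotations(
                    man$UCSC_RefGene_Name, man$UCSC_RefGene_Group),
                    use.names = FALSE))
      lapply(Filter(length, list(up = degs$up, down = degs$down)),
             function(g) suppressWarnings(
               enrichGeneSets(g, universe, sets)))
    })
  }
  if (!is.null(config$ct))
    bundle$qpcr <- stage("qpcr", qpcrAnalysis(readCtTable(config$ct)))

  # write tables
  writeTsv(bundle$dml, file.path(outdir, "dml.tsv"))
  writeTsv(bundle$de, file.path(outdir, "de.tsv"))
  if (!is.null(bundle$dm_distribution)) {
    writeTsv(bundle$dm_distribution$region,
             file.path(outdir, "dml_region_distribution.tsv"))
    writeTsv(bundle$dm_distribution$island,
             file.path(outdir, "dml_island_distribution.tsv"))
  }
  if (nrow(bundle$integrated) > 0) {
    writeTsv(bundle$integrated, file.path(outdir, "integrated.tsv"))
    writeTsv(bundle$correlation, file.path(outdir, "region_correlation.tsv"))
    writeTsv(bundle$dmg_counts, file.path(outdir, "dmg_quadrant_counts.tsv"))
    writeTsv(bundle$candidates$hyperDown,
             file.path(outdir, "candidates_hyper_down.tsv"))
    writeTsv(bundle$candidates$hypoUp,
             file.path(outdir, "candidates_hypo_up.tsv"))
  }
  if (!is.null(bundle$enrichment))
    for (nm in names(bundle$enrichment))
      writeTsv(bundle$enrichment[[nm]],
               file.path(outdir, sprintf("enrichment_%s.tsv", nm)))
  if (!is.null(bundle$qpcr))
    writeTsv(bundle$qpcr, file.path(outdir, "qpcr.tsv"))
  writeLines(c(degs$up), file.path(outdir, "degs_up.txt"))
  writeLines(c(degs$down), file.path(outdir, "degs_down.txt"))

  prov <- list(
    package = "methexint",
    version = as.character(packageVersion("methexint")),
    seed = config$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    input_md5 = as.list(tools::md5sum(unlist(config[c("beta", "samples",
                                                      "manifest",
                                                      "counts")]))))
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(bundle)
}

#' Load the bundled candidate-table fixtures
#'
#' The package ships the two published 15-row candidate tables
#' (hypermethylated-downregulated and hypomethylated-upregulated genes) as
#' plain-text fixtures. On load the tables are integrity-checked: 15 rows
#' each, and the printed `beta_change` must equal the recomputed
#' `|beta_case_avg - beta_control_avg|` within 5e-9.
#'
#' @return list of two data.frames `table1` (hyper-down) and `table2`
#'   (hypo-up) with canonical lower-case columns plus the signed
#'   `delta_beta` re-derived from the group means, in the schema accepted
#'   by [rankCandidates()].
#' @export
loadFixtureTables <- function() {
  readFix <- function(name) {
    path <- system.file("extdata", name, package = "methexint")
    if (!nzchar(path)) stop("fixture not installed: ", name)
    d <- read.delim(path, stringsAsFactors = FALSE,
                    na.strings = character(0))
    if (nrow(d) != 15)
      stop("fixture integrity error: ", name, " must have 15 rows")
    err <- abs(abs(d$beta_case_avg - d$beta_control_avg) - d$beta_change)
    if (any(err > 5e-9))
      stop("fixture integrity error: beta_change does not re-derive in ",
           name)
    data.frame(probe_id = d$Probe_ID, gene = d$Gene,
               beta_case_avg = d$beta_case_avg,
               beta_control_avg = d$beta_control_avg,
               beta_change = d$beta_change,
               delta_beta = d$beta_case_avg - d$beta_control_avg,
               abs_delta_beta = d$beta_change,
               island_relation = ifelse(nzchar(d$RELATION_TO_CPG_ISLAND),
                                        d$RELATION_TO_CPG_ISLAND,
                                        "OpenSea"),
               log2fc = d$log2FoldChange, padj = d$padj,
               stringsAsFactors = FALSE)
  }
  list(table1 = readFix("table1_hyper_down.tsv"),
       table2 = readFix("table2_hypo_up.tsv"))
}
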