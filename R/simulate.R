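#' Simulation parameters for a matched case/control multi-omics study
#'
#' Defines the conditions of a synthetic paired-tissue study: matched
#' case/control sample pairs profiled on a 450K-style methylation array and
#' by RNA-seq, with planted differential methylation, planted differential
#' expression, and a configurable negative coupling between promoter
#' methylation and expression.
#'
#' @param nPairs number of matched sample pairs (>= 2); each pair contributes
#'   one case and one control column to both assays.
#' @param nProbes number of array probes (>= `nGenes`).
#' @param nGenes number of genes.
#' @param fracDml fraction of probes with a planted methylation difference.
#' @param deltaBetaEffect planted |delta-beta| (case minus control group mean),
#'   in `[0, 1]`.
#' @param fracDeg fraction of genes with a planted expression difference.
#' @param lfcEffect planted |log2 fold change| for differential genes (>= 0).
#' @param nbDispersion negative-binomial dispersion alpha (> 0); count
#'   variance is `mu + alpha * mu^2`.
#' @param couplingStrength coupling between a planted promoter delta-beta and
#'   its gene's log2 fold change, in `[-1, 0]`; `-1` means a planted promoter
#'   hypermethylation of `deltaBetaEffect` depresses expression by the full
#'   `lfcEffect`.
#' @param baseDepth expected library size (sum of expected counts per sample).
#' @param betaPrecision precision phi of the Beta(mu * phi, (1 - mu) * phi)
#'   noise model around each probe's group mean.
#' @param librarySdLog sd (log scale) of the log-normal per-sample library
#'   size factors.
#' @param seed integer seed; identical configurations reproduce bit-identical
#'   datasets.
#' @return A validated `SimulationConfig` (list).
#' @export
simulationConfig <- function(nPairs = 6, nProbes = 6000, nGenes = 1200,
                             fracDml = 0.1, deltaBetaEffect = 0.3,
                             fracDeg = 0.1, lfcEffect = 2,
                             nbDispersion = 0.05, couplingStrength = -1,
                             baseDepth = 1e6, betaPrecision = 40,
                             librarySdLog = 0.2, seed = 1) {
  stopifnot(is.numeric(nPairs), is.numeric(nProbes), is.numeric(nGenes))
  if (nPairs < 2) stop("nPairs must be >= 2")
  if (nGenes < 1 || nProbes < nGenes)
    stop("need nProbes >= nGenes >= 1")
  for (f in c(fracDml, fracDeg))
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  if (deltaBetaEffect < 0 || deltaBetaEffect > 1)
    stop("deltaBetaEffect must lie in [0, 1]")
  if (lfcEffect < 0) stop("lfcEffect must be >= 0")
  if (nbDispersion <= 0) stop("nbDispersion must be > 0")
  if (couplingStrength < -1 || couplingStrength > 0)
    stop("couplingStrength must lie in [-1, 0]")
  if (baseDepth <= 0 || betaPrecision <= 0 || librarySdLog < 0)
    stop("baseDepth and betaPrecision must be positive")
  cfg <- list(nPairs = as.integer(nPairs), nProbes = as.integer(nProbes),
              nGenes = as.integer(nGenes), fracDml = fracDml,
              deltaBetaEffect = deltaBetaEffect, fracDeg = fracDeg,
              lfcEffect = lfcEffect, nbDispersion = nbDispersion,
              couplingStrength = couplingStrength, baseDepth = baseDepth,
              betaPrecision = betaPrecision, librarySdLog = librarySdLog,
              seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  cfg
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat("SimulationConfig:\n")
  cat(sprintf("  %d pairs, %d probes, %d genes, seed %d\n",
              x$nPairs, x$nProbes, x$nGenes, x$seed))
  cat(sprintf("  planted DML: %.0f%% at |delta-beta| %.2f; planted DEG: %.0f%% at |log2FC| %.1f\n",
              100 * x$fracDml, x$deltaBetaEffect, 100 * x$fracDeg,
              x$lfcEffect))
  cat(sprintf("  NB dispersion %.3f, promoter coupling %.2f\n",
              x$nbDispersion, x$couplingStrength))
  invisible(x)
}

# region layout of a synthetic gene, relative to its TSS (plus-strand
# geometry; spans chosen so every region class is sampleable)
.GENE_REGIONS <- list(
  TSS1500  = c(-1500L, -201L),
  TSS200   = c(-200L,  -1L),
  `1stExon` = c(0L, 299L),
  `5UTR`   = c(300L, 799L),
  Body     = c(800L, 9499L),
  `3UTR`   = c(9500L, 9999L))

.REGION_WEIGHTS <- c(TSS1500 = 0.16, TSS200 = 0.12, `1stExon` = 0.08,
                     `5UTR` = 0.10, Body = 0.44, `3UTR` = 0.10)

#' Generate a synthetic probe manifest with gene models and CpG islands
#'
#' Lays synthetic genes along 22 chromosomes (10 kb genes, 50 kb spacing),
#' places CpG islands of 300-2000 bp (near 60% of TSSs plus some intergenic
#' ones), and scatters probes over gene region classes (`TSS1500`, `TSS200`,
#' `5UTR`, `1stExon`, `Body`, `3UTR`) and intergenic space. Every probe's
#' island relation is computed from its position and the island intervals
#' with [classifyIslandRelation()], so stored annotation and geometry agree
#' by construction. About 10% of genic probes carry a second region
#' annotation (emulating overlapping transcripts).
#'
#' @param nProbes,nGenes positive integers, `nProbes >= nGenes`.
#' @param seed integer seed.
#' @param fracIntergenic fraction of probes placed outside any gene.
#' @return list with elements `manifest` (data.frame: `probe_id`, `chrom`,
#'   `pos`, `strand`, `UCSC_RefGene_Name`, `UCSC_RefGene_Group`,
#'   `Relation_to_UCSC_CpG_Island`), `genes` (gene models with TSS), and
#'   `islands` (1-based inclusive intervals).
#' @export
generateManifest <- function(nProbes, nGenes, seed = 1,
                             fracIntergenic = 0.3) {
  if (nProbes < 1 || nGenes < 1) stop("nProbes and nGenes must be positive")
  if (nProbes < nGenes) stop("need nProbes >= nGenes")
  set.seed(as.integer(seed))

  chroms <- paste0("chr", seq_len(22))
  geneChrom <- chroms[((seq_len(nGenes) - 1L) %% 22L) + 1L]
  slot <- ((seq_len(nGenes) - 1L) %/% 22L)
  tss <- 50000L + slot * 50000L
  genes <- data.frame(gene = sprintf("G%04d", seq_len(nGenes)),
                      chrom = geneChrom, tss = tss,
                      strand = sample(c("+", "-"), nGenes, replace = TRUE),
                      stringsAsFactors = FALSE)

  # islands: near TSS for ~60% of genes, plus intergenic ones in the gaps
  hasIsl <- runif(nGenes) < 0.6
  len <- as.integer(round(runif(sum(hasIsl), 300, 2000)))
  islTss <- data.frame(chrom = genes$chrom[hasIsl],
                       start = genes$tss[hasIsl] - len %/% 2L)
  islTss$end <- islTss$start + len - 1L
  nExtra <- max(1L, round(0.2 * nGenes))
  exG <- sample(nGenes, nExtra, replace = TRUE)
  exLen <- as.integer(round(runif(nExtra, 300, 2000)))
  exStart <- genes$tss[exG] + as.integer(round(runif(nExtra, 20000, 35000)))
  islands <- rbind(islTss,
                   data.frame(chrom = genes$chrom[exG], start = exStart,
                              end = exStart + exLen - 1L))
  islands <- islands[order(islands$chrom, islands$start), , drop = FALSE]
  rownames(islands) <- NULL

  nInter <- round(fracIntergenic * nProbes)
  nGenic <- nProbes - nInter
  gIdx <- sample(nGenes, nGenic, replace = TRUE)
  cls <- sample(names(.REGION_WEIGHTS), nGenic, replace = TRUE,
                prob = .REGION_WEIGHTS)
  off <- vapply(cls, function(cl) {
    r <- .GENE_REGIONS[[cl]]
    as.integer(round(runif(1, r[1], r[2])))
  }, integer(1))
  posGenic <- genes$tss[gIdx] + off
  geneName <- genes$gene[gIdx]
  # second annotation for ~10% of genic probes: same locus, another class
  second <- runif(nGenic) < 0.1
  cls2 <- ifelse(second,
                 vapply(cls, function(cl)
                   sample(setdiff(names(.GENE_REGIONS), cl), 1), ""),
                 "")
  annName <- ifelse(second, paste(geneName, geneName, sep = ";"), geneName)
  annGroup <- ifelse(second, paste(cls, cls2, sep = ";"), cls)

  interG <- sample(nGenes, nInter, replace = TRUE)
  posInter <- genes$tss[interG] +
    as.integer(round(runif(nInter, 12000, 38000)))

  manifest <- data.frame(
    probe_id = sprintf("cg%08d", seq_len(nProbes)),
    chrom = c(genes$chrom[gIdx], genes$chrom[interG]),
    pos = c(posGenic, posInter),
    strand = sample(c("+", "-"), nProbes, replace = TRUE),
    UCSC_RefGene_Name = c(annName, rep("", nInter)),
    UCSC_RefGene_Group = c(annGroup, rep("", nInter)),
    stringsAsFactors = FALSE)

  rel <- character(nProbes)
  for (ch in unique(manifest$chrom)) {
    i <- manifest$chrom == ch
    isl <- islands[islands$chrom == ch, , drop = FALSE]
    rel[i] <- classifyIslandRelation(manifest$pos[i], isl$start, isl$end)
  }
  manifest$Relation_to_UCSC_CpG_Island <- rel
  list(manifest = manifest, genes = genes, islands = islands)
}

#' Simulate a beta-value matrix with planted differential methylation
#'
#' Each probe gets a baseline mean drawn from a bimodal Beta(0.4, 0.4)
#' squeezed to `[0.03, 0.97]`; per-sample values are Beta-distributed around
#' the group mean with precision `betaPrecision`. A fraction `fracDml` of
#' probes is planted with a signed case-group shift of `deltaBetaEffect`
#' (baselines for planted probes are drawn so the shifted mean stays inside
#' `(0, 1)`; shifts that would still escape are clamped with a warning).
#'
#' @param manifest result of [generateManifest()] (list) or its `manifest`
#'   data.frame.
#' @param config a [simulationConfig()].
#' @return list with `meth` (a [MethylationSet-class]) and `truth`
#'   (data.frame of planted probes: `probe_id`, `delta_beta`).
#' @export
generateMethylation <- function(manifest, config) {
  man <- if (is.data.frame(manifest)) manifest else manifest$manifest
  stopifnot(inherits(config, "SimulationConfig"))
  if (nrow(man) != config$nProbes)
    stop("manifest size does not match config$nProbes")
  set.seed(config$seed + 1L)
  n <- config$nProbes
  d <- config$deltaBetaEffect

  muCtrl <- 0.03 + 0.94 * rbeta(n, 0.4, 0.4)
  nDml <- round(config$fracDml * n)
  planted <- if (nDml > 0) sort(sample(n, nDml)) else integer(0)
  sgn <- sample(c(1, -1), length(planted), replace = TRUE)
  lo <- 0.03; hi <- 0.97
  if (length(planted)) {
    # draw planted baselines so mu and mu + sgn*d both fit in [lo, hi]
    up <- sgn > 0
    muCtrl[planted[up]] <- runif(sum(up), lo, max(lo, hi - d))
    muCtrl[planted[!up]] <- runif(sum(!up), min(hi, lo + d), hi)
  }
  muCase <- muCtrl
  muCase[planted] <- muCtrl[planted] + sgn * d
  if (any(muCase < lo - 1e-12 | muCase > hi + 1e-12)) {
    warning("planted shifts clamped to keep group means inside (0, 1)")
    muCase <- pmin(pmax(muCase, 0.01), 0.99)
  }

  # shape1 = mu*phi, shape2 = (1-mu)*phi; vectorised over the full matrix
  phi <- config$betaPrecision
  caseMat <- matrix(rbeta(n * config$nPairs, rep(muCase * phi, config$nPairs),
                          rep((1 - muCase) * phi, config$nPairs)), nrow = n)
  ctrlMat <- matrix(rbeta(n * config$nPairs, rep(muCtrl * phi, config$nPairs),
                          rep((1 - muCtrl) * phi, config$nPairs)), nrow = n)
  beta <- cbind(caseMat, ctrlMat)
  beta <- pmin(pmax(beta, 1e-6), 1 - 1e-6)
  rownames(beta) <- man$probe_id

  group <- rep(c("case", "control"), each = config$nPairs)
  pair <- rep(sprintf("P%02d", seq_len(config$nPairs)), 2)
  ms <- MethylationSet(beta, group, pair,
                       sampleIds = paste(group, pair, sep = "_"))
  truth <- data.frame(probe_id = man$probe_id[planted],
                      delta_beta = sgn * d, stringsAsFactors = FALSE)
  list(meth = ms, truth = truth)
}

#' Simulate an RNA-seq count matrix with planted effects and promoter coupling
#'
#' Gene abundances are log-normal and scaled so expected library size is
#' `baseDepth`; counts are negative-binomial with dispersion `nbDispersion`
#' and log-normal per-sample library factors. A fraction `fracDeg` of genes
#' gets a signed `lfcEffect`. Additionally, every gene whose promoter
#' (TSS1500/TSS200) carries a planted differentially methylated probe is
#' coupled: its log2 fold change is set to
#' `couplingStrength * delta_beta * lfcEffect / deltaBetaEffect`, so at
#' `couplingStrength = -1` promoter hypermethylation fully represses the gene.
#'
#' @param manifest result of [generateManifest()].
#' @param config a [simulationConfig()].
#' @param methTruth the `truth` data.frame from [generateMethylation()].
#' @return list with `rna` (an [RnaCountSet-class]) and `truth` (list:
#'   `dml` planted probes, `deg` planted genes with `log2fc` and `source`
#'   ("planted" or "coupled"), `coupled` gene-to-probe map).
#' @export
generateCounts <- function(manifest, config, methTruth) {
  stopifnot(inherits(config, "SimulationConfig"))
  genes <- manifest$genes
  man <- manifest$manifest
  set.seed(config$seed + 2L)
  nG <- config$nGenes
  nS <- 2L * config$nPairs

  w <- rlnorm(nG, meanlog = 0, sdlog = 1)
  mu0 <- config$baseDepth * w / sum(w)

  # promoter-coupled genes: planted DML probes annotated TSS1500/TSS200
  coupled <- data.frame(gene = character(0), probe_id = character(0),
                        delta_beta = numeric(0))
  if (nrow(methTruth) > 0 && config$deltaBetaEffect > 0) {
    mrows <- man[match(methTruth$probe_id, man$probe_id), ]
    for (i in seq_len(nrow(mrows))) {
      gs <- strsplit(mrows$UCSC_RefGene_Name[i], ";", fixed = TRUE)[[1]]
      cl <- strsplit(mrows$UCSC_RefGene_Group[i], ";", fixed = TRUE)[[1]]
      keep <- cl %in% PROMOTER_CLASSES
      for (g in unique(gs[keep]))
        coupled <- rbind(coupled, data.frame(
          gene = g, probe_id = mrows$probe_id[i],
          delta_beta = methTruth$delta_beta[i]))
    }
    if (nrow(coupled) > 0) {
      # one probe per gene: keep the largest |delta beta|
      o <- order(coupled$gene, -abs(coupled$delta_beta), coupled$probe_id)
      coupled <- coupled[o, ][!duplicated(coupled$gene[o]), , drop = FALSE]
      rownames(coupled) <- NULL
    }
  }

  lfc <- numeric(nG)
  names(lfc) <- genes$gene
  src <- rep("", nG)
  if (nrow(coupled) > 0) {
    idx <- match(coupled$gene, genes$gene)
    lfc[idx] <- config$couplingStrength * coupled$delta_beta *
      config$lfcEffect / config$deltaBetaEffect
    src[idx] <- "coupled"
  }
  nDeg <- round(config$fracDeg * nG)
  free <- which(src == "")
  degIdx <- if (nDeg > 0) sort(sample(free, min(nDeg, length(free))))
            else integer(0)
  lfc[degIdx] <- sample(c(1, -1), length(degIdx), replace = TRUE) *
    config$lfcEffect
  src[degIdx] <- "planted"

  libF <- rlnorm(nS, 0, config$librarySdLog)
  group <- rep(c("case", "control"), each = config$nPairs)
  muMat <- outer(mu0, libF) * 2 ^ outer(lfc, as.numeric(group == "case"))
  cnt <- matrix(rnbinom(nG * nS, mu = muMat, size = 1 / config$nbDispersion),
                nrow = nG)
  rownames(cnt) <- genes$gene
  pair <- rep(sprintf("P%02d", seq_len(config$nPairs)), 2)
  rs <- RnaCountSet(cnt, group, pair,
                    sampleIds = paste(group, pair, sep = "_"))

  degTruth <- data.frame(gene = genes$gene, log2fc = lfc,
                         base_mean = mu0, source = src,
                         stringsAsFactors = FALSE)
  degTruth <- degTruth[degTruth$source != "", , drop = FALSE]
  rownames(degTruth) <- NULL
  list(rna = rs,
       truth = list(dml = methTruth, deg = degTruth, coupled = coupled))
}

#' Simulate a complete matched case/control study
#'
#' Convenience wrapper running [generateManifest()], [generateMethylation()]
#' and [generateCounts()] under one configuration.
#'
#' @param config a [simulationConfig()].
#' @return list with `manifest`, `genes`, `islands`, `meth`
#'   ([MethylationSet-class]), `rna` ([RnaCountSet-class]) and `truth`.
#' @examples
#' study <- simulateStudy(simulationConfig(nProbes = 300, nGenes = 60,
#'                                         nPairs = 4, seed = 7))
#' study$meth
#' @export
simulateStudy <- function(config = simulationConfig()) {
  mf <- generateManifest(config$nProbes, config$nGenes, seed = config$seed)
  me <- generateMethylation(mf, config)
  rn <- generateCounts(mf, config, me$truth)
  list(manifest = mf$manifest, genes = mf$genes, islands = mf$islands,
       meth = me$meth, rna = rn$rna, truth = rn$truth)
}

#' Write a simulated study to disk as plain-text tables
#'
#' Writes manifest, beta matrix, count matrix and sample sheet as TSV and the
#' planted truth as JSON, the formats consumed by [runPipeline()].
#'
#' @param study result of [simulateStudy()].
#' @param outdir output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
writeStudy <- function(study, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- c(manifest = file.path(outdir, "manifest.tsv"),
         beta = file.path(outdir, "beta.tsv"),
         counts = file.path(outdir, "counts.tsv"),
         samples = file.path(outdir, "samples.tsv"),
         truth = file.path(outdir, "truth.json"))
  writeTsv(study$manifest, p["manifest"])
  b <- data.frame(probe_id = rownames(betaValues(study$meth)),
                  betaValues(study$meth), check.names = FALSE)
  writeTsv(b, p["beta"])
  k <- data.frame(gene = rownames(counts(study$rna)), counts(study$rna),
                  check.names = FALSE)
  writeTsv(k, p["counts"])
  ss <- data.frame(sample_id = colnames(study$meth),
                   group = sampleGroups(study$meth),
                   pair_id = pairIds(study$meth))
  writeTsv(ss, p["samples"])
  jsonlite::write_json(study$truth, p["truth"], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(p)
}
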