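#' Quadrant of a gene in delta-beta / log2-fold-change space
#'
#' The joint methylation-expression plane is split by the axes: `part1` =
#' hypomethylated and upregulated (`delta < 0, lfc > 0`), `part2` = hyper-up,
#' `part3` = hypo-down, `part4` = hypermethylated and downregulated; a value
#' exactly on an axis is `boundary` and excluded from quadrant counts.
#' Parts 1 and 4 are the anti-correlated quadrants expected when promoter
#' methylation represses transcription.
#'
#' @param deltaBeta,log2fc finite numeric vectors (recycled to equal
#'   length).
#' @return Character vector of `"part1"`..`"part4"`/`"boundary"`.
#' @examples
#' assignQuadrant(c(0.36, -0.53, 0), c(-4.7, 2.95, 2))
#' @export
assignQuadrant <- function(deltaBeta, log2fc) {
  n <- max(length(deltaBeta), length(log2fc))
  deltaBeta <- rep_len(deltaBeta, n); log2fc <- rep_len(log2fc, n)
  if (any(!is.finite(deltaBeta)) || any(!is.finite(log2fc)))
    stop("inputs must be finite")
  ifelse(deltaBeta == 0 | log2fc == 0, "boundary",
  ifelse(deltaBeta < 0 & log2fc > 0, "part1",
  ifelse(deltaBeta > 0 & log2fc > 0, "part2",
  ifelse(deltaBeta < 0 & log2fc < 0, "part3", "part4"))))
}

#' Join differential methylation and expression results at gene level
#'
#' Expands significant DM loci to their annotated genes via the manifest,
#' chooses one representative locus per gene (largest `|delta beta|`, ties
#' broken by lower p-value then lexicographic probe id), flags the gene
#' promoter-related when the representative locus is annotated TSS1500 or
#' TSS200 for that gene, and merges the expression results by gene symbol.
#' Genes without an expression measurement are dropped and counted.
#'
#' @param dml result of [callDML()]; only rows with `significant = TRUE`
#'   are used (a pre-filtered table also works).
#' @param manifest manifest data.frame covering the DML probes.
#' @param de result of [nbWaldTest()] (full table, all measured genes).
#' @return data.frame: `gene`, `probe_id`, `beta_case_avg`,
#'   `beta_control_avg`, `delta_beta`, `abs_delta_beta`, `island_relation`,
#'   `region_group`, `promoter_related`, `log2fc`, `padj`, `quadrant`;
#'   attribute `"n_dropped"` counts DM genes missing from the expression
#'   table.
#' @export
joinDmDe <- function(dml, manifest, de) {
  if ("significant" %in% colnames(dml))
    dml <- dml[dml$significant, , drop = FALSE]
  if (nrow(dml) == 0) {
    warning("no significant DM loci to integrate")
    out <- data.frame(gene = character(0))
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  man <- annotateRegionGroups(manifest)
  mi <- match(dml$probe_id, man$probe_id)
  if (anyNA(mi)) stop("DML probes missing from manifest")
  ann <- parseGeneAnnotations(man$UCSC_RefGene_Name[mi],
                              man$UCSC_RefGene_Group[mi])
  pieces <- lapply(seq_len(nrow(dml)), function(i) {
    a <- ann[[i]]
    if (nrow(a) == 0) return(NULL)
    data.frame(gene = unique(a$gene), row = i, stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, pieces)
  if (is.null(long) || nrow(long) == 0) {
    warning("no significant DM locus is annotated to a gene")
    out <- data.frame(gene = character(0))
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  # representative locus per gene: max |delta beta|, then min p, then probe id
  o <- order(long$gene, -dml$abs_delta_beta[long$row],
             dml$p_value[long$row], dml$probe_id[long$row])
  long <- long[o, , drop = FALSE]
  rep1 <- long[!duplicated(long$gene), , drop = FALSE]

  i <- rep1$row
  mi1 <- mi[i]
  promoter <- vapply(seq_len(nrow(rep1)), function(j) {
    a <- ann[[rep1$row[j]]]
    any(a$gene == rep1$gene[j] & a$region_class %in% PROMOTER_CLASSES)
  }, logical(1))
  rec <- data.frame(
    gene = rep1$gene,
    probe_id = dml$probe_id[i],
    beta_case_avg = dml$beta_case_avg[i],
    beta_control_avg = dml$beta_control_avg[i],
    delta_beta = dml$delta_beta[i],
    abs_delta_beta = dml$abs_delta_beta[i],
    island_relation = man$Relation_to_UCSC_CpG_Island[mi1],
    region_group = man$region_group[mi1],
    promoter_related = promoter,
    stringsAsFactors = FALSE)
  di <- match(rec$gene, de$gene)
  dropped <- sum(is.na(di))
  rec <- rec[!is.na(di), , drop = FALSE]
  di <- di[!is.na(di)]
  rec$log2fc <- de$log2fc[di]
  rec$padj <- de$padj[di]
  rec$quadrant <- assignQuadrant(rec$delta_beta, rec$log2fc)
  rownames(rec) <- NULL
  attr(rec, "n_dropped") <- dropped
  rec
}

#' Methylation-expression correlation per genomic region group
#'
#' Pearson correlation between the signed delta-beta and the log2 fold
#' change of the integrated records, within each of the six gene-linked
#' region groups. Groups with fewer than 3 genes, or zero variance in
#' either variable, are reported with `NA`.
#'
#' @param records result of [joinDmDe()].
#' @return data.frame: `region_group`, `pearson_r`, `p_value` (two-sided,
#'   t-distribution with n-2 df), `n_genes`.
#' @export
regionCorrelation <- function(records) {
  groups <- setdiff(REGION_GROUPS, "Intergenic")
  out <- lapply(groups, function(g) {
    r <- records[records$region_group == g, , drop = FALSE]
    n <- nrow(r)
    if (n < 3 || var(r$delta_beta) == 0 || var(r$log2fc) == 0)
      return(data.frame(region_group = g, pearson_r = NA_real_,
                        p_value = NA_real_, n_genes = n))
    ct <- cor.test(r$delta_beta, r$log2fc, method = "pearson")
    data.frame(region_group = g, pearson_r = unname(ct$estimate),
               p_value = ct$p.value, n_genes = n)
  })
  do.call(rbind, out)
}

#' Promoter-/enhancer-related DMG partition with quadrant counts
#'
#' Splits integrated records into promoter-related genes (representative
#' locus in TSS1500/TSS200) and enhancer-related genes (any other
#' significant locus, the complementary "not promoter" definition) and
#' tallies quadrant membership. Percentages use the partition total as
#' denominator and are rounded to one decimal (round-half-even).
#'
#' @param records result of [joinDmDe()].
#' @return data.frame: `partition` (`"promoter"`/`"enhancer"`), `quadrant`,
#'   `count`, `percentage`.
#' @export
classifyDMGs <- function(records) {
  part <- ifelse(records$promoter_related, "promoter", "enhancer")
  out <- lapply(c("promoter", "enhancer"), function(p) {
    r <- records[part == p, , drop = FALSE]
    tab <- table(factor(r$quadrant, levels = QUADRANTS))
    data.frame(partition = p, quadrant = names(tab),
               count = as.integer(tab),
               percentage = if (nrow(r) > 0)
                 round(100 * as.integer(tab) / nrow(r), 1) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Top candidate tables ranked by delta-beta
#'
#' Builds the two candidate tables: hypermethylated-downregulated
#' (`delta_beta > 0`, `log2fc < 0`) and hypomethylated-upregulated
#' (`delta_beta < 0`, `log2fc > 0`), both additionally gated on the
#' expression significance criteria (`padj < padjThreshold`,
#' `|log2fc| >= lfcThreshold`), ranked by decreasing `|delta beta|` (ties:
#' lower `padj`, then gene symbol), truncated to the top `k` genes.
#'
#' @param records result of [joinDmDe()] (or a table carrying the same
#'   columns, e.g. [loadFixtureTables()] output).
#' @param k rows to keep per table (default 15).
#' @param padjThreshold,lfcThreshold expression gates (defaults 0.05, 1).
#' @return list of two data.frames, `hyperDown` and `hypoUp`, in the
#'   candidate-table schema (`Probe_ID`, `Gene`, `beta_case_avg`,
#'   `beta_control_avg`, `beta_change`, `RELATION_TO_CPG_ISLAND`,
#'   `log2FoldChange`, `padj`); `beta_change` is the absolute delta-beta.
#' @export
rankCandidates <- function(records, k = 15, padjThreshold = 0.05,
                           lfcThreshold = 1) {
  gate <- records$padj < padjThreshold &
    abs(records$log2fc) >= lfcThreshold
  fmt <- function(r) {
    o <- order(-r$abs_delta_beta, r$padj, r$gene)
    r <- head(r[o, , drop = FALSE], k)
    isl <- if ("island_relation" %in% colnames(r)) r$island_relation
           else rep("", nrow(r))
    data.frame(Probe_ID = r$probe_id, Gene = r$gene,
               beta_case_avg = r$beta_case_avg,
               beta_control_avg = r$beta_control_avg,
               beta_change = r$abs_delta_beta,
               RELATION_TO_CPG_ISLAND = isl,
               log2FoldChange = r$log2fc, padj = r$padj,
               stringsAsFactors = FALSE, row.names = NULL)
  }
  list(hyperDown = fmt(records[gate & records$delta_beta > 0 &
                                 records$log2fc < 0, , drop = FALSE]),
       hypoUp = fmt(records[gate & records$delta_beta < 0 &
                              records$log2fc > 0, , drop = FALSE]))
}

#' Remove previously reported genes from a candidate table
#'
#' @param table candidate table with a `Gene` (or `gene`) column.
#' @param exclusionList character vector of gene symbols to drop.
#' @return Filtered table; attribute `"removed"` lists the dropped genes.
#' @export
filterReported <- function(table, exclusionList) {
  col <- if ("Gene" %in% colnames(table)) "Gene" else "gene"
  drop <- table[[col]] %in% exclusionList
  out <- table[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- table[[col]][drop]
  out
}
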