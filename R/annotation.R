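#' Classify a probe position relative to CpG islands
#'
#' Assigns each position the standard 450K island relation: `Island` inside
#' an island, `N_Shore`/`S_Shore` within 2 kb of the lower-/higher-coordinate
#' edge, `N_Shelf`/`S_Shelf` within the next 2 kb, `OpenSea` beyond 4 kb.
#' With several islands on the chromosome the nearest island decides (edge
#' distance, 0 inside); ties are broken toward the lower-coordinate island.
#' Coordinates are 1-based inclusive.
#'
#' @param pos integer vector of probe positions.
#' @param islandStart,islandEnd equal-length vectors of island intervals
#'   (1-based inclusive, `start <= end`). Empty vectors classify everything
#'   as `OpenSea`.
#' @return Character vector of island relations, one per position.
#' @examples
#' classifyIslandRelation(c(10200, 9500, 14400), 10000, 10500)
#' @export
classifyIslandRelation <- function(pos, islandStart, islandEnd) {
  if (length(islandStart) != length(islandEnd))
    stop("islandStart and islandEnd must have equal length")
  if (length(islandStart) == 0)
    return(rep("OpenSea", length(pos)))
  islandStart <- as.numeric(islandStart)
  islandEnd <- as.numeric(islandEnd)
  if (any(islandStart > islandEnd) || any(islandStart < 1))
    stop("invalid island interval: need 1 <= start <= end")
  o <- order(islandStart, islandEnd)
  s <- islandStart[o]; e <- islandEnd[o]
  vapply(as.numeric(pos), function(p) {
    # signed offset from each island: 0 inside, <0 upstream (N side)
    off <- ifelse(p < s, p - s, ifelse(p > e, p - e, 0))
    d <- abs(off)
    i <- which(d == min(d))[1]  # islands sorted by start: tie -> lower coord
    dp <- off[i]
    if (dp == 0) "Island"
    else if (dp < 0) {
      if (dp >= -2000) "N_Shore" else if (dp >= -4000) "N_Shelf"
      else "OpenSea"
    } else {
      if (dp <= 2000) "S_Shore" else if (dp <= 4000) "S_Shelf"
      else "OpenSea"
    }
  }, character(1))
}

#' Parse semicolon-delimited manifest gene annotations
#'
#' @param geneField,groupField character vectors from the manifest columns
#'   `UCSC_RefGene_Name` and `UCSC_RefGene_Group` (parallel, semicolon
#'   delimited; empty string = intergenic probe).
#' @return List (one element per probe) of data.frames with columns `gene`,
#'   `region_class`, deduplicated per (gene, class) pair.
#' @export
parseGeneAnnotations <- function(geneField, groupField) {
  mapply(function(g, r) {
    if (is.na(g) || !nzchar(g))
      return(data.frame(gene = character(0), region_class = character(0)))
    gs <- strsplit(g, ";", fixed = TRUE)[[1]]
    rs <- strsplit(r, ";", fixed = TRUE)[[1]]
    if (length(gs) != length(rs))
      stop("gene and region annotation fields differ in length")
    unique(data.frame(gene = gs, region_class = rs,
                      stringsAsFactors = FALSE))
  }, geneField, groupField, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Assign the six-way genomic region group of a probe
#'
#' Collapses a probe's region-class annotations to one group: no annotation
#' is `Intergenic`; only promoter classes (TSS1500/TSS200) is `Promoter`;
#' exactly one distinct class maps to itself (`Body` becomes `GeneBody`);
#' two or more distinct classes (across any genes) is `MultipleLocations`.
#'
#' @param annotations data.frame with a `region_class` column (one row per
#'   gene annotation of the probe), as produced by [parseGeneAnnotations()].
#' @return One of `"1stExon"`, `"3UTR"`, `"5UTR"`, `"GeneBody"`,
#'   `"MultipleLocations"`, `"Promoter"`, `"Intergenic"`.
#' @export
assignRegionGroup <- function(annotations) {
  cls <- unique(annotations$region_class)
  cls <- cls[nzchar(cls)]
  bad <- setdiff(cls, REGION_CLASSES)
  if (length(bad))
    stop("unknown region class: ", paste(bad, collapse = ", "))
  if (length(cls) == 0) return("Intergenic")
  if (all(cls %in% PROMOTER_CLASSES)) return("Promoter")
  if (length(cls) == 1)
    return(switch(cls, Body = "GeneBody", cls))
  "MultipleLocations"
}

#' Annotate a manifest with region groups
#'
#' @param manifest manifest data.frame (see [readManifest()]).
#' @return The manifest with an added `region_group` column.
#' @export
annotateRegionGroups <- function(manifest) {
  ann <- parseGeneAnnotations(manifest$UCSC_RefGene_Name,
                              manifest$UCSC_RefGene_Group)
  manifest$region_group <- vapply(ann, assignRegionGroup, character(1))
  manifest
}

#' Region and island distribution of differentially methylated loci
#'
#' Tallies, separately for hyper- and hypomethylated loci, the proportion of
#' loci per genomic region group and per CpG-island relation.
#'
#' @param dml data.frame with columns `probe_id` and `direction`
#'   (`"hyper"`/`"hypo"`), e.g. the significant subset of [callDML()].
#' @param manifest manifest data.frame covering all DML probes.
#' @return list of two data.frames, `region` (`direction`, `region_group`,
#'   `count`, `proportion`) and `island` (same with `island_relation`);
#'   proportions sum to 1 within each direction.
#' @export
dmlRegionDistribution <- function(dml, manifest) {
  miss <- setdiff(dml$probe_id, manifest$probe_id)
  if (length(miss))
    stop("probes missing from manifest: ", paste(head(miss, 3),
                                                 collapse = ", "))
  man <- annotateRegionGroups(manifest)
  i <- match(dml$probe_id, man$probe_id)
  tally <- function(value, levels) {
    do.call(rbind, lapply(split(value, dml$direction), function(v) {
      tab <- table(factor(v, levels = levels))
      data.frame(category = names(tab), count = as.integer(tab),
                 proportion = as.numeric(tab) / length(v))
    }))
  }
  reg <- tally(man$region_group[i], REGION_GROUPS)
  isl <- tally(man$Relation_to_UCSC_CpG_Island[i], ISLAND_RELATIONS)
  reg$direction <- sub("\\..*$", "", rownames(reg))
  isl$direction <- sub("\\..*$", "", rownames(isl))
  rownames(reg) <- rownames(isl) <- NULL
  names(reg)[1] <- "region_group"
  names(isl)[1] <- "island_relation"
  list(region = reg[, c("direction", "region_group", "count", "proportion")],
       island = isl[, c("direction", "island_relation", "count",
                        "proportion")])
}

#' Read a probe manifest TSV
#'
#' Expects columns `probe_id`, `chrom`, `pos`, `strand`,
#' `UCSC_RefGene_Name`, `UCSC_RefGene_Group`,
#' `Relation_to_UCSC_CpG_Island` (multi-annotations semicolon-delimited;
#' blank island relation is read as `OpenSea`).
#'
#' @param path path to the TSV file.
#' @return Manifest data.frame.
#' @export
readManifest <- function(path) {
  man <- read.delim(path, stringsAsFactors = FALSE,
                    na.strings = character(0))
  need <- c("probe_id", "chrom", "pos", "UCSC_RefGene_Name",
            "UCSC_RefGene_Group", "Relation_to_UCSC_CpG_Island")
  miss <- setdiff(need, colnames(man))
  if (length(miss))
    stop("manifest lacks columns: ", paste(miss, collapse = ", "))
  blank <- !nzchar(man$Relation_to_UCSC_CpG_Island)
  man$Relation_to_UCSC_CpG_Island[blank] <- "OpenSea"
  if (any(man$pos < 1)) stop("manifest positions must be >= 1 (1-based)")
  man
}
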