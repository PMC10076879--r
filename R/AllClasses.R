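#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats cor cor.test fisher.test ks.test median p.adjust pnorm
#'   phyper prcomp quantile rbeta rbinom rlnorm rnbinom rnorm runif sd setNames
#'   t.test var wilcox.test
#' @importFrom utils head read.delim write.table packageVersion
NULL

REGION_CLASSES <- c("TSS1500", "TSS200", "5UTR", "1stExon", "Body", "3UTR")
PROMOTER_CLASSES <- c("TSS1500", "TSS200")
ISLAND_RELATIONS <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf",
                      "OpenSea")
REGION_GROUPS <- c("1stExon", "3UTR", "5UTR", "GeneBody", "MultipleLocations",
                   "Promoter", "Intergenic")
QUADRANTS <- c("part1", "part2", "part3", "part4", "boundary")

.validGroups <- function(object) {
  cd <- SummarizedExperiment::colData(object)
  msg <- NULL
  if (!all(c("group", "pair_id") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'group' and 'pair_id'")
  else {
    grp <- as.character(cd$group)
    if (anyNA(grp) || !all(grp %in% c("case", "control")))
      msg <- c(msg, "group must be 'case' or 'control'")
    else if (sum(grp == "case") < 2L || sum(grp == "control") < 2L)
      msg <- c(msg, "each group needs at least 2 samples")
  }
  msg
}

#' Container for a beta-value methylation matrix
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with an assay named
#' `"beta"` holding per-probe methylation proportions in `[0, 1]` and column
#' metadata identifying the case/control group and matched pair of every
#' sample.
#'
#' @aliases MethylationSet-class
#' @seealso [MethylationSet()] for construction, [betaValues()],
#'   [sampleGroups()], [pairIds()] for access.
#' @exportClass MethylationSet
setClass("MethylationSet", contains = "SummarizedExperiment")

setValidity("MethylationSet", function(object) {
  msg <- NULL
  if (!"beta" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'beta' is required")
  else {
    b <- SummarizedExperiment::assay(object, "beta")
    if (anyNA(b) || any(b < 0) || any(b > 1))
      msg <- c(msg, "beta values must be in [0, 1] with no missing values")
  }
  msg <- c(msg, .validGroups(object))
  if (length(msg)) msg else TRUE
})

#' Container for a gene-level RNA-seq count matrix
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with an assay named
#' `"counts"` of non-negative integer read counts (genes x samples) and the
#' same case/control/pair column metadata as [MethylationSet-class].
#'
#' @aliases RnaCountSet-class
#' @seealso [RnaCountSet()], [BiocGenerics::counts()].
#' @exportClass RnaCountSet
setClass("RnaCountSet", contains = "SummarizedExperiment")

setValidity("RnaCountSet", function(object) {
  msg <- NULL
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    x <- SummarizedExperiment::assay(object, "counts")
    if (anyNA(x) || any(x < 0) || any(x != round(x)))
      msg <- c(msg, "counts must be non-negative integers")
  }
  msg <- c(msg, .validGroups(object))
  if (length(msg)) msg else TRUE
})

.makeColData <- function(n, group, pairId, sampleIds) {
  group <- as.character(group)
  if (length(group) != n || length(pairId) != n)
    stop("group and pairId must have one entry per sample column")
  if (is.null(sampleIds))
    sampleIds <- paste0(substr(group, 1, 4), "_", pairId)
  S4Vectors::DataFrame(group = factor(group, levels = c("control", "case")),
                       pair_id = as.character(pairId),
                       row.names = sampleIds)
}

#' Construct a MethylationSet
#'
#' @param beta numeric matrix of beta values (probes x samples), all in
#'   `[0, 1]`.
#' @param group character vector, one of `"case"`/`"control"` per column.
#' @param pairId vector identifying the matched patient pair of each column.
#' @param sampleIds optional column names; defaults to `<group>_<pair>`.
#' @return A [MethylationSet-class] object.
#' @examples
#' b <- matrix(runif(40), nrow = 10)
#' ms <- MethylationSet(b, rep(c("case", "control"), each = 2), c(1, 2, 1, 2))
#' @export
MethylationSet <- function(beta, group, pairId, sampleIds = NULL) {
  beta <- as.matrix(beta)
  if (is.null(rownames(beta)))
    rownames(beta) <- sprintf("probe_%05d", seq_len(nrow(beta)))
  cd <- .makeColData(ncol(beta), group, pairId, sampleIds)
  colnames(beta) <- rownames(cd)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(beta = beta), colData = cd)
  new("MethylationSet", se)
}

#' Construct an RnaCountSet
#'
#' @param counts integer matrix of read counts (genes x samples).
#' @inheritParams MethylationSet
#' @return An [RnaCountSet-class] object.
#' @examples
#' k <- matrix(rpois(40, 50), nrow = 10)
#' rs <- RnaCountSet(k, rep(c("case", "control"), each = 2), c(1, 2, 1, 2))
#' @export
RnaCountSet <- function(counts, group, pairId, sampleIds = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("gene_%05d", seq_len(nrow(counts)))
  cd <- .makeColData(ncol(counts), group, pairId, sampleIds)
  colnames(counts) <- rownames(cd)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd)
  new("RnaCountSet", se)
}

#' Extract the beta-value matrix
#'
#' @param object a [MethylationSet-class].
#' @return Numeric matrix of beta values.
#' @export
setGeneric("betaValues", function(object) standardGeneric("betaValues"))

#' @rdname betaValues
#' @export
setMethod("betaValues", "MethylationSet", function(object)
  SummarizedExperiment::assay(object, "beta"))

#' Case/control group labels of the samples
#'
#' @param object a [MethylationSet-class] or [RnaCountSet-class].
#' @return Character vector of `"case"`/`"control"` labels, named by sample.
#' @export
setGeneric("sampleGroups", function(object) standardGeneric("sampleGroups"))

#' @rdname sampleGroups
#' @export
setMethod("sampleGroups", "SummarizedExperiment", function(object)
  setNames(as.character(SummarizedExperiment::colData(object)$group),
           colnames(object)))

#' Matched-pair identifiers of the samples
#'
#' @param object a [MethylationSet-class] or [RnaCountSet-class].
#' @return Character vector of pair identifiers, named by sample.
#' @export
setGeneric("pairIds", function(object) standardGeneric("pairIds"))

#' @rdname pairIds
#' @export
setMethod("pairIds", "SummarizedExperiment", function(object)
  setNames(as.character(SummarizedExperiment::colData(object)$pair_id),
           colnames(object)))

#' @importFrom BiocGenerics counts
#' @export
BiocGenerics::counts

#' Raw counts of an RnaCountSet
#'
#' @param object an [RnaCountSet-class].
#' @return Integer matrix of counts.
#' @export
setMethod("counts", "RnaCountSet", function(object)
  SummarizedExperiment::assay(object, "counts"))

.showGroups <- function(object) {
  grp <- sampleGroups(object)
  cat(sprintf("samples: %d case / %d control (%d pairs)\n",
              sum(grp == "case"), sum(grp == "control"),
              length(unique(pairIds(object)))))
}

setMethod("show", "MethylationSet", function(object) {
  cat(sprintf("MethylationSet: %d probes x %d samples\n",
              nrow(object), ncol(object)))
  .showGroups(object)
  b <- betaValues(object)
  cat(sprintf("beta range: [%.3f, %.3f]\n", min(b), max(b)))
})

setMethod("show", "RnaCountSet", function(object) {
  cat(sprintf("RnaCountSet: %d genes x %d samples\n",
              nrow(object), ncol(object)))
  .showGroups(object)
  cat(sprintf("median library size: %s\n",
              format(median(colSums(counts(object))), big.mark = ",")))
})
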