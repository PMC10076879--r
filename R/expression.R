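#' Median-of-ratios size factors
#'
#' For each sample, the median over genes (restricted to genes whose counts
#' are positive in every sample, so the geometric mean is positive) of the
#' ratio count / geometric-mean; factors are rescaled to geometric mean 1.
#'
#' @param counts non-negative count matrix (genes x samples).
#' @return Positive numeric vector, one factor per sample.
#' @export
computeSizeFactors <- function(counts) {
  counts <- as.matrix(counts)
  logGeo <- rowMeans(log(counts))
  use <- is.finite(logGeo)
  if (!any(use))
    stop("no gene has positive counts in every sample")
  geo <- exp(logGeo[use])
  sf <- apply(counts[use, , drop = FALSE], 2, function(cnts)
    median(cnts / geo))
  sf / exp(mean(log(sf)))
}

#' Simplified negative-binomial Wald differential expression test
#'
#' A self-contained NB Wald stage: median-of-ratios normalization,
#' per-gene method-of-moments dispersion pooled across groups, fold change
#' on pseudo-mean-stabilised normalized means, and a two-sided p-value for
#' the Wald statistic against a t reference whose df are the pooled
#' within-group replicates. Deliberately simpler than shrinkage-based
#' DE fitters: there is no information sharing across genes and no outlier
#' refitting, which keeps the stage transparent and testable.
#'
#' Per gene `g` with normalized group means `mu_case`, `mu_ctrl` and pooled
#' dispersion `alpha = max(floor, (s^2 - mu) / mu^2)`:
#' `log2fc = log2((mu_case + c) / (mu_ctrl + c))` with pseudo-mean
#' `c = 0.5`, `Var(mu_hat_k) = (mu_k + alpha * mu_k^2) / n_k`, and
#' `Wald z = log2fc / SE` with the delta-method standard error.
#'
#' @param rs an [RnaCountSet-class], or a count matrix together with
#'   `group`.
#' @param group optional character vector of `"case"`/`"control"` labels
#'   when `rs` is a plain matrix.
#' @param pseudoMean fold-change stabilisation constant (default 0.5).
#' @param dispersionFloor lower bound on the dispersion (default 1e-8).
#' @return data.frame (all-zero genes excluded): `gene`, `base_mean`,
#'   `mu_case`, `mu_control`, `dispersion`, `log2fc`, `se`, `stat`,
#'   `p_value`, `padj`, `direction`; attribute `"excluded"` names all-zero
#'   genes, attribute `"size_factors"` the factors used.
#' @export
nbWaldTest <- function(rs, group = NULL, pseudoMean = 0.5,
                       dispersionFloor = 1e-8) {
  if (is(rs, "RnaCountSet")) {
    cnt <- counts(rs)
    group <- sampleGroups(rs)
  } else {
    cnt <- as.matrix(rs)
    if (is.null(group)) stop("group labels required for a plain matrix")
  }
  ci <- which(group == "case"); ki <- which(group == "control")
  if (length(ci) < 2 || length(ki) < 2)
    stop("each group needs at least 2 samples")
  allZero <- rowSums(cnt) == 0
  excluded <- rownames(cnt)[allZero]
  cnt <- cnt[!allZero, , drop = FALSE]

  sf <- computeSizeFactors(cnt)
  y <- sweep(cnt, 2, sf, "/")
  muC <- rowMeans(y[, ci, drop = FALSE])
  muK <- rowMeans(y[, ki, drop = FALSE])
  vC <- apply(y[, ci, drop = FALSE], 1, var)
  vK <- apply(y[, ki, drop = FALSE], 1, var)
  # pooled within-group moments: df-weighted variance, mean of group means
  wC <- length(ci) - 1; wK <- length(ki) - 1
  s2 <- (wC * vC + wK * vK) / (wC + wK)
  mu <- (muC + muK) / 2
  alpha <- pmax(dispersionFloor,
                ifelse(mu > 0, (s2 - mu) / mu^2, dispersionFloor))

  lfc <- log2((muC + pseudoMean) / (muK + pseudoMean))
  varMuC <- (muC + alpha * muC^2) / length(ci)
  varMuK <- (muK + alpha * muK^2) / length(ki)
  se <- sqrt(varMuC / (muC + pseudoMean)^2 +
             varMuK / (muK + pseudoMean)^2) / log(2)
  stat <- ifelse(se > 0, lfc / se, 0)
  # t reference with the pooled within-group df: the moment-based variance
  # is estimated from few replicates, and a normal reference would be
  # anti-conservative at typical RNA-seq group sizes
  pv <- 2 * stats::pt(-abs(stat), df = wC + wK)
  pv <- pmin(pmax(pv, .Machine$double.xmin), 1)
  res <- data.frame(
    gene = rownames(cnt),
    base_mean = rowMeans(y),
    mu_case = muC, mu_control = muK,
    dispersion = alpha,
    log2fc = lfc, se = se, stat = stat,
    p_value = pv, padj = bhAdjust(pv),
    direction = ifelse(lfc >= 0, "up", "down"),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "excluded") <- excluded
  attr(res, "size_factors") <- sf
  res
}

#' Call differentially expressed genes
#'
#' Standard gates: `padj < padjThreshold` and `|log2fc| >= lfcThreshold`.
#'
#' @param res result of [nbWaldTest()] (needs `gene`, `log2fc`, `padj`).
#' @param lfcThreshold fold-change gate (default 1).
#' @param padjThreshold adjusted-p gate (default 0.05).
#' @return list with character vectors `up` and `down`.
#' @export
callDEGs <- function(res, lfcThreshold = 1, padjThreshold = 0.05) {
  if (nrow(res) == 0) stop("empty DE results")
  sig <- res$padj < padjThreshold
  list(up = res$gene[sig & res$log2fc >= lfcThreshold],
       down = res$gene[sig & res$log2fc <= -lfcThreshold])
}

#' PCA of samples on log-normalized counts
#'
#' Transforms to `log2(normalized count + 1)`, centers genes, and projects
#' samples onto the leading principal components by SVD. The sign of each
#' component is fixed so its largest-magnitude gene loading is positive.
#'
#' @param rs an [RnaCountSet-class].
#' @param nComponents components to return (default 2; reduced if fewer are
#'   available).
#' @return list with `coordinates` (samples x components),
#'   `variance_explained` (fractions), and `group` labels.
#' @export
pcaQC <- function(rs, nComponents = 2) {
  stopifnot(is(rs, "RnaCountSet"))
  cnt <- counts(rs)
  if (ncol(cnt) < 3) stop("PCA QC needs at least 3 samples")
  sf <- computeSizeFactors(cnt)
  x <- log2(sweep(cnt, 2, sf, "/") + 1)
  x <- x - rowMeans(x)
  sv <- svd(x)
  k <- min(nComponents, ncol(cnt) - 1)
  coords <- sweep(sv$v[, seq_len(k), drop = FALSE], 2,
                  sv$d[seq_len(k)], "*")
  for (j in seq_len(k)) {
    load <- sv$u[, j]
    if (load[which.max(abs(load))] < 0) {
      coords[, j] <- -coords[, j]
    }
  }
  rownames(coords) <- colnames(cnt)
  colnames(coords) <- paste0("PC", seq_len(k))
  ve <- sv$d^2 / sum(sv$d^2)
  list(coordinates = coords,
       variance_explained = ve[seq_len(k)],
       group = sampleGroups(rs))
}

#' Overlap of two gene lists
#'
#' @param listA,listB character vectors of unique identifiers; `listA` is
#'   the reference whose shared percentage is reported.
#' @return list: `n_common`, `n_a_only`, `n_b_only`, `pct_a_shared`
#'   (`100 * |A intersect B| / |A|`).
#' @export
setOverlap <- function(listA, listB) {
  if (length(listA) == 0) stop("listA must be non-empty")
  if (anyDuplicated(listA) || anyDuplicated(listB))
    stop("lists must contain unique identifiers")
  common <- intersect(listA, listB)
  list(n_common = length(common),
       n_a_only = length(setdiff(listA, listB)),
       n_b_only = length(setdiff(listB, listA)),
       pct_a_shared = 100 * length(common) / length(listA))
}

#' Read a count matrix TSV (first column = gene)
#'
#' @param path TSV path.
#' @return Integer matrix with gene ids as rownames.
#' @export
readCountMatrix <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "numeric"
  m
}
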