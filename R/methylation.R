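#' Beta value from methylated/unmethylated intensities
#'
#' `beta = M / (M + U + offset)`, the standard Illumina form; the offset
#' regularises low-intensity probes and keeps beta strictly below 1.
#'
#' @param M,U non-negative methylated / unmethylated intensities (vectors or
#'   matrices of equal shape).
#' @param offset positive regularisation constant (default 100).
#' @return Beta values in `[0, 1)`.
#' @examples
#' computeBeta(300, 600)   # 0.3
#' @export
computeBeta <- function(M, U, offset = 100) {
  if (any(M < 0) || any(U < 0)) stop("intensities must be non-negative")
  if (offset <= 0) stop("offset must be positive")
  M / (M + U + offset)
}

#' Quantile-normalize a beta matrix
#'
#' Forces every column onto the common distribution given by the row-wise
#' mean of the sorted columns while preserving within-column ranks; tied
#' values receive the mean of the values they span. Delegates to
#' [limma::normalizeQuantiles()].
#'
#' @param x numeric matrix (probes x samples), no missing values unless
#'   `imputeMissing = TRUE`.
#' @param imputeMissing replace missing entries by their row mean before
#'   normalizing.
#' @return Normalized matrix of the same shape and dimnames.
#' @export
quantileNormalizeBeta <- function(x, imputeMissing = FALSE) {
  x <- as.matrix(x)
  if (anyNA(x)) {
    if (!imputeMissing)
      stop("missing values present; set imputeMissing = TRUE to row-mean impute")
    rm <- rowMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- rm[idx[, 1]]
  }
  if (ncol(x) < 2) {
    warning("single column: quantile normalization is the identity")
    return(x)
  }
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Pairwise sample correlation QC
#'
#' Pearson correlation between all sample columns of a beta matrix, the
#' standard reproducibility check before differential methylation analysis.
#' Zero-variance samples are flagged and their correlations reported as
#' `NA`.
#'
#' @param x numeric matrix (probes x samples), at least two columns.
#' @return Correlation matrix with attribute `"flagged"` naming
#'   zero-variance samples.
#' @export
sampleCorrelationQC <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least two samples")
  v <- apply(x, 2, var)
  flagged <- colnames(x)[v == 0]
  r <- suppressWarnings(cor(x))
  diag(r) <- 1
  attr(r, "flagged") <- flagged
  r
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact p by enumeration of rank assignments when the combined sample size
#' is at most `exactThreshold` and there are no ties; otherwise the normal
#' approximation with tie-corrected variance. The continuity correction is
#' off by default: at the group sizes this pipeline targets it makes the
#' discrete p-value distribution markedly conservative near 1, while the
#' uncorrected approximation is closer to uniform under the null. Groups
#' must each hold at least two values.
#'
#' @param x,y numeric vectors for the two groups.
#' @param exactThreshold maximum combined size for the exact test
#'   (default 12).
#' @param correct apply the continuity correction in the approximation.
#' @return Two-sided p-value in `(0, 1]`.
#' @examples
#' wilcoxonRankSum(c(1, 2), c(3, 4))   # 1/3
#' @export
wilcoxonRankSum <- function(x, y, exactThreshold = 12, correct = FALSE) {
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 values")
  if (anyNA(c(x, y))) stop("missing values not allowed")
  ties <- anyDuplicated(c(x, y)) > 0
  if (ties && length(unique(c(x, y))) == 1) return(1)
  useExact <- !ties && (length(x) + length(y)) <= exactThreshold
  p <- suppressWarnings(
    wilcox.test(x, y, exact = useExact, correct = correct)$p.value)
  min(max(p, .Machine$double.xmin), 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment `q(i) = min_{j >= i} m * p(j) / j`, capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same order as the input.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Call differentially methylated loci
#'
#' Per-probe group means, signed delta-beta (case minus control), a
#' two-sided Wilcoxon p-value (rank-sum by default, signed-rank on matched
#' pairs with `paired = TRUE`) and BH-adjusted FDR. A probe is significant
#' when the raw p-value is below `pThreshold` **and** `|delta beta| >=
#' deltaThreshold`; the FDR is reported but is not part of the gate.
#'
#' @param ms a [MethylationSet-class] (beta values already normalized).
#' @param deltaThreshold effect-size gate on `|delta beta|` (default 0.2).
#' @param pThreshold raw p-value gate (default 0.05).
#' @param paired use the Wilcoxon signed-rank test on matched pairs.
#' @param exactThreshold passed to [wilcoxonRankSum()].
#' @return data.frame (one row per probe): `probe_id`, `beta_case_avg`,
#'   `beta_control_avg`, `delta_beta`, `abs_delta_beta`, `p_value`, `fdr`,
#'   `direction` (`"hyper"`/`"hypo"`), `significant`; attribute `"n_calls"`
#'   holds the hyper/hypo significant counts.
#' @export
callDML <- function(ms, deltaThreshold = 0.2, pThreshold = 0.05,
                    paired = FALSE, exactThreshold = 12) {
  stopifnot(is(ms, "MethylationSet"))
  b <- betaValues(ms)
  grp <- sampleGroups(ms)
  ci <- which(grp == "case"); ki <- which(grp == "control")
  if (length(ci) < 2 || length(ki) < 2)
    stop("each group needs at least 2 samples")
  caseAvg <- rowMeans(b[, ci, drop = FALSE])
  ctrlAvg <- rowMeans(b[, ki, drop = FALSE])
  delta <- caseAvg - ctrlAvg
  if (paired) {
    pr <- pairIds(ms)
    ord <- match(pr[ci], pr[ki])
    if (anyNA(ord)) stop("paired test requires complete matched pairs")
    ki <- ki[ord]
    pv <- vapply(seq_len(nrow(b)), function(i)
      suppressWarnings(wilcox.test(b[i, ci], b[i, ki], paired = TRUE,
                                   exact = FALSE, correct = FALSE)$p.value),
      numeric(1))
    pv[is.nan(pv)] <- 1
  } else {
    pv <- vapply(seq_len(nrow(b)), function(i)
      wilcoxonRankSum(b[i, ci], b[i, ki], exactThreshold = exactThreshold),
      numeric(1))
  }
  res <- data.frame(
    probe_id = rownames(b),
    beta_case_avg = caseAvg,
    beta_control_avg = ctrlAvg,
    delta_beta = delta,
    abs_delta_beta = abs(delta),
    p_value = pv,
    fdr = bhAdjust(pv),
    direction = ifelse(delta > 0, "hyper", "hypo"),
    significant = pv < pThreshold & abs(delta) >= deltaThreshold,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "n_calls") <- c(
    hyper = sum(res$significant & res$direction == "hyper"),
    hypo = sum(res$significant & res$direction == "hypo"))
  res
}

#' Read a beta matrix TSV (first column = probe id)
#'
#' @param path TSV path.
#' @return Numeric matrix with probe ids as rownames.
#' @export
readBetaMatrix <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "numeric"
  m
}
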