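#' Read a qPCR Ct table
#'
#' TSV with columns `sample_id`, `group` (`case`/`control`), `gene`,
#' `ct_target`, `ct_reference` (reference-gene Ct, beta-actin role).
#'
#' @param path TSV path.
#' @return data.frame of Ct records.
#' @export
readCtTable <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "gene", "ct_target", "ct_reference")
  miss <- setdiff(need, colnames(d))
  if (length(miss)) stop("Ct table lacks columns: ",
                         paste(miss, collapse = ", "))
  d
}

#' Relative expression by the 2^-ddCt method
#'
#' For one gene: `dCt = ct_target - ct_reference` per sample,
#' `ddCt = dCt - mean(control dCt)`, `fold = 2^-ddCt`. The geometric mean
#' of control-group folds is 1 by construction, so case folds read directly
#' as expression relative to the control group. Records with a missing
#' target or reference Ct are skipped with a warning.
#'
#' @param records data.frame of Ct records for a single gene (columns as in
#'   [readCtTable()]).
#' @return data.frame: `sample_id`, `group`, `delta_ct`, `ddct`, `fold`.
#' @examples
#' ct <- data.frame(sample_id = 1:4,
#'                  group = c("case", "case", "control", "control"),
#'                  gene = "G", ct_target = c(24, 25, 26, 26),
#'                  ct_reference = 20)
#' ddctFoldChange(ct)
#' @export
ddctFoldChange <- function(records) {
  if (length(unique(records$gene)) > 1)
    stop("records must belong to a single gene")
  bad <- is.na(records$ct_target) | is.na(records$ct_reference)
  if (any(bad)) {
    warning(sum(bad), " record(s) with missing Ct skipped")
    records <- records[!bad, , drop = FALSE]
  }
  if (any(records$ct_target <= 0) || any(records$ct_reference <= 0) ||
      any(!is.finite(records$ct_target)) ||
      any(!is.finite(records$ct_reference)))
    stop("Ct values must be positive and finite")
  isCase <- records$group == "case"
  if (!any(isCase) || !any(!isCase))
    stop("need at least one case and one control record")
  dct <- records$ct_target - records$ct_reference
  ddct <- dct - mean(dct[!isCase])
  data.frame(sample_id = records$sample_id, group = records$group,
             delta_ct = dct, ddct = ddct, fold = 2^(-ddct),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Normality check by a Lilliefors-style Kolmogorov-Smirnov test
#'
#' Computes the one-sample KS statistic `D = sup |F_hat - Phi_hat|` against
#' a normal with the sample's own mean and SD. The p-value uses the
#' Lilliefors correction for estimated parameters
#' ([nortest::lillie.test()]) when `n >= 5`, and the plain KS p-value
#' (conservative with fitted parameters) for `n` of 3 or 4. The verdict is
#' "normal" when `p >= 0.05`. A constant sample is non-normal by
#' convention.
#'
#' @param x numeric vector, `n >= 3`.
#' @return list: `statistic` (D), `p_value`, `normal` (logical),
#'   `zero_variance` flag.
#' @export
normalityCheck <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) stop("normality check needs n >= 3")
  if (sd(x) == 0)
    return(list(statistic = NA_real_, p_value = NA_real_, normal = FALSE,
                zero_variance = TRUE))
  z <- pnorm(sort(x), mean(x), sd(x))
  i <- seq_len(n)
  D <- max(i / n - z, z - (i - 1) / n)
  p <- if (n >= 5) nortest::lillie.test(x)$p.value
       else suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x))$p.value)
  list(statistic = D, p_value = p, normal = p >= 0.05,
       zero_variance = FALSE)
}

#' Significance stars for a p-value
#'
#' `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, `ns` otherwise.
#'
#' @param p numeric vector of p-values.
#' @return Character vector of star codes.
#' @export
significanceStars <- function(p) {
  ifelse(p < 0.001, "***",
  ifelse(p < 0.01, "**",
  ifelse(p < 0.05, "*", "ns")))
}

#' Compare case and control values with normality-driven test selection
#'
#' Both groups passing [normalityCheck()] selects the Welch two-sample
#' t-test; otherwise (including groups too small to assess, n < 3) the
#' Mann-Whitney test. Significance stars follow the usual convention:
#' `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, `ns` otherwise.
#'
#' @param case,control numeric vectors, at least 2 values each.
#' @return list: `test` (`"welch_t"`/`"mann_whitney"`), `statistic`,
#'   `p_value`, `stars`.
#' @export
groupCompare <- function(case, control) {
  if (length(case) < 2 || length(control) < 2)
    stop("each group needs at least 2 values")
  canAssess <- length(case) >= 3 && length(control) >= 3 &&
    sd(case) > 0 && sd(control) > 0
  bothNormal <- canAssess && normalityCheck(case)$normal &&
    normalityCheck(control)$normal
  if (bothNormal) {
    ht <- t.test(case, control, var.equal = FALSE)
    test <- "welch_t"
  } else {
    ht <- suppressWarnings(wilcox.test(case, control, correct = TRUE))
    if (is.nan(ht$p.value)) ht$p.value <- 1
    test <- "mann_whitney"
  }
  p <- ht$p.value
  list(test = test, statistic = unname(ht$statistic), p_value = p,
       stars = significanceStars(p))
}

#' Per-gene qPCR analysis
#'
#' Runs [ddctFoldChange()] and [groupCompare()] (on the per-sample fold
#' changes) for every gene in a Ct table.
#'
#' @param ct data.frame of Ct records (see [readCtTable()]).
#' @return data.frame, one row per gene: `gene`, `n_case`, `n_control`,
#'   `mean_fold_case` (geometric), `test`, `p_value`, `stars`.
#' @export
qpcrAnalysis <- function(ct) {
  genes <- unique(ct$gene)
  rows <- lapply(genes, function(g) {
    f <- ddctFoldChange(ct[ct$gene == g, , drop = FALSE])
    cs <- f$fold[f$group == "case"]; ko <- f$fold[f$group == "control"]
    cmp <- groupCompare(cs, ko)
    data.frame(gene = g, n_case = length(cs), n_control = length(ko),
               mean_fold_case = exp(mean(log(cs))),
               test = cmp$test, p_value = cmp$p_value, stars = cmp$stars,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
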