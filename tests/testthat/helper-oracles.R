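# Independent brute-force oracles used across the suite.

# Exact two-sided Wilcoxon rank-sum p by full enumeration of the
# choose(n1 + n2, n1) equally likely rank assignments (no ties assumed).
enumWilcoxonP <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  uObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(n1 + n2, n1)
  us <- apply(splits, 2, function(i) sum(seq_len(n1 + n2)[i]) -
                n1 * (n1 + 1) / 2)
  total <- ncol(splits)
  if (uObs > n1 * n2 / 2) p <- 2 * sum(us >= uObs) / total
  else p <- 2 * sum(us <= uObs) / total
  min(p, 1)
}

# Step-up BH by direct definition: q_(i) = min_{j >= i} m * p_(j) / j.
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m))
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# Textbook Pearson correlation.
brutePearson <- function(a, b) {
  sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
}

# Median-of-ratios size factors from the definition, rescaled to
# geometric mean one.
bruteSizeFactors <- function(cnt) {
  geo <- exp(rowMeans(log(cnt)))
  ok <- is.finite(geo) & geo > 0
  sf <- apply(cnt, 2, function(cl) median(cl[ok] / geo[ok]))
  sf / exp(mean(log(sf)))
}

# Minimal integrated-record table for integration tests.
makeRecords <- function(...) {
  d <- data.frame(..., stringsAsFactors = FALSE)
  defaults <- list(probe_id = sprintf("cg%02d", seq_len(nrow(d))),
                   beta_case_avg = 0.5, beta_control_avg = 0.3,
                   island_relation = "OpenSea", region_group = "Promoter",
                   promoter_related = TRUE, padj = 0.01)
  for (nm in names(defaults))
    if (!nm %in% colnames(d)) d[[nm]] <- defaults[[nm]]
  if (!"abs_delta_beta" %in% colnames(d))
    d$abs_delta_beta <- abs(d$delta_beta)
  if (!"quadrant" %in% colnames(d))
    d$quadrant <- assignQuadrant(d$delta_beta, d$log2fc)
  d
}
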