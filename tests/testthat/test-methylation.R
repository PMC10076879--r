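test_that("beta computation follows the offset intensity ratio", {
  expect_equal(computeBeta(0, 0, 100), 0)
  expect_equal(computeBeta(300, 600, 100), 0.3)
  expect_equal(computeBeta(900, 0, 100), 0.9)
  expect_error(computeBeta(-1, 5), "non-negative")
  expect_error(computeBeta(1, 5, offset = 0), "offset")
  m <- matrix(c(100, 200, 300, 400), 2)
  expect_true(all(computeBeta(m, m) < 0.5))
})

test_that("quantile normalization maps columns onto the mean distribution", {
  cst <- matrix(5, 4, 3)
  expect_equal(quantileNormalizeBeta(cst), cst)
  x <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 2)
  out <- quantileNormalizeBeta(x)
  expect_equal(out[, 1], c(2.5, 3.5, 4.5))
  expect_equal(out[, 2], c(2.5, 3.5, 4.5))
  # columns that are permutations of each other end up identical multisets
  set.seed(1)
  v <- runif(50)
  y <- cbind(v, sample(v), sample(v))
  out <- quantileNormalizeBeta(y)
  expect_equal(sort(out[, 1]), sort(out[, 2]))
  expect_equal(sort(out[, 2]), sort(out[, 3]))
  # ranks within each column are preserved
  expect_identical(order(out[, 3]), order(y[, 3]))
  expect_warning(one <- quantileNormalizeBeta(y[, 1, drop = FALSE]),
                 "single column")
  expect_equal(one, y[, 1, drop = FALSE])
  y[2, 1] <- NA
  expect_error(quantileNormalizeBeta(y), "missing")
  expect_silent(quantileNormalizeBeta(y, imputeMissing = TRUE))
})

test_that("sample correlation QC equals the textbook Pearson formula", {
  set.seed(2)
  x <- matrix(runif(400), 100, 4, dimnames = list(NULL, paste0("s", 1:4)))
  r <- sampleCorrelationQC(x)
  expect_equal(dim(r), c(4, 4))
  expect_equal(diag(r), setNames(rep(1, 4), colnames(x)))
  expect_equal(r, t(r))
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(r[i, j], brutePearson(x[, i], x[, j]), tolerance = 1e-12)
  dup <- cbind(x[, 1], x[, 1])
  expect_equal(sampleCorrelationQC(dup)[1, 2], 1)
  neg <- cbind(x[, 1], 2 * mean(x[, 1]) - x[, 1])
  expect_equal(sampleCorrelationQC(neg)[1, 2], -1)
  flat <- cbind(x[, 1], rep(0.5, 100))
  rf <- sampleCorrelationQC(flat)
  expect_true(is.na(rf[1, 2]))
  expect_identical(attr(rf, "flagged"), colnames(flat)[2])
  expect_error(sampleCorrelationQC(x[, 1, drop = FALSE]), "two samples")
})

test_that("Wilcoxon rank-sum p matches worked small-sample values", {
  expect_equal(wilcoxonRankSum(c(1, 2), c(3, 4)), 2 / 6, tolerance = 1e-12)
  expect_equal(wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6)), 2 / 20,
               tolerance = 1e-12)
  expect_equal(wilcoxonRankSum(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(wilcoxonRankSum(c(2, 2), c(2, 2)), 1)
  expect_error(wilcoxonRankSum(1, c(1, 2)), "at least 2")
})

test_that("exact Wilcoxon p equals full enumeration for all small designs", {
  set.seed(3)
  for (n1 in 2:5) for (n2 in 2:5) {
    if (n1 + n2 > 10) next
    for (rep in 1:5) {
      xy <- sample(1000, n1 + n2)   # integers without ties
      x <- xy[seq_len(n1)]; y <- xy[-seq_len(n1)]
      expect_equal(wilcoxonRankSum(x, y, exactThreshold = 10),
                   enumWilcoxonP(x, y), tolerance = 1e-12,
                   info = sprintf("n1=%d n2=%d rep=%d", n1, n2, rep))
    }
  }
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  expect_equal(bhAdjust(0.05), 0.05)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(c(0.05, 0.5)), c(0.10, 0.5))
  expect_error(bhAdjust(c(0.2, 1.4)), "\\[0, 1\\]")
  set.seed(4)
  for (rep in 1:20) {
    p <- runif(sample(1:50, 1))
    q <- bhAdjust(p)
    expect_lt(max(abs(q - bruteBH(p))), 1e-12)
    expect_true(all(q >= p))                       # q >= p elementwise
    expect_true(all(diff(q[order(p)]) >= -1e-15))  # order-preserving
  }
})

test_that("DML calling applies both the p-value and the delta-beta gate", {
  set.seed(5)
  n <- 50; nP <- 10
  b <- matrix(rbeta(n * 2 * nP, 8, 8), n)
  # probe 1: large planted shift (hyper); probe 2: a clear but small shift
  # that passes the p gate while failing the 0.2 delta-beta gate
  b[1, 1:nP] <- pmin(b[1, 1:nP] + 0.4, 0.99)
  b[2, ] <- 0.40 + rnorm(2 * nP, 0, 0.01)
  b[2, 1:nP] <- b[2, 1:nP] + 0.15
  ms <- MethylationSet(b, rep(c("case", "control"), each = nP),
                       rep(1:nP, 2))
  res <- callDML(ms)
  expect_true(res$significant[1])
  expect_identical(res$direction[1], "hyper")
  expect_false(res$significant[2])   # p passes, |delta beta| 0.15 fails
  expect_lt(res$p_value[2], 0.05)
  expect_true(all(res$fdr >= res$p_value))
  expect_equal(res$abs_delta_beta, abs(res$delta_beta))
  expect_identical(attr(res, "n_calls")[["hyper"]],
                   sum(res$significant & res$delta_beta > 0))
})

test_that("DML results are invariant to sample column permutation", {
  set.seed(6)
  b <- matrix(rbeta(200 * 8, 5, 5), 200)
  grp <- rep(c("case", "control"), each = 4)
  ms <- MethylationSet(b, grp, rep(1:4, 2))
  perm <- sample(8)
  ms2 <- MethylationSet(b[, perm], grp[perm], rep(1:4, 2)[perm])
  r1 <- callDML(ms); r2 <- callDML(ms2)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  expect_equal(r1$delta_beta, r2$delta_beta, tolerance = 1e-12)
})

test_that("the paired signed-rank variant detects a consistent pair shift", {
  set.seed(7)
  nP <- 8
  base <- matrix(rbeta(30 * nP, 5, 5), 30)
  b <- cbind(pmin(base + 0.25, 0.99), base)   # case = control + shift
  ms <- MethylationSet(b, rep(c("case", "control"), each = nP),
                       rep(1:nP, 2))
  res <- callDML(ms, paired = TRUE)
  expect_true(all(res$p_value < 0.05))
  expect_true(all(res$direction == "hyper"))
})

test_that("beta containers reject malformed input", {
  b <- matrix(runif(20), 5)
  expect_error(MethylationSet(b + 2, rep(c("case", "control"), 2), 1:4),
               "beta values")
  expect_error(MethylationSet(b, rep("case", 4), 1:4), "at least 2")
  expect_error(MethylationSet(b, c("case", "ctl", "control", "control"),
                              1:4), "group")
})
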