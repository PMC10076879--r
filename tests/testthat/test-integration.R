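test_that("quadrant assignment matches the sign convention", {
  expect_identical(assignQuadrant(0.362, -4.72), "part4")
  expect_identical(assignQuadrant(-0.531, 2.95), "part1")
  expect_identical(assignQuadrant(0.2, 1.5), "part2")
  expect_identical(assignQuadrant(-0.2, -1.5), "part3")
  expect_identical(assignQuadrant(0, 2), "boundary")
  expect_identical(assignQuadrant(0.3, 0), "boundary")
  expect_error(assignQuadrant(NA, 1), "finite")
  expect_error(assignQuadrant(0.1, Inf), "finite")
})

test_that("quadrants are odd under a joint sign flip", {
  set.seed(12)
  db <- runif(100, -0.6, 0.6); fc <- runif(100, -4, 4)
  fwd <- assignQuadrant(db, fc)
  rev <- assignQuadrant(-db, -fc)
  map <- c(part1 = "part4", part2 = "part3", part3 = "part2",
           part4 = "part1", boundary = "boundary")
  expect_identical(unname(map[fwd]), rev)
})

test_that("gene-level join picks the max |delta beta| representative locus", {
  man <- data.frame(
    probe_id = c("cg01", "cg02", "cg03", "cg04"),
    chrom = "chr1", pos = 1:4, strand = "+",
    UCSC_RefGene_Name = c("GENE1", "GENE1", "GENE2", "GENE3"),
    UCSC_RefGene_Group = c("TSS200", "Body", "Body", "TSS1500"),
    Relation_to_UCSC_CpG_Island = c("Island", "OpenSea", "N_Shore",
                                    "OpenSea"),
    stringsAsFactors = FALSE)
  dml <- data.frame(
    probe_id = c("cg01", "cg02", "cg03", "cg04"),
    beta_case_avg = c(0.55, 0.75, 0.3, 0.6),
    beta_control_avg = c(0.30, 0.35, 0.6, 0.3),
    delta_beta = c(0.25, 0.40, -0.3, 0.3),
    abs_delta_beta = c(0.25, 0.40, 0.3, 0.3),
    p_value = c(0.001, 0.002, 0.001, 0.01),
    direction = c("hyper", "hyper", "hypo", "hyper"),
    stringsAsFactors = FALSE)
  de <- data.frame(gene = c("GENE1", "GENE2"),
                   log2fc = c(-2, 1.5), padj = c(0.01, 0.02))
  rec <- joinDmDe(dml, man, de)
  expect_identical(nrow(rec), 2L)
  g1 <- rec[rec$gene == "GENE1", ]
  expect_identical(g1$probe_id, "cg02")       # max |delta beta| wins
  expect_equal(g1$delta_beta, 0.40)
  expect_false(g1$promoter_related)           # cg02 is a Body probe
  expect_identical(g1$quadrant, "part4")
  g2 <- rec[rec$gene == "GENE2", ]
  expect_identical(g2$quadrant, "part1")
  expect_identical(attr(rec, "n_dropped"), 1L)  # GENE3 not in DE table
  expect_warning(out <- joinDmDe(dml[0, ], man, de), "no significant")
  expect_identical(nrow(out), 0L)
})

test_that("representative-locus ties break by p-value then probe id", {
  man <- data.frame(
    probe_id = c("cg09", "cg01"), chrom = "chr1", pos = 1:2, strand = "+",
    UCSC_RefGene_Name = "G", UCSC_RefGene_Group = "TSS200",
    Relation_to_UCSC_CpG_Island = "Island", stringsAsFactors = FALSE)
  dml <- data.frame(probe_id = c("cg09", "cg01"),
                    beta_case_avg = 0.5, beta_control_avg = 0.2,
                    delta_beta = 0.3, abs_delta_beta = 0.3,
                    p_value = c(0.01, 0.01), direction = "hyper",
                    stringsAsFactors = FALSE)
  de <- data.frame(gene = "G", log2fc = -2, padj = 0.01)
  rec <- joinDmDe(dml, man, de)
  expect_identical(rec$probe_id, "cg01")  # lexicographic tie-break
  expect_true(rec$promoter_related)
})

test_that("region correlation recovers exact collinearity", {
  rec <- makeRecords(gene = paste0("g", 1:3),
                     delta_beta = c(0.1, 0.2, 0.3),
                     log2fc = c(-1, -2, -3),
                     region_group = "Promoter")
  rc <- regionCorrelation(rec)
  pr <- rc[rc$region_group == "Promoter", ]
  expect_equal(pr$pearson_r, -1, tolerance = 1e-9)
  expect_identical(pr$n_genes, 3L)
  # groups with fewer than 3 genes are undefined
  expect_true(is.na(rc$pearson_r[rc$region_group == "GeneBody"]))
  # exact negative proportionality over many genes
  set.seed(13)
  db <- runif(40, -0.5, 0.5)
  rec2 <- makeRecords(gene = paste0("h", 1:40), delta_beta = db,
                      log2fc = -3 * db, region_group = "5UTR")
  rc2 <- regionCorrelation(rec2)
  expect_equal(rc2$pearson_r[rc2$region_group == "5UTR"], -1,
               tolerance = 1e-9)
  expect_lt(rc2$p_value[rc2$region_group == "5UTR"], 1e-6)
})

test_that("DMG partition counts conserve totals and round percentages", {
  set.seed(14)
  n <- 235
  qd <- c(rep("part4", 113), sample(c("part1", "part2", "part3"),
                                    n - 113, replace = TRUE))
  rec <- makeRecords(gene = paste0("p", seq_len(n)),
                     delta_beta = ifelse(qd %in% c("part2", "part4"),
                                         0.3, -0.3),
                     log2fc = ifelse(qd %in% c("part1", "part2"), 2, -2))
  rec$quadrant <- qd
  rec$promoter_related <- TRUE
  cls <- classifyDMGs(rec)
  pro <- cls[cls$partition == "promoter", ]
  expect_identical(sum(pro$count), as.integer(n))
  expect_identical(pro$count[pro$quadrant == "part4"], 113L)
  expect_equal(pro$percentage[pro$quadrant == "part4"], 48.1)  # 113/235
  enh <- cls[cls$partition == "enhancer", ]
  expect_identical(sum(enh$count), 0L)
  one <- makeRecords(gene = "x", delta_beta = 0.3, log2fc = -1)
  c1 <- classifyDMGs(one)
  expect_equal(c1$percentage[c1$partition == "promoter" &
                               c1$quadrant == "part4"], 100)
})

test_that("candidate ranking reproduces the published table order", {
  fix <- loadFixtureTables()
  shuffled1 <- fix$table1[sample(15), ]
  cand <- rankCandidates(shuffled1)
  expect_identical(cand$hyperDown$Gene, fix$table1$gene)
  expect_identical(nrow(cand$hypoUp), 0L)
  shuffled2 <- fix$table2[sample(15), ]
  top1 <- rankCandidates(shuffled2, k = 1)
  expect_identical(top1$hypoUp$Gene, "CASS4")
  expect_equal(top1$hypoUp$beta_change, 0.58500842)
  empty <- rankCandidates(fix$table1[0, ])
  expect_identical(nrow(empty$hyperDown), 0L)
  expect_identical(nrow(empty$hypoUp), 0L)
  # gates: a row failing padj or lfc is excluded
  loose <- fix$table1
  loose$padj[1] <- 0.2
  loose$log2fc[2] <- -0.5
  cut <- rankCandidates(loose)
  expect_identical(nrow(cut$hyperDown), 13L)
})

test_that("reported-gene filtering removes exactly the listed symbols", {
  fix <- loadFixtureTables()
  both <- rbind(rankCandidates(fix$table1)$hyperDown,
                rankCandidates(fix$table2)$hypoUp)
  expect_identical(nrow(both), 30L)
  expect_identical(nrow(filterReported(both, character(0))), 30L)
  expect_identical(nrow(filterReported(both, both$Gene)), 0L)
  excl <- setdiff(both$Gene, c("TMEM184A", "GREM2", "SFN", "KIR3DX1",
                               "HPGD", "ESR1", "CASS4", "BST2", "PIK3CG",
                               "RNASE1"))
  kept <- filterReported(both, excl)
  expect_identical(nrow(kept), 10L)
  expect_setequal(attr(kept, "removed"), excl)
})
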