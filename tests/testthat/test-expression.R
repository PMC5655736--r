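small_expr <- function() {
  counts <- matrix(c(3L, 0L, 100L,
                     6L, 10L, 200L), nrow = 3,
                   dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  expression_matrix(counts,
                    lengths = c(g1 = 1000, g2 = 500, g3 = 2000),
                    samples = tibble::tibble(sample_id = c("s1", "s2"),
                                             tissue = "t", replicate = 1:2))
}

test_that("CPM and RPKM follow their defining formulas and cross-check", {
  counts <- matrix(c(3L, 999997L), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  expr <- expression_matrix(counts, lengths = c(g1 = 2000, g2 = 1000),
                            samples = tibble::tibble(sample_id = "s1",
                                                     tissue = "t", replicate = 1))
  expect_equal(cpm(expr)["g1", "s1"], 3)
  # count 100, length 2000, library 1e6 -> RPKM 50
  counts2 <- matrix(c(100L, 999900L), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  expr2 <- expression_matrix(counts2, lengths = c(g1 = 2000, g2 = 1000),
                             samples = expr$samples)
  expect_equal(rpkm(expr2)["g1", "s1"], 50)
  # identity: RPKM = CPM * 1000 / length, for every gene and sample
  e <- small_expr()
  expect_equal(rpkm(e), cpm(e) * 1000 / c(1000, 500, 2000))
  expect_equal(cpm(e)["g2", "s1"], 0)
})

test_that("expressed filter requires CPM >= 3 in every replicate, inclusive", {
  mk <- function(v1, v2, v3) {
    counts <- rbind(g1 = as.integer(v1), filler = as.integer(v2))
    colnames(counts) <- paste0("s", 1:3)
    storage.mode(counts) <- "integer"
    expression_matrix(counts, lengths = c(g1 = 1000, filler = 1000),
                      samples = tibble::tibble(sample_id = paste0("s", 1:3),
                                               tissue = "root", replicate = 1:3))
  }
  # CPMs (3.1, 3.5, 4.0) -> expressed
  e1 <- mk(c(31, 35, 40), 1e7 - c(31, 35, 40))
  expect_true("g1" %in% expressed_filter(e1, "root"))
  # one replicate at 2.9 -> not expressed
  e2 <- mk(c(31, 29, 40), 1e7 - c(31, 29, 40))
  expect_false("g1" %in% expressed_filter(e2, "root"))
  # exactly 3.0 everywhere -> expressed (inclusive threshold)
  e3 <- mk(c(30, 30, 30), 1e7 - c(30, 30, 30))
  expect_true("g1" %in% expressed_filter(e3, "root"))
})

test_that("differential expression is calibrated under the null", {
  tr <- expression_truth(n_genes = 2000, dispersion = 0.05)
  sim <- simulate_expression(NULL, tr, c("a", "b"), 3,
                             library_size = 2000 * 200, seed = 51)
  de <- differential_expression(sim$expr, "a", "b")
  frac <- mean(de$de)
  se3 <- 3 * sqrt(0.05 * 0.95 / nrow(de))
  expect_lte(frac, 0.05 + se3)
  # all-zero genes are absent from the result
  expect_false(any(rowSums(sim$expr$counts)[de$gene_id] == 0))
})

test_that("differential expression recovers planted 8-fold genes", {
  de_genes <- sprintf("g%04d", 1:50)
  tr <- expression_truth(
    n_genes = 1000,
    planted_de = tibble::tibble(gene_id = de_genes, tissue_up = "b", log2fc = 3),
    dispersion = 0.05,
    baseline_means = setNames(rep(500, 1000), sprintf("g%04d", 1:1000)))
  sim <- simulate_expression(NULL, tr, c("a", "b"), 3,
                             library_size = 1000 * 500, seed = 52)
  de <- differential_expression(sim$expr, "a", "b")
  hits <- de$de[match(de_genes, de$gene_id)]
  expect_gte(mean(hits), 0.9)
  expect_true(all(de$direction[match(de_genes, de$gene_id)][hits] == "up_b"))
  gl <- glance(de)
  expect_equal(gl$n_de, sum(de$de))
})

test_that("the NB exact test broadly agrees with edgeR on the same data", {
  skip_if_not_installed("edgeR")
  de_genes <- sprintf("g%04d", 1:30)
  tr <- expression_truth(
    n_genes = 500,
    planted_de = tibble::tibble(gene_id = de_genes, tissue_up = "b", log2fc = 2.5),
    dispersion = 0.05)
  sim <- simulate_expression(NULL, tr, c("a", "b"), 3,
                             library_size = 500 * 300, seed = 53)
  de <- differential_expression(sim$expr, "a", "b")

  grp <- factor(sim$expr$samples$tissue, levels = c("a", "b"))
  y <- edgeR::DGEList(counts = sim$expr$counts, group = grp)
  y <- edgeR::calcNormFactors(y)
  y <- edgeR::estimateCommonDisp(y)
  et <- edgeR::exactTest(y)
  tt <- edgeR::topTags(et, n = Inf)$table
  edger_hits <- rownames(tt)[tt$FDR <= 0.05]
  own_hits <- de$gene_id[de$de]
  # the two testers call substantially the same genes
  jaccard <- length(intersect(edger_hits, own_hits)) /
    max(1, length(union(edger_hits, own_hits)))
  expect_gte(jaccard, 0.8)
  # and their p-values rank genes the same way
  shared <- intersect(de$gene_id, rownames(tt))
  expect_gte(cor(rank(de$p_value[match(shared, de$gene_id)]),
                 rank(tt$PValue[match(shared, rownames(tt))])), 0.95)
})

test_that("replicate QC returns squared correlations near 1 at low noise", {
  tr <- expression_truth(n_genes = 800, dispersion = 0.02)
  sim <- simulate_expression(NULL, tr, "root", 3, library_size = 800 * 300,
                             seed = 54)
  qc <- replicate_qc(sim$expr)
  expect_equal(nrow(qc), 3)                    # 3 replicate pairs
  expect_true(all(qc$r_squared >= 0.9))        # the study-like noise regime

  # identical replicates give exactly 1
  cts <- sim$expr$counts
  cts[, 2] <- cts[, 1]; cts[, 3] <- cts[, 1]
  e2 <- expression_matrix(cts, lengths = sim$expr$lengths,
                          samples = sim$expr$samples)
  expect_equal(replicate_qc(e2)$r_squared, rep(1, 3))
})

test_that("the enrichment filter applies fold and q rules and is monotone", {
  m <- rbind(g1 = c(vascular = 13.0, nonvascular = 10.0, ground = 9.0),
             g2 = c(10.8, 10.0, 2.0),
             g3 = c(30.0, 5.0, 5.0))
  q <- c(g1 = 1e-4, g2 = 1e-4, g3 = 0.01)
  kept <- enrichment_filter(m, "vascular", c("nonvascular", "ground"), q)
  expect_true("g1" %in% kept)          # 1.3-fold, significant
  expect_false("g2" %in% kept)         # 1.08-fold
  expect_false("g3" %in% kept)         # fold ok but q = 0.01 > 0.001

  # monotonicity: raising fold or tightening q never grows the set
  set.seed(61)
  m2 <- matrix(runif(300, 0, 20), 100, 3,
               dimnames = list(sprintf("g%03d", 1:100),
                               c("focal", "c1", "c2")))
  q2 <- setNames(runif(100, 0, 0.01), rownames(m2))
  base <- enrichment_filter(m2, "focal", c("c1", "c2"), q2,
                            fold = 1.2, q_max = 0.001)
  for (f in c(1.5, 2)) {
    expect_true(all(enrichment_filter(m2, "focal", c("c1", "c2"), q2,
                                      fold = f, q_max = 0.001) %in% base))
  }
  expect_true(all(enrichment_filter(m2, "focal", c("c1", "c2"), q2,
                                    fold = 1.2, q_max = 1e-4) %in% base))
})

test_that("pairwise-slope correlation equals plain Pearson on tissue means", {
  ref <- c(10, 2, 30, 4, 7)
  expect_equal(pairwise_slope_correlation(ref, ref), 1)
  expect_equal(pairwise_slope_correlation(ref, -ref), -1)
  expect_error(pairwise_slope_correlation(ref, rep(5, 5)),
               class = "methexpress_undefined")

  set.seed(71)
  for (i in 1:1000) {
    k <- sample(3:8, 1)
    x <- rnorm(k); y <- rnorm(k)
    expect_equal(pairwise_slope_correlation(x, y), cor(x, y), tolerance = 1e-12)
  }
})

test_that("coexpression ranking flags the planted module at r >= 0.9", {
  members <- sprintf("g%04d", 11:40)
  tr <- expression_truth(
    n_genes = 200,
    coexpr_module = list(reference = "g0010", members = members, target_r = 0.95),
    dispersion = 0.01)
  sim <- simulate_expression(NULL, tr,
                             c("root", "shoot", "vascular", "nonvascular", "embryo"),
                             3, library_size = 1e6, seed = 72)
  cx <- coexpression(sim$expr, "g0010")
  expect_gte(mean(cx$coexpressed[cx$gene_id %in% members]), 0.8)
  # non-members are mostly uncorrelated
  expect_lt(mean(cx$coexpressed[!cx$gene_id %in% members]), 0.2)
})
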