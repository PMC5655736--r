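test_that("window tiling keeps fully-contained windows and gates eligibility", {
  calls <- make_calls("chr1", seq(0, 240, by = 10), k = 5L, n = 10L)
  win <- build_windows(calls, calls, c(chr1 = 250))
  expect_equal(win$start, c(0L, 50L, 100L, 150L))  # window [200,300) would overhang

  # 14 eligible cytosines -> untested
  c14 <- make_calls("chr1", seq(0, 91, by = 7), k = 5L, n = 10L)  # 14 sites < 100
  w14 <- build_windows(c14, c14, c(chr1 = 100))
  expect_false(w14$tested[1])
  expect_equal(w14$n_cytosines[1], 14L)

  # a cytosine needs >= 4x in BOTH samples to contribute
  ca <- make_calls("chr1", 0:19, k = 3L, n = 5L)
  cb <- make_calls("chr1", 0:19, k = 2L, n = c(rep(5L, 19), 3L))
  w <- build_windows(ca, cb, c(chr1 = 100), min_cytosines = 15L)
  expect_equal(w$n_cytosines[1], 19L)   # the 3x-in-B site is excluded
})

test_that("window Fisher p-values match the enumeration oracle", {
  expect_equal(window_fisher(60, 40, 10, 90), oracle_fisher2x2(60, 100, 10, 100),
               tolerance = 1e-10)
  expect_equal(window_fisher(30, 30, 30, 30), 1)
  # extreme table: p = 2 / C(30, 15)
  expect_equal(window_fisher(15, 0, 0, 15), 2 / choose(30, 15), tolerance = 1e-12)

  set.seed(17)
  for (i in 1:500) {
    n1 <- sample(1:100, 1); n2 <- sample(1:100, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    expect_equal(window_fisher(k1, n1 - k1, k2, n2 - k2),
                 oracle_fisher2x2(k1, n1, k2, n2), tolerance = 1e-10)
  }
})

test_that("window Fisher agrees with fisher.test as an independent reference", {
  set.seed(23)
  for (i in 1:100) {
    n1 <- sample(5:80, 1); n2 <- sample(5:80, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    ft <- stats::fisher.test(matrix(c(k1, n1 - k1, k2, n2 - k2), 2, byrow = TRUE))
    expect_equal(window_fisher(k1, n1 - k1, k2, n2 - k2), ft$p.value,
                 tolerance = 1e-7)
  }
})

test_that("significant-window merging follows the strict p < 0.001 touch rule", {
  win <- tibble::tibble(chrom = "chr1",
                        start = c(100L, 150L, 300L, 500L),
                        end = c(200L, 250L, 400L, 600L),
                        p_value = c(1e-5, 1e-4, 1e-6, 0.001))
  reg <- merge_windows(win)
  # overlapping significant windows concatenate; p = 0.001 exactly is NOT
  # significant; the isolated window stays a single region
  expect_equal(nrow(reg), 2)
  expect_equal(reg$start, c(100L, 300L))
  expect_equal(reg$end, c(250L, 400L))
  expect_equal(reg$min_p[1], 1e-5)

  # merged output is disjoint and sorted
  expect_true(all(diff(reg$start) > 0))
  expect_true(all(reg$start[-1] >= reg$end[-nrow(reg)]))
})

test_that("DMR classification applies strict 30/70 thresholds and direction", {
  mk_region <- function() tibble::tibble(chrom = "chr1", start = 0L, end = 100L,
                                         n_windows = 1L, min_p = 1e-6)
  mk_call <- function(k) make_calls("chr1", seq(0, 95, by = 5), k = k, n = 20L)
  # 75% vs 20% -> DMR, hyper in A
  d1 <- classify_dmrs(mk_region(), mk_call(15L), mk_call(4L))
  expect_equal(nrow(d1), 1)
  expect_equal(d1$direction, "hyper_a")
  # 50% vs 10% -> not a DMR (fails > 70%)
  expect_equal(nrow(classify_dmrs(mk_region(), mk_call(10L), mk_call(2L))), 0)
  # exactly 70% / 30% -> not a DMR (strict inequalities)
  expect_equal(nrow(classify_dmrs(mk_region(), mk_call(14L), mk_call(6L))), 0)
})

test_that("self-comparison yields no DMRs and a null genome stays clean", {
  g <- generate_genome(1, 100000, 0.44, seed = 19)
  tr <- methylome_truth(rates = c(CG = 0.6, CHG = 0.3, CHH = 0.05),
                        error_rate = 0.002, coverage_mean = 8)
  sim <- simulate_methylome(g, NULL, tr, c("a", "b"), 3, seed = 7)
  pa <- dplyr::filter(merge_replicates(sim$tables[1:3]), chrom != "spikein")
  pb <- dplyr::filter(merge_replicates(sim$tables[4:6]), chrom != "spikein")
  ca <- call_methylation(pa, 0.002); cb <- call_methylation(pb, 0.002)
  expect_equal(nrow(detect_dmrs(ca, ca, c(chr1 = 100000))), 0)
  expect_equal(nrow(detect_dmrs(ca, cb, c(chr1 = 100000))), 0)
})

test_that("planted DMRs are recovered at their coordinates", {
  g <- generate_genome(1, 300000, 0.44, seed = 29)
  starts <- seq(20000L, 280000L, by = 40000L)
  pd <- tibble::tibble(chrom = "chr1", start = starts, end = starts + 300L,
                       tissue_high = "vascular", rate_high = 0.9, rate_low = 0.05)
  tr <- methylome_truth(rates = c(CG = 0.05, CHG = 0.05, CHH = 0.02),
                        planted_dmrs = pd, error_rate = 0.002, coverage_mean = 10)
  sim <- simulate_methylome(g, NULL, tr, c("vascular", "nonvascular"), 3, seed = 31)
  ca <- call_methylation(dplyr::filter(merge_replicates(sim$tables[1:3]),
                                       chrom != "spikein"), 0.002)
  cb <- call_methylation(dplyr::filter(merge_replicates(sim$tables[4:6]),
                                       chrom != "spikein"), 0.002)
  dmrs <- detect_dmrs(ca, cb, c(chr1 = 300000))
  hit <- purrr::map_lgl(seq_len(nrow(pd)), function(i) {
    any(dmrs$start < pd$end[i] & dmrs$end > pd$start[i])
  })
  expect_gte(mean(hit), 0.9)
  outside <- purrr::map_lgl(seq_len(nrow(dmrs)), function(i) {
    !any(dmrs$start[i] < pd$end + 100 & dmrs$end[i] > pd$start - 100)
  })
  expect_equal(sum(outside), 0)
  expect_true(all(dmrs$direction == "hyper_a"))
})

test_that("gene association honours the 1-kb rule with strand-aware relations", {
  genes <- dplyr::bind_rows(
    make_gene("gp", strand = "+", start = 5000, end = 8000),
    make_gene("gm", strand = "-", start = 20000, end = 23000))
  mk_dmr <- function(s, e) tibble::tibble(chrom = "chr1", start = s, end = e,
                                          name = "d", level_a = 0.8,
                                          level_b = 0.1)
  a1 <- associate_genes(mk_dmr(4100L, 4200L), genes)
  expect_equal(a1$gene_id, "gp")
  expect_equal(a1$relation, "5' flank")

  expect_equal(nrow(associate_genes(mk_dmr(3900L, 3990L), genes)), 0)

  a3 <- associate_genes(mk_dmr(6000L, 6100L), genes)
  expect_equal(a3$relation, "overlap")

  # genomic-left of a minus-strand gene is its 3' flank
  a4 <- associate_genes(mk_dmr(19500L, 19600L), genes)
  expect_equal(a4$gene_id, "gm")
  expect_equal(a4$relation, "3' flank")
})

test_that("per-gene hypermethylation uses N >= 20, upper tail and BH", {
  # gene 1: 25 fully methylated sites; gene 2: 19 callable sites (excluded);
  # gene 3: background-level methylation
  genes <- dplyr::bind_rows(
    make_gene("g1", start = 0, end = 300),
    make_gene("g2", start = 1000, end = 1190),
    make_gene("g3", start = 2000, end = 2300))
  pos <- c(seq(0, 240, by = 10), seq(1000, 1180, by = 10), seq(2000, 2240, by = 10))
  k <- c(rep(28L, 25), rep(0L, 19), rep(c(28L, 0L, 0L, 0L, 0L), 5))
  calls <- make_calls("chr1", pos, k = k, n = 30L)
  # pad the background with many null sites so p_bg is low
  bg <- make_calls("chr1", seq(10000, 19990, by = 10), k = 0L, n = 30L)
  all_calls <- dplyr::bind_rows(calls, bg)
  hyper <- hypermethylated_genes(all_calls, genes, "CG")
  expect_setequal(hyper$gene_id, c("g1", "g3"))    # g2 has N = 19 < 20
  expect_true(hyper$significant[hyper$gene_id == "g1"])
  # K at the background expectation is not significant
  p_bg <- hyper$p_bg[1]
  n_at_exp <- 40L; k_at_exp <- as.integer(round(n_at_exp * p_bg))
  expect_gt(binomial_tail(k_at_exp, n_at_exp, p_bg), 0.3)
})

test_that("k-means recovers planted DMR archetypes and flags degeneracy", {
  set.seed(43)
  lv <- rbind(
    cbind(runif(40, 0.8, 0.95), runif(40, 0.0, 0.15)),   # hyper-A
    cbind(runif(40, 0.0, 0.15), runif(40, 0.8, 0.95)))   # hyper-B
  res <- cluster_dmrs(lv, k = 2, seed = 5)
  truth <- rep(1:2, each = 40)
  agreement <- max(mean(res$labels == truth), mean(res$labels == 3 - truth))
  expect_gte(agreement, 0.95)
  expect_gt(res$silhouette, 0.5)

  r1 <- cluster_dmrs(lv, k = 1, seed = 5)
  expect_true(is.na(r1$silhouette))

  same <- matrix(0.5, 10, 2)
  expect_warning(rd <- cluster_dmrs(same, k = 2, seed = 5), "degenerate")
  expect_true(rd$degenerate)

  expect_error(cluster_dmrs(lv, k = 200, seed = 1), "exceeds")
})
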