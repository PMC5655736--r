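test_that("genome generation is seed-deterministic and hits the GC target", {
  g1 <- generate_genome(1, 100000, 0.44, seed = 7)
  g2 <- generate_genome(1, 100000, 0.44, seed = 7)
  expect_identical(unclass(g1), unclass(g2))
  expect_true("spikein" %in% names(g1))

  b <- strsplit(unclass(g1)[["chr1"]], "")[[1]]
  gc <- mean(b %in% c("G", "C"))
  expect_lt(abs(gc - 0.44), 0.01)   # ~6 sigma at 100 kb

  expect_error(generate_genome(1, 1000, 1.5, seed = 1), "gc_fraction")
})

test_that("cytosine context assignment follows the strand's own 5'->3' triplet", {
  g <- structure(c(chr1 = "CCGG"), class = "genome_sequence")
  ctx <- annotate_contexts(g)
  plus <- ctx[ctx$strand == "+", ]
  expect_equal(plus$context[plus$pos == 1], "CG")    # C at 1-based pos 2
  expect_equal(plus$context[plus$pos == 0], "CHG")   # CCG

  # CG symmetry: the G at 1-based pos 3 of ACGT is a minus-strand CG cytosine
  g2 <- structure(c(chr1 = "ACGT"), class = "genome_sequence")
  ctx2 <- annotate_contexts(g2)
  minus <- ctx2[ctx2$strand == "-", ]
  expect_equal(minus$context[minus$pos == 2], "CG")

  g3 <- structure(c(chr1 = "ACATT"), class = "genome_sequence")
  ctx3 <- annotate_contexts(g3)
  expect_equal(ctx3$context[ctx3$pos == 1 & ctx3$strand == "+"], "CHH")
})

test_that("contexts near chromosome ends fall back by available bases; N skips", {
  # trailing C: no downstream bases -> CHH fallback
  g <- structure(c(chr1 = "AAC"), class = "genome_sequence")
  ctx <- annotate_contexts(g)
  expect_equal(ctx$context[ctx$pos == 2 & ctx$strand == "+"], "CHH")
  # CA at the end: cannot be CG, CHG undeterminable -> CHH fallback
  g2 <- structure(c(chr1 = "AACA"), class = "genome_sequence")
  ctx2 <- annotate_contexts(g2)
  expect_equal(ctx2$context[ctx2$pos == 2 & ctx2$strand == "+"], "CHH")
  # N in the triplet skips the site
  g3 <- structure(c(chr1 = "ACNG"), class = "genome_sequence")
  ctx3 <- annotate_contexts(g3)
  expect_false(any(ctx3$pos == 1 & ctx3$strand == "+"))
})

test_that("methylome simulation is deterministic and respects degenerate truth", {
  g <- generate_genome(1, 20000, 0.44, seed = 3, spikein_length = 1000)
  tr0 <- methylome_truth(rates = c(CG = 0, CHG = 0, CHH = 0), error_rate = 0,
                         coverage_mean = 5)
  s1 <- simulate_methylome(g, NULL, tr0, "root", 2, seed = 9)
  s2 <- simulate_methylome(g, NULL, tr0, "root", 2, seed = 9)
  expect_identical(s1$tables, s2$tables)
  expect_true(all(purrr::map_lgl(s1$tables, ~ all(.x$meth == 0))))
})

test_that("spike-in methylated fraction estimates the planted error rate", {
  g <- generate_genome(1, 5000, 0.44, seed = 5, spikein_length = 30000)
  tr <- methylome_truth(error_rate = 0.002, coverage_mean = 10)
  sim <- simulate_methylome(g, NULL, tr, "root", 3, seed = 2)
  sp <- merge_replicates(sim$tables)
  sp <- dplyr::filter(sp, chrom == "spikein")
  expect_gt(sum(sp$n), 1e5)
  est <- sum(sp$k) / sum(sp$n)
  expect_gte(est, 0.0015)   # ~4.5 sigma band around 0.002 at >=1e5 reads
  expect_lte(est, 0.0025)
})

test_that("planted DMR windows straddle the 30/70 thresholds at 10x", {
  g <- generate_genome(1, 50000, 0.44, seed = 8)
  pd <- tibble::tibble(chrom = "chr1", start = 20000L, end = 20300L,
                       tissue_high = "vascular", rate_high = 0.9, rate_low = 0.05)
  tr <- methylome_truth(rates = c(CG = 0.05, CHG = 0.05, CHH = 0.02),
                        planted_dmrs = pd, error_rate = 0.002, coverage_mean = 10)
  sim <- simulate_methylome(g, NULL, tr, c("vascular", "nonvascular"), 3, seed = 4)
  lev <- function(tabs, lo, hi) {
    p <- merge_replicates(tabs)
    p <- p[p$chrom == "chr1" & p$pos >= lo & p$pos < hi, ]
    sum(p$k) / sum(p$n)
  }
  expect_gt(lev(sim$tables[1:3], 20000, 20300), 0.7)
  expect_lt(lev(sim$tables[4:6], 20000, 20300), 0.3)
  # outside the planted interval both tissues share the low baseline
  expect_lt(lev(sim$tables[1:3], 30000, 31000), 0.3)
})

test_that("overlapping planted DMRs are rejected", {
  pd <- tibble::tibble(chrom = "chr1", start = c(100L, 250L), end = c(300L, 400L),
                       tissue_high = "a", rate_high = 0.9, rate_low = 0.05)
  expect_error(methylome_truth(planted_dmrs = pd), "overlap")
})

test_that("expression simulation recovers planted fold changes", {
  de <- tibble::tibble(gene_id = sprintf("g%04d", 1:10),
                       tissue_up = "vascular", log2fc = 3)
  tr <- expression_truth(n_genes = 300, planted_de = de, dispersion = 0.05)
  sim <- simulate_expression(NULL, tr, c("vascular", "nonvascular"), 3,
                             library_size = 300 * 500, seed = 6)
  cm <- sim$expr$counts
  sa <- sim$expr$samples$sample_id[sim$expr$samples$tissue == "vascular"]
  sb <- sim$expr$samples$sample_id[sim$expr$samples$tissue == "nonvascular"]
  ratio <- rowMeans(cm[de$gene_id, sa]) / pmax(1, rowMeans(cm[de$gene_id, sb]))
  # planted 8-fold genes land within 2-fold of 8 on average at n=3
  expect_true(all(ratio > 4 & ratio < 16))
})

test_that("NB simulation approaches Poisson as dispersion vanishes", {
  tr <- expression_truth(n_genes = 500, dispersion = 1e-6,
                         baseline_means = setNames(rep(100, 500),
                                                   sprintf("g%04d", 1:500)))
  sim <- simulate_expression(NULL, tr, "root", 3, library_size = 500 * 100, seed = 1)
  x <- as.vector(sim$expr$counts)
  # Poisson: variance ~ mean
  expect_lt(abs(var(x) / mean(x) - 1), 0.2)
})

test_that("coexpression module members correlate with the reference as targeted", {
  members <- sprintf("g%04d", 101:130)
  tr <- expression_truth(
    n_genes = 300,
    coexpr_module = list(reference = "g0100", members = members, target_r = 0.95),
    dispersion = 0.01)
  tissues <- c("root", "shoot", "vascular", "nonvascular", "embryo")
  sim <- simulate_expression(NULL, tr, tissues, 3, library_size = 1e6, seed = 12)
  cx <- coexpression(sim$expr, "g0100", genes = members)
  expect_gte(mean(cx$r >= 0.9), 0.8)
})

test_that("a simulated study round-trips through the on-disk formats", {
  g <- generate_genome(1, 30000, 0.44, seed = 2, spikein_length = 1000)
  genes <- generate_gene_models(g, 3, seed = 5)
  tr <- methylome_truth(coverage_mean = 6)
  sim <- simulate_methylome(g, genes, tr, "root", 2, seed = 3)
  et <- expression_truth(n_genes = 50)
  se <- simulate_expression(NULL, et, "root", 2, library_size = 1e4, seed = 4)
  dir <- withr::local_tempdir()
  write_simulated_study(sim, se, g, genes, dir)

  back_tab <- read_methcounts(file.path(dir, "root_rep1.methcounts.tsv"))
  expect_equal(as.data.frame(back_tab), as.data.frame(sim$tables$root_rep1))
  back_genes <- read_gene_models(file.path(dir, "genes.bed"))
  expect_equal(back_genes$start, genes$start)
  expect_equal(back_genes$end, genes$end)
  back_expr <- read_counts_matrix(file.path(dir, "counts.tsv"),
                                  file.path(dir, "samples.tsv"))
  expect_equal(back_expr$counts, se$expr$counts)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$error_rate, tr$error_rate)
})
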