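#' Default run configuration pinning the standard thresholds
#'
#' The `"paper"` profile reproduces the study parameterisation exactly:
#' coverage >= 4x for site calling, site FDR 0.01, 100-bp/50-bp DMR windows
#' with >= 15 cytosines and a window merge cut-off of p < 0.001, the
#' <30%/>70% DMR rule, +/-1000 bp gene association, per-gene
#' hypermethylation with N >= 20 and BH FDR <= 0.05, expressed-gene CPM >=
#' 3, DE FDR <= 0.05, coexpression r >= 0.9, enrichment fold > 1.2 at q <=
#' 0.001, GO Bonferroni < 0.05.
#'
#' @param profile Currently only `"paper"`.
#' @return Named list of parameters.
#' @export
default_config <- function(profile = "paper") {
  if (!identical(profile, "paper")) stop_mx("unknown config profile")
  list(
    min_coverage = 4L, site_fdr = 0.01, error_rate_floor = 1e-4,
    window_size = 100L, step = 50L, min_cytosines = 15L, window_alpha = 0.001,
    low_cut = 0.30, high_cut = 0.70, flank = 1000L,
    hyper_min_cytosines = 20L, hyper_fdr = 0.05,
    flank_bp = 2000L, flank_window = 20L, body_bins = 100L, min_exonic_bp = 100L,
    min_cpm = 3, de_fdr = 0.05, coexpr_r = 0.9,
    enrich_fold = 1.2, enrich_q = 0.001, go_alpha = 0.05,
    kmeans_k = 4L
  )
}

#' Run the full tissue-comparative pipeline on a simulated study
#'
#' End-to-end orchestration: simulate a study (genome, methylomes,
#' expression), pool replicates, estimate the spike-in error rate, call
#' methylated cytosines, run the methylation-state PCA, build metagene
#' profiles, detect and gene-associate DMRs between the configured contrast
#' pair, call hypermethylated genes, test differential expression, and rank
#' coexpression against a reference gene. Outputs (DMR BED, call / DE /
#' profile TSVs) and a reproducibility manifest are written under `outdir`.
#' Re-running with the same config and seed reproduces every output
#' byte-for-byte.
#'
#' @param config Parameter list from [default_config()], plus the run keys
#'   `tissues` (character), `n_replicates`, `contrast` (length-2 character),
#'   `seed`, and the simulation sizes `n_chrom`, `chrom_length`, `n_genes`.
#' @param outdir Output directory.
#' @return List with the principal results (`error_rate`, `calls`, `pca`,
#'   `profiles`, `dmrs`, `dmr_genes`, `hyper`, `de`, `coexpr`, `manifest`),
#'   invisibly written to `outdir`.
#' @export
run_pipeline <- function(config, outdir) {
  cfg <- utils::modifyList(default_config(), config)
  req <- c("tissues", "n_replicates", "contrast", "seed")
  missing <- setdiff(req, names(cfg))
  if (length(missing)) stop_mx(paste0("config missing: ", paste(missing, collapse = ", ")))
  if (!all(cfg$contrast %in% cfg$tissues)) {
    stop_mx("contrast references a tissue not in the tissue list")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  genome <- generate_genome(cfg[["n_chrom"]] %||% 1L, cfg[["chrom_length"]] %||% 300000L,
                            cfg[["gc_fraction"]] %||% 0.44, seed = cfg$seed)
  genes <- generate_gene_models(genome, cfg[["n_genes"]] %||% 60L, seed = cfg$seed + 1L)
  mtruth <- methylome_truth(
    planted_dmrs = cfg[["planted_dmrs"]] %||% NULL,
    error_rate = cfg[["error_rate"]] %||% 0.002,
    coverage_mean = cfg[["coverage_mean"]] %||% 8
  )
  sim <- simulate_methylome(genome, genes, mtruth, cfg$tissues,
                            cfg$n_replicates, seed = cfg$seed + 2L)
  etruth <- expression_truth(dispersion = cfg[["dispersion"]] %||% 0.05)
  sime <- simulate_expression(genes, etruth, cfg$tissues, cfg$n_replicates,
                              library_size = cfg[["library_size"]] %||% 2e5,
                              seed = cfg$seed + 3L)

  # pool replicates per tissue, estimate the error rate from all spike-ins
  pooled <- purrr::map(setNames(cfg$tissues, cfg$tissues), function(ti) {
    reps <- sim$tables[grep(paste0("^", ti, "_rep"), names(sim$tables))]
    merge_replicates(reps)
  })
  spike <- bind_rows(purrr::map(pooled, ~ filter(.x, .data$chrom == "spikein")))
  err <- estimate_error_rate(
    spike %>% group_by(.data$chrom, .data$pos, .data$strand) %>%
      summarise(k = sum(.data$k), n = sum(.data$n), .groups = "drop"),
    floor = cfg$error_rate_floor)

  calls <- purrr::map(pooled, function(p) {
    call_methylation(filter(p, .data$chrom != "spikein"), err,
                     min_cov = cfg$min_coverage, fdr = cfg$site_fdr)
  })

  state <- build_state_matrix(
    purrr::map(sim$tables, ~ filter(.x, .data$chrom != "spikein")),
    err, context = "CG", min_cov = cfg$min_coverage, fdr = cfg$site_fdr)
  pca <- methylation_pca(state)

  chrom_lengths <- setNames(nchar(unclass(genome)), names(genome))
  bins <- bin_genes(genes, cfg$flank_bp, cfg$flank_window, cfg$body_bins,
                    cfg$min_exonic_bp, chrom_lengths)
  profiles <- purrr::imap(calls, function(cc, ti) {
    profile_sample(cc, bins, "CG") %>% mutate(group = ti)
  }) %>% bind_rows()

  ca <- calls[[cfg$contrast[1]]]; cb <- calls[[cfg$contrast[2]]]
  dmrs <- detect_dmrs(ca, cb, chrom_lengths[setdiff(names(genome), "spikein")],
                      cfg$window_size, cfg$step, cfg$min_coverage,
                      cfg$min_cytosines, cfg$window_alpha, cfg$low_cut,
                      cfg$high_cut)
  dmr_genes <- associate_genes(dmrs, genes, cfg$flank)
  hyper <- hypermethylated_genes(ca, genes, "CG", cfg$hyper_min_cytosines,
                                 cfg$hyper_fdr)
  de <- differential_expression(sime$expr, cfg$contrast[1], cfg$contrast[2],
                                fdr = cfg$de_fdr)
  ref_gene <- cfg[["reference_gene"]] %||% genes$gene_id[1]
  # pairwise tissue slopes need at least 3 tissue classes
  coexpr <- if (length(cfg$tissues) >= 3) {
    coexpression(sime$expr, ref_gene, min_r = cfg$coexpr_r)
  } else {
    tibble(gene_id = character(), r = double(), coexpressed = logical())
  }

  # outputs
  write_bed(dmrs, file.path(outdir, "dmrs.bed"))
  readr::write_tsv(dmr_genes, file.path(outdir, "dmr_genes.tsv"), progress = FALSE)
  readr::write_tsv(hyper, file.path(outdir, "hypermethylated_genes.tsv"), progress = FALSE)
  readr::write_tsv(as_tibble(de), file.path(outdir, "differential_expression.tsv"),
                   progress = FALSE)
  readr::write_tsv(profiles, file.path(outdir, "profiles.tsv"), progress = FALSE)
  readr::write_tsv(pca$scores, file.path(outdir, "pca_scores.tsv"), progress = FALSE)
  readr::write_tsv(coexpr, file.path(outdir, "coexpression.tsv"), progress = FALSE)
  for (ti in names(calls)) {
    readr::write_tsv(calls[[ti]], file.path(outdir, paste0("calls_", ti, ".tsv")),
                     progress = FALSE)
  }

  manifest <- list(
    package = "methexpress",
    version = as.character(utils::packageVersion("methexpress")),
    seed = cfg$seed,
    error_rate = err,
    parameters = cfg[order(names(cfg))],
    outputs = sort(list.files(outdir))
  )
  manifest$parameter_hash <- unname(tools::md5sum(
    write_tmp_json(manifest$parameters)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")

  invisible(list(error_rate = err, calls = calls, pca = pca,
                 profiles = profiles, dmrs = dmrs, dmr_genes = dmr_genes,
                 hyper = hyper, de = de, coexpr = coexpr,
                 manifest = manifest, genes = genes, genome = genome,
                 expr = sime$expr))
}

write_tmp_json <- function(x) {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, null = "null")
  f
}
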