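#' Generate a random genome with an unmethylated spike-in chromosome
#'
#' Bases are drawn i.i.d. with the requested G+C fraction. One extra
#' chromosome named `"spikein"` is appended; downstream it is simulated fully
#' unmethylated so that its apparent methylation estimates the bisulfite
#' non-conversion (error) rate, mirroring the unmethylated spike-in control
#' added to bisulfite libraries.
#'
#' @param n_chrom Number of genomic chromosomes (excluding the spike-in).
#' @param chrom_length Length of each chromosome in bp (>= 10 kb recommended).
#' @param gc_fraction Target G+C fraction, in (0, 1).
#' @param seed Integer seed; identical seeds give identical genomes.
#' @param spikein_length Length of the spike-in chromosome in bp.
#' @return A `genome_sequence` named character vector (`chr1`, ...,
#'   `spikein`).
#' @export
generate_genome <- function(n_chrom, chrom_length, gc_fraction, seed,
                            spikein_length = 10000L) {
  if (gc_fraction <= 0 || gc_fraction >= 1) {
    stop_mx("gc_fraction must be strictly between 0 and 1")
  }
  set.seed(seed)
  probs <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
             G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  draw <- function(n) paste(sample(names(probs), n, replace = TRUE, prob = probs),
                            collapse = "")
  seqs <- vapply(seq_len(n_chrom), function(i) draw(chrom_length), character(1))
  names(seqs) <- paste0("chr", seq_len(n_chrom))
  seqs <- c(seqs, spikein = draw(spikein_length))
  structure(seqs, class = "genome_sequence")
}

#' Catalogue every cytosine with its strand and sequence context
#'
#' Both strands are scanned; a minus-strand cytosine appears as `G` on the
#' reference and its context is read from the reverse complement. Contexts
#' are `CG`, `CHG` and `CHH` (H = A, C or T). Sites whose 3' context bases
#' contain `N` are skipped; sites within 2 bp of a chromosome end whose
#' context cannot be fully determined fall back to the broadest class
#' consistent with the visible bases (`CHH`, or `CG` when the immediate
#' neighbour is visible and is G).
#'
#' @param genome A `genome_sequence` (named character vector).
#' @return Tibble with `chrom`, `pos` (0-based), `strand`, `context`, sorted
#'   by chromosome and position.
#' @export
annotate_contexts <- function(genome) {
  res <- purrr::imap(as.list(unclass(genome)), function(s, chrom) {
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    L <- length(b)
    at <- function(i) ifelse(i >= 1 & i <= L, b[pmax(pmin(i, L), 1)], NA_character_)
    ctx_of <- function(n1, n2) {
      # n1 = first downstream base (5'->3' on the cytosine's own strand)
      ctx <- ifelse(is.na(n1), "CHH",
             ifelse(n1 == "G", "CG",
             ifelse(is.na(n2), "CHH",
             ifelse(n2 == "G", "CHG", "CHH"))))
      bad <- (!is.na(n1) & n1 == "N") | (!is.na(n1) & n1 != "G" & !is.na(n2) & n2 == "N")
      ctx[bad] <- NA_character_
      ctx
    }
    ip <- which(b == "C")
    im <- which(b == "G")
    plus <- if (length(ip)) {
      tibble(chrom = chrom, pos = ip - 1L, strand = "+",
             context = ctx_of(at(ip + 1L), at(ip + 2L)))
    } else NULL
    minus <- if (length(im)) {
      comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
      cmp <- function(x) ifelse(is.na(x), NA_character_, unname(comp[x]))
      tibble(chrom = chrom, pos = im - 1L, strand = "-",
             context = ctx_of(cmp(at(im - 1L)), cmp(at(im - 2L))))
    } else NULL
    bind_rows(plus, minus)
  })
  bind_rows(res) %>%
    filter(!is.na(.data$context)) %>%
    arrange(match(.data$chrom, names(genome)), .data$pos, .data$strand)
}

#' Describe the methylome ground truth for simulation
#'
#' @param rates Named numeric vector of per-context baseline methylation
#'   probabilities, names `CG`, `CHG`, `CHH`; plant-typical ordering is
#'   CG > CHG > CHH.
#' @param body_cg_multiplier Multiplier applied to the CG rate inside exons
#'   (gene-body CG enrichment); capped so rates stay <= 1.
#' @param planted_dmrs Tibble with `chrom`, `start`, `end` (0-based
#'   half-open), `tissue_high`, `rate_high`, `rate_low`. For recoverability
#'   under the 30/70 classification rule, `rate_high` must be > 0.7 and
#'   `rate_low` < 0.3.
#' @param error_rate Bisulfite non-conversion rate; must lie in the
#'   spike-in-plausible range \[1e-4, 3.3e-3\].
#' @param coverage_mean Mean per-site read depth (Poisson).
#' @param flip_fraction Fraction of sites whose true state is flipped in
#'   every tissue after the first, relative to the first tissue (a different
#'   random site subset per tissue). Emulates broad tissue-specific
#'   methylation differences, e.g. for testing sample discrimination by PCA;
#'   default 0 (tissues identical outside planted DMRs).
#' @return List of class `methylome_truth`.
#' @export
methylome_truth <- function(rates = c(CG = 0.75, CHG = 0.45, CHH = 0.05),
                            body_cg_multiplier = 1,
                            planted_dmrs = NULL,
                            error_rate = 0.002,
                            coverage_mean = 8,
                            flip_fraction = 0) {
  if (!all(METH_CONTEXTS %in% names(rates))) stop_mx("rates must name CG, CHG, CHH")
  if (any(rates < 0 | rates > 1)) stop_mx("rates must lie in [0,1]")
  if (error_rate < 0 || error_rate > 0.0033) {
    stop_mx("error_rate outside the spike-in-plausible range [0, 0.0033]")
  }
  if (!is.null(planted_dmrs)) {
    planted_dmrs <- as_tibble(planted_dmrs)
    if (any(planted_dmrs$rate_high <= 0.7) || any(planted_dmrs$rate_low >= 0.3)) {
      stop_mx("planted DMRs need rate_high > 0.7 and rate_low < 0.3")
    }
    by_chr <- split(planted_dmrs, planted_dmrs$chrom)
    for (d in by_chr) {
      d <- d[order(d$start), ]
      if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])) {
        stop_mx("planted DMR intervals overlap")
      }
    }
  }
  if (flip_fraction < 0 || flip_fraction > 1) {
    stop_mx("flip_fraction must lie in [0, 1]")
  }
  structure(list(rates = rates, body_cg_multiplier = body_cg_multiplier,
                 planted_dmrs = planted_dmrs, error_rate = error_rate,
                 coverage_mean = coverage_mean, flip_fraction = flip_fraction),
            class = "methylome_truth")
}

#' Simulate bisulfite count tables for several tissues and replicates
#'
#' Site-level simulation: each cytosine has a true binary methylation state
#' drawn once with its regional rate and shared by all tissues and
#' replicates, so that outside planted differences the tissues are a true
#' null background and replicates differ only by read-sampling noise.
#' Tissue-specific truth enters in two ways: inside a planted DMR interval
#' the state is re-drawn per tissue with `rate_high` (for `tissue_high`) or
#' `rate_low` (all other tissues); and when `truth$flip_fraction > 0` every
#' tissue after the first has the state flipped at that fraction of sites
#' (a tissue-specific random subset). Per replicate, coverage is Poisson
#' and the observed methylated count is binomial with success probability
#' `1 - error_rate` at truly methylated sites and `error_rate` (bisulfite
#' non-conversion) at unmethylated ones. Sites drawing zero coverage are
#' omitted from that replicate's table. The `spikein` chromosome is forced
#' fully unmethylated.
#'
#' Regional rates: per-context baselines, multiplied by
#' `truth$body_cg_multiplier` for CG sites inside exons.
#'
#' @param genome A `genome_sequence`.
#' @param genes Gene-model tibble (see [read_gene_models()]); may be `NULL`.
#' @param truth A [methylome_truth()] object.
#' @param tissues Character vector of tissue labels.
#' @param n_replicates Replicates per tissue.
#' @param seed Integer seed.
#' @return List with `tables` (named list `tissue_rep` of methcounts tibbles,
#'   spike-in rows included under chromosome `"spikein"`), `sites` (the
#'   context catalogue) and `truth`.
#' @export
simulate_methylome <- function(genome, genes, truth, tissues, n_replicates, seed) {
  stopifnot(inherits(truth, "methylome_truth"))
  set.seed(seed)
  sites <- annotate_contexts(genome)
  ns <- nrow(sites)
  base_rate <- unname(truth$rates[sites$context])
  if (!is.null(genes) && truth$body_cg_multiplier != 1) {
    in_exon <- rep(FALSE, ns)
    for (i in seq_len(nrow(genes))) {
      ex <- genes$exons[[i]]
      on_chr <- which(sites$chrom == genes$chrom[i])
      if (!length(on_chr)) next
      p <- sites$pos[on_chr]
      hit <- rep(FALSE, length(p))
      for (j in seq_len(nrow(ex))) hit <- hit | (p >= ex[j, "start"] & p < ex[j, "end"])
      in_exon[on_chr] <- in_exon[on_chr] | hit
    }
    is_cg <- sites$context == "CG"
    base_rate[in_exon & is_cg] <- pmin(1, base_rate[in_exon & is_cg] * truth$body_cg_multiplier)
  }
  base_rate[sites$chrom == "spikein"] <- 0

  # one shared baseline state: tissues are a null background except where
  # truth plants differences
  base_state <- rbinom(ns, 1L, base_rate)
  pd <- truth$planted_dmrs
  state_for <- function(tissue, first_tissue) {
    state <- base_state
    if (!is.null(pd)) {
      for (i in seq_len(nrow(pd))) {
        sel <- sites$chrom == pd$chrom[i] & sites$pos >= pd$start[i] &
          sites$pos < pd$end[i]
        r <- if (identical(tissue, pd$tissue_high[i])) pd$rate_high[i] else pd$rate_low[i]
        state[sel] <- rbinom(sum(sel), 1L, r)
      }
    }
    if (truth$flip_fraction > 0 && !identical(tissue, first_tissue)) {
      flip <- runif(ns) < truth$flip_fraction & sites$chrom != "spikein"
      state[flip] <- 1L - state[flip]
    }
    state[sites$chrom == "spikein"] <- 0L
    state
  }

  err <- truth$error_rate
  tables <- list()
  for (tissue in tissues) {
    state <- state_for(tissue, tissues[1])
    emit_p <- ifelse(state == 1L, 1 - err, err)
    for (rep_i in seq_len(n_replicates)) {
      cov <- rpois(ns, truth$coverage_mean)
      keep <- cov > 0
      meth <- integer(ns)
      meth[keep] <- rbinom(sum(keep), cov[keep], emit_p[keep])
      tab <- tibble(chrom = sites$chrom[keep], pos = sites$pos[keep],
                    strand = sites$strand[keep], context = sites$context[keep],
                    meth = meth[keep], total = as.integer(cov[keep]))
      tables[[paste0(tissue, "_rep", rep_i)]] <- tab
    }
  }
  list(tables = tables, sites = sites, truth = truth)
}

#' Extract the spike-in rows of a methcounts table
#'
#' @param table Methcounts tibble.
#' @param spikein_chrom Name of the spike-in chromosome.
#' @return Tibble of spike-in sites.
#' @export
spikein_sites <- function(table, spikein_chrom = "spikein") {
  filter(table, .data$chrom == spikein_chrom)
}

#' Describe the expression ground truth for simulation
#'
#' @param n_genes Number of genes.
#' @param planted_de Tibble with `gene_id`, `tissue_up`, `log2fc` (> 0).
#' @param coexpr_module List with `reference`, `members` (gene ids) and
#'   `target_r` (target Pearson correlation of tissue profiles), or `NULL`.
#' @param dispersion Negative-binomial dispersion (> 0).
#' @param baseline_means Optional named per-gene baseline means; drawn
#'   log-normally when `NULL`.
#' @return List of class `expression_truth`.
#' @export
expression_truth <- function(n_genes = 2000,
                             planted_de = NULL,
                             coexpr_module = NULL,
                             dispersion = 0.05,
                             baseline_means = NULL) {
  if (dispersion <= 0) stop_mx("dispersion must be > 0")
  if (!is.null(planted_de)) {
    planted_de <- as_tibble(planted_de)
    if (any(planted_de$log2fc <= 0)) stop_mx("planted log2 fold changes must be > 0")
  }
  structure(list(n_genes = n_genes, planted_de = planted_de,
                 coexpr_module = coexpr_module, dispersion = dispersion,
                 baseline_means = baseline_means),
            class = "expression_truth")
}

#' Simulate an RNA-seq counts matrix with planted structure
#'
#' Counts are negative-binomial around tissue-specific means. Differential
#' expression is planted multiplicatively (`2^log2fc` in `tissue_up`).
#' Coexpression-module members' tissue-mean profiles are affine transforms of
#' the reference gene's profile plus Gaussian noise whose variance is
#' calibrated so the profile correlation hits `target_r` in expectation.
#' Per-sample means are scaled so every library's expected size equals
#' `library_size`.
#'
#' @param genes Optional gene-model tibble supplying gene ids and lengths;
#'   when `NULL`, `truth$n_genes` synthetic genes of length 1--5 kb are used.
#' @param truth An [expression_truth()] object.
#' @param tissues Character vector of tissue labels.
#' @param n_replicates Replicates per tissue.
#' @param library_size Expected reads per library.
#' @param seed Integer seed.
#' @return List with `expr` (an `expr_matrix`) and `truth` (the input truth
#'   plus the realised tissue-mean profile matrix `profiles`).
#' @export
simulate_expression <- function(genes = NULL, truth, tissues, n_replicates,
                                library_size = 2e6, seed) {
  stopifnot(inherits(truth, "expression_truth"))
  if (library_size <= 0) stop_mx("library_size must be > 0")
  set.seed(seed)
  if (!is.null(genes)) {
    gene_ids <- genes$gene_id
    lens <- purrr::map_int(genes$exons, ~ sum(.x[, "end"] - .x[, "start"]))
    lengths <- setNames(as.numeric(lens), gene_ids)
  } else {
    gene_ids <- sprintf("g%04d", seq_len(truth$n_genes))
    lengths <- setNames(round(runif(length(gene_ids), 1000, 5000)), gene_ids)
  }
  ng <- length(gene_ids)
  nt <- length(tissues)
  base <- truth$baseline_means %||%
    setNames(rlnorm(ng, meanlog = log(100), sdlog = 1), gene_ids)
  base <- base[gene_ids]

  # tissue-mean profile matrix (genes x tissues), multiplicative effects
  prof <- matrix(rep(base, nt), nrow = ng, dimnames = list(gene_ids, tissues))
  if (!is.null(truth$planted_de)) {
    for (i in seq_len(nrow(truth$planted_de))) {
      g <- truth$planted_de$gene_id[i]
      tu <- truth$planted_de$tissue_up[i]
      if (!g %in% gene_ids) stop_mx(paste0("planted DE gene not in gene set: ", g))
      if (!tu %in% tissues) stop_mx(paste0("planted DE tissue unknown: ", tu))
      prof[g, tu] <- prof[g, tu] * 2^truth$planted_de$log2fc[i]
    }
  }
  cm <- truth$coexpr_module
  if (!is.null(cm)) {
    ref <- cm$reference
    if (!ref %in% gene_ids) stop_mx("coexpression reference gene not in gene set")
    # the reference is a strongly tissue-specific gene: its log-profile is
    # standardised so the contrast is guaranteed, not left to chance
    z <- rnorm(nt)
    z <- (z - mean(z)) / sd(z)
    prof[ref, ] <- base[ref] * exp(1.2 * z)
    x <- prof[ref, ]
    target_r <- cm$target_r %||% 0.95
    zx <- (x - mean(x)) / sd(x)
    for (g in cm$members) {
      if (!g %in% gene_ids) stop_mx(paste0("module member not in gene set: ", g))
      # orthogonalised noise: the member's tissue-mean profile correlates
      # with the reference at exactly target_r before count noise
      e <- rnorm(nt)
      e <- e - mean(e) - zx * sum(e * zx) / sum(zx * zx)
      ze <- e / sqrt(sum(e^2) / (nt - 1))
      y <- target_r * zx + sqrt(1 - target_r^2) * ze
      y <- y - min(y) + 0.25                      # keep positive
      prof[g, ] <- y * base[g] / mean(y)          # rescale to the gene's level
    }
  }

  # balance the unplanted background so every tissue's total expression is
  # identical: planted fold changes and module correlations then survive
  # library-size normalisation undistorted (no compositional artefact)
  special <- character(0)
  if (!is.null(truth$planted_de)) special <- c(special, truth$planted_de$gene_id)
  if (!is.null(cm)) special <- c(special, cm$reference, cm$members)
  bg <- setdiff(gene_ids, special)
  if (length(bg) > 0 && length(special) > 0) {
    tot <- colSums(prof)
    target <- mean(tot)
    need <- target - colSums(prof[special, , drop = FALSE])
    f <- need / colSums(prof[bg, , drop = FALSE])
    if (all(f > 0)) prof[bg, ] <- sweep(prof[bg, , drop = FALSE], 2, f, "*")
  }

  samples <- tidyr::expand_grid(tissue = tissues, replicate = seq_len(n_replicates)) %>%
    mutate(sample_id = paste0(.data$tissue, "_rep", .data$replicate)) %>%
    select("sample_id", "tissue", "replicate")
  counts <- matrix(0L, ng, nrow(samples),
                   dimnames = list(gene_ids, samples$sample_id))
  scale_all <- library_size / mean(colSums(prof))
  for (j in seq_len(nrow(samples))) {
    mu <- prof[, samples$tissue[j]] * scale_all
    counts[, j] <- rnbinom(ng, mu = mu, size = 1 / truth$dispersion)
  }
  expr <- expression_matrix(counts, lengths = lengths, samples = samples)
  truth$profiles <- prof
  list(expr = expr, truth = truth)
}

#' Generate non-overlapping synthetic gene models
#'
#' Convenience generator used by tests and the pipeline: genes of the given
#' body length, single- or two-exon, placed on the genomic chromosomes with
#' at least `gap` bp between neighbours and `flank` bp clear of chromosome
#' ends (so 2-kb flank windows are never truncated).
#'
#' @param genome A `genome_sequence`.
#' @param n_genes Number of genes to place.
#' @param gene_length Gene body length in bp.
#' @param gap Minimum spacing between genes; the default keeps every
#'   gene's 2-kb flanks clear of neighbouring gene bodies.
#' @param flank Clearance kept at chromosome ends.
#' @param seed Integer seed.
#' @return Gene-model tibble as from [read_gene_models()].
#' @export
generate_gene_models <- function(genome, n_genes, gene_length = 1500L,
                                 gap = 2500L, flank = 2100L, seed = 1L) {
  set.seed(seed)
  chroms <- setdiff(names(genome), "spikein")
  lens <- nchar(unclass(genome))[chroms]
  slots <- purrr::map(chroms, function(ch) {
    starts <- seq(flank, lens[[ch]] - flank - gene_length, by = gene_length + gap)
    if (!length(starts)) return(NULL)
    tibble(chrom = ch, start = as.integer(starts))
  })
  slots <- bind_rows(slots)
  if (nrow(slots) < n_genes) stop_mx("genome too small for the requested gene count")
  slots <- slots[sort(sample.int(nrow(slots), n_genes)), ]
  slots %>%
    mutate(gene_id = sprintf("g%04d", row_number()),
           strand = sample(c("+", "-"), n(), replace = TRUE),
           end = .data$start + gene_length,
           exons = purrr::map2(.data$start, .data$end,
                               ~ cbind(start = .x, end = .y))) %>%
    select("gene_id", "chrom", "strand", "start", "end", "exons")
}

#' Write a simulated study to disk
#'
#' Emits everything a downstream run reads: the genome FASTA, gene models as
#' BED12, one methcounts TSV per tissue x replicate, the counts matrix and
#' sample sheet, and a `truth.json` recording planted DMRs, DE genes and
#' module membership for assertions.
#'
#' @param sim_meth Result of [simulate_methylome()].
#' @param sim_expr Result of [simulate_expression()], or `NULL`.
#' @param genome A `genome_sequence`.
#' @param genes Gene-model tibble.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_study <- function(sim_meth, sim_expr, genome, genes, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(genome, file.path(dir, "genome.fa"))
  bed12 <- gene_models_to_bed12(genes)
  writeLines(bed12, file.path(dir, "genes.bed"))
  for (nm in names(sim_meth$tables)) {
    write_methcounts(sim_meth$tables[[nm]], file.path(dir, paste0(nm, ".methcounts.tsv")))
  }
  truth <- list(
    planted_dmrs = sim_meth$truth$planted_dmrs,
    error_rate = sim_meth$truth$error_rate,
    rates = as.list(sim_meth$truth$rates)
  )
  if (!is.null(sim_expr)) {
    write_counts_matrix(sim_expr$expr, file.path(dir, "counts.tsv"),
                        file.path(dir, "samples.tsv"))
    truth$planted_de <- sim_expr$truth$planted_de
    truth$coexpr_module <- sim_expr$truth$coexpr_module
  }
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

gene_models_to_bed12 <- function(genes) {
  vapply(seq_len(nrow(genes)), function(i) {
    ex <- genes$exons[[i]]
    sizes <- ex[, "end"] - ex[, "start"]
    offs <- ex[, "start"] - genes$start[i]
    paste(genes$chrom[i], genes$start[i], genes$end[i], genes$gene_id[i], 0,
          genes$strand[i], genes$start[i], genes$end[i], 0, nrow(ex),
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(offs, collapse = ","), ","),
          sep = "\t")
  }, character(1))
}
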