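#' Define metagene bins for one gene
#'
#' Builds the 300 bins of the metagene coordinate system: 100 fixed 20-bp
#' windows upstream of the gene start, 100 near-equal bins partitioning the
#' exon-concatenated gene body, and 100 fixed 20-bp windows downstream of the
#' gene end. Bins are numbered 1..100 within each region in the gene's own
#' 5'->3' orientation (minus-strand genes reversed). A body bin that spans an
#' exon junction maps to more than one genomic interval, so the result is one
#' row per genomic piece.
#'
#' Genes with total exonic length below `min_exonic_bp` cannot host 100
#' body bins and return `NULL`.
#'
#' @param gene One row of a gene-model tibble (list or 1-row tibble with
#'   `gene_id`, `chrom`, `strand`, `start`, `end`, `exons`).
#' @param flank_bp Flank width (default 2000).
#' @param flank_window Flank window size (default 20).
#' @param body_bins Number of gene-body bins (default 100).
#' @param min_exonic_bp Minimum exonic length (default 100).
#' @param chrom_length Optional chromosome length; flank bins extending past
#'   either end are truncated and flagged.
#' @return Tibble with `gene_id`, `region` (`upstream`/`body`/`downstream`),
#'   `bin` (1-based), `chrom`, `start`, `end` (0-based half-open, genomic),
#'   `truncated`; or `NULL` for a too-short gene.
#' @export
bin_gene <- function(gene, flank_bp = 2000L, flank_window = 20L,
                     body_bins = 100L, min_exonic_bp = 100L,
                     chrom_length = NULL) {
  ex <- gene$exons[[1]] %||% gene$exons
  if (is.list(ex) && !is.matrix(ex)) ex <- ex[[1]]
  exonic <- sum(ex[, "end"] - ex[, "start"])
  if (exonic < min_exonic_bp) return(NULL)
  n_flank <- as.integer(flank_bp / flank_window)
  minus <- gene$strand == "-"

  # genomic-left and genomic-right flank windows
  left <- tibble(start = seq(gene$start - flank_bp, gene$start - flank_window,
                             by = flank_window)) %>%
    mutate(end = .data$start + flank_window)
  right <- tibble(start = seq(gene$end, gene$end + flank_bp - flank_window,
                              by = flank_window)) %>%
    mutate(end = .data$start + flank_window)
  # 5'->3': for + genes, upstream = left with bin 1 farthest from the gene;
  # for - genes, upstream = right with bin 1 farthest (largest start).
  if (!minus) {
    up <- left %>% mutate(bin = row_number())
    down <- right %>% mutate(bin = row_number())
  } else {
    up <- right %>% mutate(bin = rev(row_number()))
    down <- left %>% mutate(bin = rev(row_number()))
  }
  up$region <- "upstream"; down$region <- "downstream"

  # body: partition the exon-concatenated coordinate into body_bins pieces
  # whose lengths differ by at most 1 bp, then map back to the genome
  base_len <- exonic %/% body_bins
  rem <- exonic %% body_bins
  bin_len <- rep(base_len, body_bins) + c(rep(1L, rem), rep(0L, body_bins - rem))
  bounds <- cumsum(c(0L, bin_len))                # concatenated coords
  ex_sorted <- ex[order(ex[, "start"]), , drop = FALSE]
  ex_len <- ex_sorted[, "end"] - ex_sorted[, "start"]
  ex_off <- cumsum(c(0L, ex_len[-length(ex_len)]))  # concat offset per exon
  body <- purrr::map(seq_len(body_bins), function(b) {
    lo <- bounds[b]; hi <- bounds[b + 1]          # concat interval [lo, hi)
    pieces <- purrr::map(seq_len(nrow(ex_sorted)), function(e) {
      s <- max(lo, ex_off[e]); t <- min(hi, ex_off[e] + ex_len[e])
      if (s >= t) return(NULL)
      tibble(start = as.integer(unname(ex_sorted[e, "start"] + (s - ex_off[e]))),
             end = as.integer(unname(ex_sorted[e, "start"] + (t - ex_off[e]))))
    })
    bind_rows(pieces) %>% mutate(bin = if (minus) body_bins - b + 1L else b)
  })
  body <- bind_rows(body) %>% mutate(region = "body")

  out <- bind_rows(up, body, down) %>%
    mutate(gene_id = gene$gene_id, chrom = gene$chrom, truncated = FALSE) %>%
    select("gene_id", "region", "bin", "chrom", "start", "end", "truncated")
  # clip flanks at chromosome boundaries
  max_end <- chrom_length %||% Inf
  clip <- out$start < 0 | out$end > max_end
  if (any(clip)) {
    out$truncated <- clip
    out$start <- pmax(out$start, 0L)
    out$end <- pmin(out$end, max_end)
    out <- filter(out, .data$end > .data$start)
  }
  out
}

#' Bin definitions for many genes
#'
#' @inheritParams bin_gene
#' @param genes Gene-model tibble.
#' @param chrom_lengths Optional named vector of chromosome lengths.
#' @return Long tibble of bins for all genes with exonic length >=
#'   `min_exonic_bp`; skipped genes recorded in attribute `skipped`.
#' @export
bin_genes <- function(genes, flank_bp = 2000L, flank_window = 20L,
                      body_bins = 100L, min_exonic_bp = 100L,
                      chrom_lengths = NULL) {
  res <- purrr::map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    bin_gene(list(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
                  start = g$start, end = g$end, exons = g$exons),
             flank_bp, flank_window, body_bins, min_exonic_bp,
             chrom_length = chrom_lengths[[g$chrom]] %||% NULL)
  })
  skipped <- genes$gene_id[purrr::map_lgl(res, is.null)]
  out <- bind_rows(res)
  attr(out, "skipped") <- skipped
  out
}

#' Metagene methylation profile of one sample
#'
#' Per gene and bin, the fraction of binomially-called methylated marks among
#' cytosines of the context covered at >= 4x; the profile value of a bin is
#' the unweighted mean of these per-gene fractions over genes where the bin
#' has at least one covered cytosine.
#'
#' @param calls Call tibble from [call_methylation()].
#' @param bins Long bin tibble from [bin_genes()].
#' @param context Context to profile (`"CG"`, `"CHG"` or `"CHH"`).
#' @return Tibble with `region`, `bin`, `level` (mean fraction), `n_genes`
#'   (genes contributing).
#' @export
profile_sample <- function(calls, bins, context) {
  sites <- calls %>%
    filter(.data$status != "uncallable", .data$context %in% !!context)
  if (nrow(bins) == 0) stop_mx("no eligible genes to profile")
  per_bin <- overlap_sites_bins(sites, bins)
  per_gene_bin <- per_bin %>%
    group_by(.data$gene_id, .data$region, .data$bin) %>%
    summarise(covered = n(),
              marks = sum(.data$status == "methylated"), .groups = "drop") %>%
    mutate(frac = .data$marks / .data$covered)
  grid <- tidyr::expand_grid(
    region = c("upstream", "body", "downstream"),
    bin = seq_len(max(bins$bin))
  )
  per_gene_bin %>%
    group_by(.data$region, .data$bin) %>%
    summarise(level = mean(.data$frac), n_genes = n(), .groups = "drop") %>%
    dplyr::right_join(grid, by = c("region", "bin")) %>%
    arrange(factor(.data$region, levels = c("upstream", "body", "downstream")),
            .data$bin)
}

# assign point sites to bin intervals (possibly several bins per site where
# 100-bp DMR windows overlap does not apply here; bins are disjoint per gene
# but flank bins of neighbouring genes may both catch a site)
overlap_sites_bins <- function(sites, bins) {
  purrr::map(split(seq_len(nrow(bins)), bins$chrom), function(idx) {
    bch <- bins[idx, ]
    sch <- sites[sites$chrom == bch$chrom[1], ]
    if (nrow(sch) == 0) return(NULL)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(sch$pos + 1L, sch$pos + 1L),
      IRanges::IRanges(bch$start + 1L, bch$end)
    )
    dplyr::bind_cols(
      sch[S4Vectors::queryHits(hits), c("pos", "status")],
      bch[S4Vectors::subjectHits(hits), c("gene_id", "region", "bin")]
    )
  }) %>% bind_rows()
}

#' Assign expressed genes to RPKM quartile groups
#'
#' Group 1 is the lowest expression quartile, group 4 the highest.
#' Breakpoints are the 25/50/75 percentiles of RPKM among the expressed
#' genes; a gene whose RPKM ties a breakpoint goes to the lower group (so a
#' constant RPKM vector puts every gene in group 1).
#'
#' @param expr An `expr_matrix`.
#' @param sample Sample id (column) whose RPKM is used.
#' @param expressed Character vector of expressed gene ids (from
#'   [expressed_filter()]).
#' @return Tibble with `gene_id`, `rpkm`, `group` (integer 1--4).
#' @export
expression_quartiles <- function(expr, sample, expressed) {
  r <- rpkm(expr)[, sample]
  r <- r[names(r) %in% expressed]
  if (length(r) < 4) stop_mx("need at least 4 expressed genes for quartiles")
  br <- quantile(r, c(0.25, 0.5, 0.75))
  grp <- 1L + (r > br[1]) + (r > br[2]) + (r > br[3])
  tibble(gene_id = names(r), rpkm = unname(r), group = as.integer(grp))
}

#' Test group differences in regional methylation profiles
#'
#' Kruskal-Wallis across groups on the per-bin average methylation levels of
#' one genic region, followed by Tukey HSD for the pairwise contrasts (run on
#' the same bin values via a one-way ANOVA). Bins are treated as the
#' observational unit; they are autocorrelated along the gene, so the
#' pairwise p-values are anticonservative and should be read comparatively.
#'
#' @param profiles Tibble with columns `group`, `region`, `bin`, `level`
#'   (e.g. several [profile_sample()] results with a `group` label).
#' @param region One of `"upstream"`, `"body"`, `"downstream"`.
#' @param bins50 If `TRUE`, flank bins are aggregated in adjacent pairs to a
#'   50-bin (40-bp) view before testing.
#' @return List with `kw_p`, `kruskal` (htest), `tukey` (tibble of pairwise
#'   contrasts with `diff`, `p_adj`).
#' @export
compare_groups <- function(profiles, region = c("upstream", "body", "downstream"),
                           bins50 = FALSE) {
  region <- match.arg(region)
  d <- profiles %>%
    filter(.data$region == !!region, !is.na(.data$level))
  if (bins50 && region != "body") {
    d <- d %>%
      mutate(bin = (.data$bin + 1L) %/% 2L) %>%
      group_by(.data$group, .data$bin) %>%
      summarise(level = mean(.data$level), .groups = "drop")
  }
  grp_ok <- d %>% group_by(.data$group) %>% summarise(nb = n(), .groups = "drop")
  dropped <- grp_ok$group[grp_ok$nb == 0]
  if (length(dropped)) warn(paste0("groups with no defined bins excluded: ",
                                   paste(dropped, collapse = ", ")))
  d <- filter(d, !.data$group %in% dropped)
  if (dplyr::n_distinct(d$group) < 2) stop_mx("need at least 2 groups with data")
  d$group <- factor(d$group)
  kw <- kruskal.test(level ~ group, data = d)
  tk <- TukeyHSD(aov(level ~ group, data = d))$group
  tukey <- as_tibble(tk, rownames = "contrast") %>%
    rename(diff = "diff", p_adj = "p adj")
  list(kw_p = kw$p.value, kruskal = kw, tukey = tukey)
}

#' Plot metagene methylation profiles
#'
#' @param profiles Tibble with `region`, `bin`, `level` and optionally
#'   `group` columns.
#' @return A ggplot object: level vs metagene coordinate, one panel spanning
#'   upstream / body / downstream.
#' @export
plot_genic_profile <- function(profiles) {
  d <- profiles %>%
    mutate(region = factor(.data$region, levels = c("upstream", "body", "downstream")),
           coord = as.integer(.data$region) * 1000L + .data$bin)
  aes <- if ("group" %in% names(d)) {
    ggplot2::aes(x = .data$coord, y = .data$level, colour = factor(.data$group))
  } else {
    ggplot2::aes(x = .data$coord, y = .data$level)
  }
  ggplot2::ggplot(d, aes) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = c(2000.5, 3000.5), linetype = "dashed",
                        colour = "grey60") +
    ggplot2::scale_x_continuous(
      breaks = c(1050, 2050, 3050),
      labels = c("upstream", "gene body", "downstream")) +
    ggplot2::labs(x = NULL, y = "methylation level", colour = "group") +
    ggplot2::theme_minimal()
}

#' @rdname methylation_pca
#' @param object A `meth_pca` object.
#' @param colour_by Optional vector (length = samples) used for point colour,
#'   e.g. tissue labels.
#' @export
autoplot.meth_pca <- function(object, colour_by = NULL, ...) {
  d <- object$scores
  d$colour_by <- colour_by %||% "sample"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                  colour = .data$colour_by)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2]),
      colour = NULL) +
    ggplot2::theme_minimal()
}
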