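#' Counts per million
#'
#' @param expr An `expr_matrix`.
#' @return Numeric matrix, genes x samples: `count * 1e6 / library size`.
#' @export
cpm <- function(expr) {
  if (any(expr$lib_sizes == 0)) stop_mx("zero library size")
  sweep(expr$counts, 2, expr$lib_sizes, "/") * 1e6
}

#' Reads per kilobase per million
#'
#' @param expr An `expr_matrix` with gene lengths.
#' @return Numeric matrix, genes x samples:
#'   `count * 1e9 / (library size * length bp)`.
#' @export
rpkm <- function(expr) {
  if (is.null(expr$lengths)) {
    stop_mx("RPKM requires gene lengths; the counts file had no length column")
  }
  if (any(expr$lib_sizes == 0)) stop_mx("zero library size")
  cpm(expr) * 1e3 / expr$lengths[rownames(expr$counts)]
}

#' Expressed-gene filter
#'
#' A gene counts as expressed in a tissue when its CPM is at least `min_cpm`
#' in every replicate of that tissue.
#'
#' @param expr An `expr_matrix`.
#' @param tissue Tissue label from the sample sheet.
#' @param min_cpm CPM threshold (default 3, inclusive).
#' @return Character vector of expressed gene ids.
#' @export
expressed_filter <- function(expr, tissue, min_cpm = 3) {
  cols <- expr$samples$sample_id[expr$samples$tissue == tissue]
  if (!length(cols)) stop_mx(paste0("no replicates for tissue: ", tissue))
  cm <- cpm(expr)[, cols, drop = FALSE]
  rownames(cm)[rowSums(cm >= min_cpm) == length(cols)]
}

#' Differential expression by a negative-binomial exact test
#'
#' A deliberately transparent two-group test: median-ratio size factors
#' normalise the libraries, a single common NB dispersion is estimated by
#' the method of moments across genes, and each gene gets an exact
#' conditional test comparing its normalised group sums (the two sums are NB
#' with sizes `n_reps / dispersion`; the p-value sums all splits of the
#' total whose joint probability does not exceed the observed one).
#' Benjamini-Hochberg FDR across genes; a gene is differentially expressed
#' iff `fdr <= 0.05`, with direction given by the sign of the log
#' fold-change.
#'
#' @param expr An `expr_matrix`.
#' @param tissue_a,tissue_b The two tissues to contrast.
#' @param fdr FDR threshold for the `de` flag (default 0.05).
#' @return Tibble with `gene_id`, `log_fc` (log2 B over A), `p_value`,
#'   `fdr`, `de`, `direction` (`"up_b"` / `"up_a"`); all-zero genes are
#'   dropped. Attribute `dispersion` records the common dispersion used.
#' @export
differential_expression <- function(expr, tissue_a, tissue_b, fdr = 0.05) {
  sa <- expr$samples$sample_id[expr$samples$tissue == tissue_a]
  sb <- expr$samples$sample_id[expr$samples$tissue == tissue_b]
  if (length(sa) < 2 || length(sb) < 2) stop_mx("need >= 2 replicates per tissue")
  cts <- expr$counts[, c(sa, sb), drop = FALSE]
  keep <- rowSums(cts) > 0
  cts <- cts[keep, , drop = FALSE]
  sf <- median_ratio_size_factors(cts)
  q <- sweep(cts, 2, sf, "/")                    # normalised counts
  na <- length(sa); nb <- length(sb)
  qa <- q[, sa, drop = FALSE]; qb <- q[, sb, drop = FALSE]

  phi <- common_dispersion_mom(qa, qb)

  ka <- round(rowSums(qa)); kb <- round(rowSums(qb))
  pv <- nb_exact_test(ka, kb, na, nb, phi)
  lfc <- log2((kb / nb + 0.125) / (ka / na + 0.125))
  out <- tibble(gene_id = rownames(cts), log_fc = lfc, p_value = pv) %>%
    mutate(fdr = p.adjust(.data$p_value, method = "BH"),
           de = .data$fdr <= !!fdr & abs(.data$log_fc) > 0,
           direction = ifelse(.data$log_fc > 0, "up_b", "up_a")) %>%
    arrange(.data$p_value)
  attr(out, "dispersion") <- phi
  class(out) <- c("methexpress_de", class(out))
  out
}

# DESeq-style median-of-ratios size factors, falling back to library-size
# ratios when no gene is expressed everywhere
median_ratio_size_factors <- function(cts) {
  pos <- rowSums(cts > 0) == ncol(cts)
  if (sum(pos) >= 10) {
    lg <- log(cts[pos, , drop = FALSE])
    ref <- rowMeans(lg)
    sf <- apply(lg, 2, function(col) exp(median(col - ref)))
  } else {
    ls <- colSums(cts)
    sf <- ls / exp(mean(log(ls)))
  }
  sf / exp(mean(log(sf)))
}

# method-of-moments common dispersion: within each group E[s2] = mu + phi*mu^2,
# so phi solves the aggregated moment equation summed over genes and groups
# (aggregating before dividing avoids the downward bias of per-gene ratios)
common_dispersion_mom <- function(qa, qb) {
  parts <- purrr::map(list(qa, qb), function(m) {
    mu <- rowMeans(m)
    v <- apply(m, 1, var)
    ok <- mu > 1
    c(num = sum(v[ok] - mu[ok]), den = sum(mu[ok]^2))
  })
  num <- sum(purrr::map_dbl(parts, "num"))
  den <- sum(purrr::map_dbl(parts, "den"))
  if (den <= 0) return(1e-4)
  max(num / den, 1e-4)
}

# exact conditional NB test on group sums: sums of r iid NB(mu, 1/phi) are
# NB(r*mu, r/phi); condition on the total and sum the probabilities of all
# splits at most as likely as the observed split
nb_exact_test <- function(ka, kb, na, nb, phi) {
  vapply(seq_along(ka), function(i) {
    t <- ka[i] + kb[i]
    if (t == 0) return(1)
    mu <- t / (na + nb)
    xs <- 0:t
    fa <- dnbinom(xs, size = na / phi, mu = na * mu, log = TRUE)
    fb <- dnbinom(t - xs, size = nb / phi, mu = nb * mu, log = TRUE)
    lp <- fa + fb
    obs <- lp[ka[i] + 1]
    tot <- logsumexp(lp)
    min(1, exp(logsumexp(lp[lp <= obs + 1e-10]) - tot))
  }, numeric(1))
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Replicate quality control on FPKM
#'
#' Squared Pearson correlation of the (untransformed) FPKM vectors for every
#' replicate pair within each sample class.
#'
#' @param expr An `expr_matrix` with gene lengths.
#' @return Tibble with `tissue`, `rep_a`, `rep_b`, `r_squared`.
#' @export
replicate_qc <- function(expr) {
  fpkm <- rpkm(expr)
  out <- purrr::map(unique(expr$samples$tissue), function(ti) {
    cols <- expr$samples$sample_id[expr$samples$tissue == ti]
    if (length(cols) < 2) return(NULL)
    prs <- utils::combn(cols, 2)
    tibble(tissue = ti, rep_a = prs[1, ], rep_b = prs[2, ],
           r_squared = apply(prs, 2, function(p) cor(fpkm[, p[1]], fpkm[, p[2]])^2))
  })
  bind_rows(out)
}

#' Focal-class enrichment filter
#'
#' Keeps a gene when, for at least one focal class, its expression is
#' strictly more than `fold` times the value in every contrast class and the
#' gene's q-value is at or below `q_max`. This is the vascular-enrichment
#' rule (> 1.2-fold above all nonvascular classes at q <= 0.001).
#'
#' @param expr_by_class Matrix or data frame of per-class expression values,
#'   genes x classes, with rownames.
#' @param focal_classes,contrast_classes Column names.
#' @param q_values Named per-gene q-values.
#' @param fold Fold threshold (strict >; default 1.2).
#' @param q_max Significance threshold (inclusive; default 0.001).
#' @return Character vector of kept gene ids.
#' @export
enrichment_filter <- function(expr_by_class, focal_classes, contrast_classes,
                              q_values, fold = 1.2, q_max = 0.001) {
  m <- as.matrix(expr_by_class)
  contr_max <- apply(m[, contrast_classes, drop = FALSE], 1, max)
  hit <- rep(FALSE, nrow(m))
  for (fc in focal_classes) {
    hit <- hit | (m[, fc] > fold * contr_max)
  }
  q <- q_values[rownames(m)]
  rownames(m)[hit & !is.na(q) & q <= q_max]
}

#' Pairwise-slope Pearson correlation of two expression profiles
#'
#' For every ordered pair of distinct tissue classes the slope of the line
#' connecting the gene's RPKM in the first tissue to the second is taken
#' (the difference RPKM_j - RPKM_i, both directions of each pair); the
#' correlation between two genes is the Pearson correlation of their slope
#' vectors. Because each pair contributes its slope with both signs, the
#' slope vectors have mean zero and the statistic equals the plain Pearson
#' correlation of the tissue-value vectors exactly - a fact the test-suite
#' verifies by brute force.
#'
#' @param reference,query Numeric vectors of per-tissue values on the same
#'   >= 3 tissue classes.
#' @return Pearson r in \[-1, 1\]; errors on a constant profile.
#' @export
pairwise_slope_correlation <- function(reference, query) {
  if (length(reference) != length(query) || length(reference) < 3) {
    stop_mx("profiles must share the same >= 3 tissue classes")
  }
  slopes <- function(x) {
    d <- outer(x, x, "-")
    d[row(d) != col(d)]
  }
  ds <- slopes(reference); dq <- slopes(query)
  if (sd(ds) == 0 || sd(dq) == 0) {
    stop_mx("constant profile: slope correlation undefined",
            class = "methexpress_undefined")
  }
  cor(ds, dq)
}

#' Rank genes by coexpression with a reference gene
#'
#' Tissue-mean RPKM profiles are correlated by [pairwise_slope_correlation()]
#' against the reference gene; genes with r >= `min_r` are flagged
#' coexpressed.
#'
#' @param expr An `expr_matrix` with gene lengths.
#' @param reference_gene Gene id.
#' @param min_r Coexpression threshold (default 0.9, inclusive).
#' @param genes Optional subset of query gene ids.
#' @return Tibble with `gene_id`, `r`, `coexpressed`, sorted by decreasing
#'   `r`; constant-profile genes are skipped.
#' @export
coexpression <- function(expr, reference_gene, min_r = 0.9, genes = NULL) {
  prof <- tissue_mean_rpkm(expr)
  if (!reference_gene %in% rownames(prof)) stop_mx("reference gene not found")
  ref <- prof[reference_gene, ]
  if (sd(ref) == 0) stop_mx("reference gene has a constant profile")
  ids <- genes %||% setdiff(rownames(prof), reference_gene)
  r <- vapply(ids, function(g) {
    tryCatch(pairwise_slope_correlation(ref, prof[g, ]),
             methexpress_undefined = function(e) NA_real_)
  }, numeric(1))
  tibble(gene_id = ids, r = r) %>%
    filter(!is.na(.data$r)) %>%
    mutate(coexpressed = .data$r >= min_r) %>%
    arrange(dplyr::desc(.data$r))
}

#' Per-tissue mean RPKM matrix
#'
#' @param expr An `expr_matrix` with gene lengths.
#' @return Matrix, genes x tissues, of replicate-averaged RPKM.
#' @export
tissue_mean_rpkm <- function(expr) {
  r <- rpkm(expr)
  tis <- unique(expr$samples$tissue)
  out <- vapply(tis, function(ti) {
    cols <- expr$samples$sample_id[expr$samples$tissue == ti]
    rowMeans(r[, cols, drop = FALSE])
  }, numeric(nrow(r)))
  colnames(out) <- tis
  out
}

#' @rdname differential_expression
#' @param x A tibble returned by [differential_expression()].
#' @param ... Unused.
#' @export
glance.methexpress_de <- function(x, ...) {
  tibble(n_genes = nrow(x), n_de = sum(x$de),
         n_up_b = sum(x$de & x$direction == "up_b"),
         n_up_a = sum(x$de & x$direction == "up_a"),
         dispersion = attr(x, "dispersion"))
}
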