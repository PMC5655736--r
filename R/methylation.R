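#' Pool replicate methylation count tables
#'
#' Per (chrom, pos, strand): read depth `n` is the sum of per-replicate
#' coverage and `k` the sum of methylated reads, over the replicates that
#' cover the site. Replicates must agree on the context of every shared
#' position.
#'
#' @param tables List of methcounts tibbles (same genome).
#' @return Tibble with `chrom`, `pos`, `strand`, `context`, `k`, `n`, sorted
#'   by chromosome and position.
#' @export
merge_replicates <- function(tables) {
  if (length(tables) < 1) stop_mx("need at least one replicate")
  all_tab <- bind_rows(tables)
  pooled <- all_tab %>%
    group_by(.data$chrom, .data$pos, .data$strand) %>%
    summarise(n_ctx = dplyr::n_distinct(.data$context),
              context = .data$context[1],
              k = sum(.data$meth), n = sum(.data$total), .groups = "drop")
  if (any(pooled$n_ctx > 1)) {
    stop_mx("conflicting contexts at the same (chrom, pos, strand)")
  }
  pooled %>%
    select("chrom", "pos", "strand", "context", "k", "n") %>%
    arrange(.data$chrom, .data$pos, .data$strand)
}

#' Estimate the bisulfite non-conversion rate from spike-in counts
#'
#' The spike-in control is fully unmethylated, so its pooled methylated-read
#' fraction (total methylated reads over total reads) estimates the error
#' rate used as the binomial success probability in site calling. A warning
#' is issued when the estimate falls outside the plausible spike-in range
#' 0.01--0.33%. When the spike-in shows zero methylated reads the
#' `floor` (default 1e-4, the low end of that range) is returned so the
#' binomial test never degenerates.
#'
#' @param spikein Pooled site tibble (columns `k`, `n`) restricted to the
#'   spike-in chromosome.
#' @param floor Lower bound applied to the estimate.
#' @return Error rate in \[0, 1\].
#' @export
estimate_error_rate <- function(spikein, floor = 1e-4) {
  if (nrow(spikein) == 0 || sum(spikein$n) == 0) {
    stop_mx("empty spike-in: cannot estimate the error rate")
  }
  rate <- sum(spikein$k) / sum(spikein$n)
  if (rate > 0.0033 || (rate < 1e-4 && rate > 0)) {
    warn(sprintf("spike-in error rate %.2e outside the typical 0.01-0.33%% range", rate))
  }
  max(rate, floor)
}

#' Upper-tail binomial probability B(x >= k; n, p)
#'
#' Exact probability that a Binomial(n, p) variable is at least `k`; the
#' per-cytosine test statistic for methylation calling, with `n` the read
#' depth, `k` the methylated reads and `p` the spike-in error rate.
#'
#' @param k Observed successes (vectorised).
#' @param n Number of trials.
#' @param p Success probability, in (0, 1).
#' @return P(X >= k), in \[0, 1\].
#' @export
binomial_tail <- function(k, n, p) {
  if (any(p <= 0) || any(p >= 1)) stop_mx("p must be strictly inside (0, 1)")
  if (any(k < 0) || any(k > n) || any(n < 0)) stop_mx("need 0 <= k <= n")
  pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' Call methylated cytosines by binomial test with BH-FDR control
#'
#' Sites with read depth below `min_cov` are flagged `uncallable` and
#' excluded from testing. All remaining sites of the sample (all three
#' contexts jointly) form one test family: per site the upper-tail binomial
#' p-value against the error rate, Benjamini-Hochberg q-values across the
#' family, and status `methylated` iff q <= `fdr`.
#'
#' @param pooled Pooled site tibble from [merge_replicates()].
#' @param error_rate Spike-in error rate; values <= 0 are lifted to
#'   `error_floor`.
#' @param min_cov Minimum read depth to test (default 4).
#' @param fdr Site-level FDR threshold (default 0.01).
#' @param error_floor Floor applied to `error_rate`.
#' @return Tibble: the pooled columns plus `p_value`, `q_value`, `status`
#'   (`methylated` / `unmethylated` / `uncallable`); attribute `error_rate`.
#' @export
call_methylation <- function(pooled, error_rate, min_cov = 4L, fdr = 0.01,
                             error_floor = 1e-4) {
  if (nrow(pooled) == 0) stop_mx("empty site table")
  p <- max(error_rate, error_floor)
  out <- pooled %>%
    mutate(p_value = NA_real_, q_value = NA_real_, status = "uncallable")
  testable <- out$n >= min_cov
  if (any(testable)) {
    pv <- binomial_tail(out$k[testable], out$n[testable], p)
    qv <- p.adjust(pv, method = "BH")
    out$p_value[testable] <- pv
    out$q_value[testable] <- qv
    out$status[testable] <- ifelse(qv <= fdr, "methylated", "unmethylated")
  }
  attr(out, "error_rate") <- p
  out
}

#' Weighted methylation level of a set of sites
#'
#' Total methylated reads over total reads (coverage-weighted), as opposed to
#' the unweighted mean of per-site fractions.
#'
#' @param sites Tibble with columns `k` and `n` (use `meth`/`total` tables
#'   via [merge_replicates()] first).
#' @param context Optional context filter (`"CG"`, `"CHG"`, `"CHH"`).
#' @return Level in \[0, 1\]; errors on an empty selection.
#' @export
weighted_level <- function(sites, context = NULL) {
  if (!is.null(context)) sites <- filter(sites, .data$context %in% !!context)
  if (nrow(sites) == 0 || sum(sites$n) == 0) {
    stop_mx("weighted level undefined on an empty selection",
            class = "methexpress_undefined")
  }
  sum(sites$k) / sum(sites$n)
}

#' Pearson correlation of methylation status between two call sets
#'
#' Computed on the binary (0/1) status vectors over sites callable in both
#' sets; the replicate-agreement QC used alongside the methylation-state PCA.
#'
#' @param calls_a,calls_b Call tibbles from [call_methylation()].
#' @return Pearson r; errors when fewer than 2 shared callable sites or a
#'   zero-variance vector.
#' @export
replicate_correlation <- function(calls_a, calls_b) {
  a <- filter(calls_a, .data$status != "uncallable")
  b <- filter(calls_b, .data$status != "uncallable")
  shared <- inner_join(
    select(a, "chrom", "pos", "strand", sa = "status"),
    select(b, "chrom", "pos", "strand", sb = "status"),
    by = c("chrom", "pos", "strand")
  )
  if (nrow(shared) < 2) stop_mx("fewer than 2 shared callable sites")
  x <- as.numeric(shared$sa == "methylated")
  y <- as.numeric(shared$sb == "methylated")
  if (sd(x) == 0 || sd(y) == 0) {
    stop_mx("zero variance in a status vector", class = "methexpress_undefined")
  }
  cor(x, y)
}

#' Build the binary methylation-state matrix for PCA
#'
#' Rows are samples (tissue x replicate), columns the cytosine sites of the
#' requested context covered at >= `min_cov` in every replicate of every
#' sample; entries are 0/1 binomial-call statuses.
#'
#' @param replicate_tables Named list of per-replicate methcounts tibbles
#'   (names become row names).
#' @param error_rate Spike-in error rate for the per-replicate calls.
#' @param context Context to use, or `NULL` for all.
#' @param min_cov Minimum coverage in every replicate.
#' @param fdr Site FDR for the calls.
#' @return Integer matrix, samples x sites, with `chrom:pos:strand` column
#'   names.
#' @export
build_state_matrix <- function(replicate_tables, error_rate, context = NULL,
                               min_cov = 4L, fdr = 0.01) {
  calls <- purrr::map(replicate_tables, function(tab) {
    if (!is.null(context)) tab <- filter(tab, .data$context %in% !!context)
    pooled <- tab %>% rename(k = "meth", n = "total")
    call_methylation(pooled, error_rate, min_cov = min_cov, fdr = fdr)
  })
  keys <- purrr::map(calls, function(cc) {
    cc <- filter(cc, .data$status != "uncallable")
    paste(cc$chrom, cc$pos, cc$strand, sep = ":")
  })
  shared <- Reduce(intersect, keys)
  if (length(shared) < 2) stop_mx("fewer than 2 sites covered in every replicate")
  mat <- t(vapply(calls, function(cc) {
    key <- paste(cc$chrom, cc$pos, cc$strand, sep = ":")
    st <- setNames(as.integer(cc$status == "methylated"), key)
    st[shared]
  }, integer(length(shared))))
  rownames(mat) <- names(replicate_tables)
  colnames(mat) <- shared
  mat
}

#' PCA on the binary methylation-state matrix
#'
#' Columns (sites) are mean-centred; components are ordered by variance
#' explained. Sign convention: within each component the loading of largest
#' magnitude is made positive, so coordinates are reproducible.
#'
#' @param state_matrix Samples x sites 0/1 matrix from
#'   [build_state_matrix()].
#' @return Object of class `meth_pca`: list with `scores` (tibble,
#'   `sample_id` + `PC1..PCk`), `var_explained`, `sdev`.
#' @export
methylation_pca <- function(state_matrix) {
  if (nrow(state_matrix) < 3) stop_mx("need at least 3 samples")
  if (ncol(state_matrix) < 2) stop_mx("need at least 2 sites")
  pc <- prcomp(state_matrix, center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  ve <- if (tot > 0) pc$sdev^2 / tot else rep(0, length(pc$sdev))
  # deterministic sign: largest-|loading| positive per component
  for (j in seq_len(ncol(pc$rotation))) {
    i_max <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i_max, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  pc$x[, pc$sdev == 0] <- 0
  scores <- as_tibble(pc$x, rownames = "sample_id")
  structure(list(scores = scores, var_explained = ve, sdev = pc$sdev),
            class = "meth_pca")
}

#' @export
print.meth_pca <- function(x, ...) {
  cat("<meth_pca> ", nrow(x$scores), " samples, ",
      length(x$var_explained), " components\n", sep = "")
  cat("variance explained: ",
      paste(sprintf("%.1f%%", 100 * head(x$var_explained, 4)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @rdname methylation_pca
#' @param x A `meth_pca` object.
#' @param ... Unused.
#' @export
tidy.meth_pca <- function(x, ...) {
  x$scores %>%
    tidyr::pivot_longer(-"sample_id", names_to = "component", values_to = "score")
}

#' @rdname methylation_pca
#' @export
glance.meth_pca <- function(x, ...) {
  tibble(n_samples = nrow(x$scores),
         n_components = length(x$var_explained),
         pve_pc1 = x$var_explained[1],
         pve_pc2 = if (length(x$var_explained) > 1) x$var_explained[2] else NA_real_)
}
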