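#' Build sliding windows for DMR testing
#'
#' 100-bp windows stepped by 50 bp tile each chromosome from position 0;
#' only windows fully contained in the chromosome are kept. All three
#' contexts are pooled. A cytosine contributes its reads to a window only
#' when it is covered at >= `min_cov` in BOTH samples; windows with fewer
#' than `min_cytosines` such cytosines are flagged untested.
#'
#' @param calls_a,calls_b Call tibbles (pooled replicates) from
#'   [call_methylation()] for the two samples.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param window_size Window width in bp (default 100).
#' @param step Step between window starts (default 50).
#' @param min_cov Per-sample coverage needed for a cytosine to count
#'   (default 4).
#' @param min_cytosines Minimum eligible cytosines for testing (default 15).
#' @param context Optional single context; default pools CG+CHG+CHH.
#' @return Tibble with `chrom`, `start`, `end`, per-sample read sums
#'   (`meth_a`, `unmeth_a`, `meth_b`, `unmeth_b`), `n_cytosines`, `tested`.
#' @export
build_windows <- function(calls_a, calls_b, chrom_lengths,
                          window_size = 100L, step = 50L, min_cov = 4L,
                          min_cytosines = 15L, context = NULL) {
  a <- calls_a; b <- calls_b
  if (!is.null(context)) {
    a <- filter(a, .data$context %in% !!context)
    b <- filter(b, .data$context %in% !!context)
  }
  sites <- inner_join(
    a %>% filter(.data$n >= min_cov) %>%
      select("chrom", "pos", "strand", ka = "k", na = "n"),
    b %>% filter(.data$n >= min_cov) %>%
      select("chrom", "pos", "strand", kb = "k", nb = "n"),
    by = c("chrom", "pos", "strand")
  )
  out <- purrr::imap(as.list(chrom_lengths), function(len, ch) {
    if (len < window_size) return(NULL)
    starts <- seq(0L, len - window_size, by = step)
    sch <- sites[sites$chrom == ch, ]
    win <- tibble(chrom = ch, start = as.integer(starts),
                  end = as.integer(starts) + window_size)
    acc <- matrix(0, nrow(win), 5,
                  dimnames = list(NULL, c("ka", "na", "kb", "nb", "ncyt")))
    if (nrow(sch)) {
      # a site at pos p falls in the window starting at step*floor(p/step)
      # and possibly the one before it
      for (shift in c(0L, 1L)) {
        ws <- (sch$pos %/% step - shift) * step
        ok <- ws >= 0 & ws <= len - window_size &
          sch$pos >= ws & sch$pos < ws + window_size
        idx <- ws[ok] %/% step + 1L
        acc[, "ka"] <- acc[, "ka"] + tapply_sum(sch$ka[ok], idx, nrow(win))
        acc[, "na"] <- acc[, "na"] + tapply_sum(sch$na[ok], idx, nrow(win))
        acc[, "kb"] <- acc[, "kb"] + tapply_sum(sch$kb[ok], idx, nrow(win))
        acc[, "nb"] <- acc[, "nb"] + tapply_sum(sch$nb[ok], idx, nrow(win))
        acc[, "ncyt"] <- acc[, "ncyt"] + tapply_sum(rep(1L, sum(ok)), idx, nrow(win))
      }
    }
    win %>% mutate(meth_a = acc[, "ka"], unmeth_a = acc[, "na"] - acc[, "ka"],
                   meth_b = acc[, "kb"], unmeth_b = acc[, "nb"] - acc[, "kb"],
                   n_cytosines = as.integer(acc[, "ncyt"]))
  })
  bind_rows(out) %>%
    mutate(tested = .data$n_cytosines >= min_cytosines &
             (.data$meth_a + .data$unmeth_a) > 0 &
             (.data$meth_b + .data$unmeth_b) > 0)
}

tapply_sum <- function(x, idx, n_out) {
  out <- numeric(n_out)
  if (length(x)) {
    s <- rowsum(as.numeric(x), idx)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

#' Two-sided Fisher exact p-value for a 2x2 read-count table
#'
#' Vectorised over windows: the table is
#' \[meth_a, unmeth_a; meth_b, unmeth_b\]; the p-value sums all
#' hypergeometric tables (given the margins) whose probability does not
#' exceed the observed one, the classic two-sided Fisher rule.
#'
#' @param meth_a,unmeth_a,meth_b,unmeth_b Non-negative integer vectors.
#' @return Numeric vector of p-values.
#' @export
window_fisher <- function(meth_a, unmeth_a, meth_b, unmeth_b) {
  n <- length(meth_a)
  p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    m <- meth_a[i] + meth_b[i]            # total methylated reads
    u <- unmeth_a[i] + unmeth_b[i]        # total unmethylated reads
    da <- meth_a[i] + unmeth_a[i]         # reads drawn for sample A
    if (m + u == 0) next
    lo <- max(0, da - u); hi <- min(da, m)
    xs <- lo:hi
    probs <- dhyper(xs, m, u, da)
    obs <- dhyper(meth_a[i], m, u, da)
    p[i] <- min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
  }
  p
}

#' Run the window Fisher test on built windows
#'
#' @param windows Tibble from [build_windows()].
#' @return The same tibble with a `p_value` column (NA for untested
#'   windows).
#' @export
test_windows <- function(windows) {
  windows$p_value <- NA_real_
  t_idx <- which(windows$tested)
  if (length(t_idx)) {
    windows$p_value[t_idx] <- window_fisher(
      windows$meth_a[t_idx], windows$unmeth_a[t_idx],
      windows$meth_b[t_idx], windows$unmeth_b[t_idx])
  }
  windows
}

#' Concatenate adjacent significant windows into candidate regions
#'
#' Windows with p-value strictly below `alpha` whose intervals touch or
#' overlap (always true for consecutive windows at a 50-bp step) merge into
#' one region spanning the union; an isolated significant window yields a
#' 100-bp region.
#'
#' @param windows Tested window tibble from [test_windows()].
#' @param alpha Significance cut-off (strict `<`; default 0.001).
#' @return Tibble with `chrom`, `start`, `end`, `n_windows`, `min_p`; sorted
#'   and disjoint.
#' @export
merge_windows <- function(windows, alpha = 0.001) {
  sig <- windows %>%
    filter(!is.na(.data$p_value), .data$p_value < alpha) %>%
    arrange(.data$chrom, .data$start)
  if (nrow(sig) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  n_windows = integer(), min_p = double()))
  }
  sig %>%
    group_by(.data$chrom) %>%
    mutate(new_run = .data$start > lag(cummax_int(.data$end), default = -1L)) %>%
    mutate(run = cumsum(.data$new_run)) %>%
    group_by(.data$chrom, .data$run) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              n_windows = n(), min_p = min(.data$p_value), .groups = "drop") %>%
    select("chrom", "start", "end", "n_windows", "min_p") %>%
    arrange(.data$chrom, .data$start)
}

cummax_int <- function(x) as.integer(cummax(x))

#' Classify candidate regions as DMRs by the 30/70 rule
#'
#' Each region's methylation percentage per sample is the weighted level
#' (summed methylated reads over summed reads) of the cytosines covered >=
#' `min_cov` in both samples. A region is a DMR iff one sample is strictly
#' below 30% and the other strictly above 70%.
#'
#' @param regions Tibble from [merge_windows()].
#' @param calls_a,calls_b The two call tibbles used for the windows.
#' @param min_cov Coverage needed in both samples (default 4).
#' @param low_cut,high_cut Classification thresholds (defaults 0.30 / 0.70).
#' @param context Optional context restriction matching [build_windows()].
#' @return Tibble of DMRs: region columns plus `level_a`, `level_b`,
#'   `direction` (`"hyper_a"` / `"hyper_b"`), `name`, `p_value` (the
#'   region's min window p).
#' @export
classify_dmrs <- function(regions, calls_a, calls_b, min_cov = 4L,
                          low_cut = 0.30, high_cut = 0.70, context = NULL) {
  if (nrow(regions) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  n_windows = integer(), min_p = double(), level_a = double(),
                  level_b = double(), direction = character(),
                  name = character(), p_value = double()))
  }
  a <- calls_a; b <- calls_b
  if (!is.null(context)) {
    a <- filter(a, .data$context %in% !!context)
    b <- filter(b, .data$context %in% !!context)
  }
  sites <- inner_join(
    a %>% filter(.data$n >= min_cov) %>%
      select("chrom", "pos", "strand", ka = "k", na = "n"),
    b %>% filter(.data$n >= min_cov) %>%
      select("chrom", "pos", "strand", kb = "k", nb = "n"),
    by = c("chrom", "pos", "strand")
  )
  lv <- purrr::map(seq_len(nrow(regions)), function(i) {
    s <- sites[sites$chrom == regions$chrom[i] &
                 sites$pos >= regions$start[i] & sites$pos < regions$end[i], ]
    if (nrow(s) == 0 || sum(s$na) == 0 || sum(s$nb) == 0) {
      return(c(NA_real_, NA_real_))
    }
    c(sum(s$ka) / sum(s$na), sum(s$kb) / sum(s$nb))
  })
  lv <- do.call(rbind, lv)
  out <- regions %>%
    mutate(level_a = lv[, 1], level_b = lv[, 2]) %>%
    filter(!is.na(.data$level_a),
           pmin(.data$level_a, .data$level_b) < low_cut,
           pmax(.data$level_a, .data$level_b) > high_cut) %>%
    mutate(direction = ifelse(.data$level_a > .data$level_b, "hyper_a", "hyper_b"),
           p_value = .data$min_p)
  out %>% mutate(name = paste0("DMR_", dplyr::row_number()))
}

#' Detect DMRs between two pooled samples
#'
#' One-call wrapper running [build_windows()], [test_windows()],
#' [merge_windows()] and [classify_dmrs()] with the standard parameters.
#' The 30/70 methylation rule is applied twice: once per tested window
#' before concatenation (only windows whose own levels straddle the
#' thresholds are merged, so a significant window that merely overlaps a
#' DMR boundary cannot drag flanking background into the region and dilute
#' its weighted level) and once on the merged region by [classify_dmrs()].
#'
#' @inheritParams build_windows
#' @inheritParams classify_dmrs
#' @param alpha Window significance cut-off for merging.
#' @return Tibble of DMRs (see [classify_dmrs()]).
#' @export
detect_dmrs <- function(calls_a, calls_b, chrom_lengths, window_size = 100L,
                        step = 50L, min_cov = 4L, min_cytosines = 15L,
                        alpha = 0.001, low_cut = 0.30, high_cut = 0.70,
                        context = NULL) {
  win <- build_windows(calls_a, calls_b, chrom_lengths, window_size, step,
                       min_cov, min_cytosines, context)
  win <- test_windows(win)
  la <- win$meth_a / pmax(1, win$meth_a + win$unmeth_a)
  lb <- win$meth_b / pmax(1, win$meth_b + win$unmeth_b)
  straddle <- pmin(la, lb) < low_cut & pmax(la, lb) > high_cut
  win$p_value[!straddle] <- NA_real_
  reg <- merge_windows(win, alpha)
  classify_dmrs(reg, calls_a, calls_b, min_cov, low_cut, high_cut, context)
}

#' Associate DMRs with genes within 1 kb
#'
#' A DMR is associated with every gene whose span, extended by `flank` bp on
#' each side, intersects the DMR. The relation records whether the DMR
#' overlaps the gene body or lies in the 5' or 3' flank (strand-aware).
#'
#' @param dmrs DMR tibble from [classify_dmrs()].
#' @param genes Gene-model tibble.
#' @param flank Extension in bp (default 1000).
#' @return Tibble with one row per (DMR, gene) association: `name`, `chrom`,
#'   `start`, `end`, `gene_id`, `relation`.
#' @export
associate_genes <- function(dmrs, genes, flank = 1000L) {
  if (nrow(dmrs) == 0 || nrow(genes) == 0) {
    return(tibble(name = character(), chrom = character(), start = integer(),
                  end = integer(), gene_id = character(), relation = character()))
  }
  out <- purrr::map(seq_len(nrow(dmrs)), function(i) {
    d <- dmrs[i, ]
    g <- genes[genes$chrom == d$chrom &
                 genes$start - flank < d$end & genes$end + flank > d$start, ]
    if (nrow(g) == 0) return(NULL)
    relation <- dplyr::case_when(
      d$start < g$end & d$end > g$start ~ "overlap",
      d$end <= g$start & g$strand == "+" ~ "5' flank",
      d$end <= g$start & g$strand == "-" ~ "3' flank",
      d$start >= g$end & g$strand == "+" ~ "3' flank",
      TRUE ~ "5' flank"
    )
    tibble(name = d$name, chrom = d$chrom, start = d$start, end = d$end,
           gene_id = g$gene_id, relation = relation)
  })
  bind_rows(out)
}

#' Call per-gene hypermethylation against the genome-wide background
#'
#' For one context, each gene's callable cytosines (coverage >= 4x) within
#' its span give N, its methylated calls give K, and the genome-wide
#' fraction of callable cytosines called methylated gives the background
#' probability P. A one-tailed (upper) binomial test per gene with N >= 20,
#' BH-corrected; significant at q <= `fdr`.
#'
#' @param calls Call tibble from [call_methylation()].
#' @param genes Gene-model tibble.
#' @param context Context to test.
#' @param min_cytosines Minimum callable cytosines per gene (default 20).
#' @param fdr BH FDR threshold (default 0.05).
#' @return Tibble with `gene_id`, `context`, `N`, `K`, `p_bg`, `p_value`,
#'   `q_value`, `significant`.
#' @export
hypermethylated_genes <- function(calls, genes, context, min_cytosines = 20L,
                                  fdr = 0.05) {
  cc <- calls %>%
    filter(.data$status != "uncallable", .data$context %in% !!context)
  if (nrow(cc) == 0) stop_mx("no callable sites in this context")
  p_bg <- mean(cc$status == "methylated")
  if (p_bg <= 0 || p_bg >= 1) {
    stop_mx("degenerate genome-wide background methylation (0 or 1)",
            class = "methexpress_undefined")
  }
  per_gene <- purrr::map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    s <- cc[cc$chrom == g$chrom & cc$pos >= g$start & cc$pos < g$end, ]
    tibble(gene_id = g$gene_id, N = nrow(s),
           K = sum(s$status == "methylated"))
  }) %>% bind_rows() %>%
    filter(.data$N >= min_cytosines)
  if (nrow(per_gene) == 0) {
    return(tibble(gene_id = character(), context = character(), N = integer(),
                  K = integer(), p_bg = double(), p_value = double(),
                  q_value = double(), significant = logical()))
  }
  per_gene %>%
    mutate(context = !!context, p_bg = p_bg,
           p_value = binomial_tail(.data$K, .data$N, p_bg),
           q_value = p.adjust(.data$p_value, method = "BH"),
           significant = .data$q_value <= fdr) %>%
    select("gene_id", "context", "N", "K", "p_bg", "p_value", "q_value",
           "significant") %>%
    arrange(.data$q_value)
}

#' Cluster DMRs on their per-sample methylation levels
#'
#' K-means (fixed seed, multiple restarts) on the matrix of per-sample
#' weighted methylation levels of each DMR; a plain mean silhouette score on
#' Euclidean distances summarises separation.
#'
#' @param dmr_levels Numeric matrix or data frame, DMRs x samples (e.g. the
#'   `level_a`/`level_b` columns of [classify_dmrs()] output).
#' @param k Number of clusters (default 4).
#' @param seed Integer seed.
#' @param nstart Random restarts for k-means.
#' @return List with `labels` (integer vector), `centers`, `silhouette`
#'   (NA when `k` is 1), `degenerate` (TRUE when the feature rows are all
#'   identical).
#' @export
cluster_dmrs <- function(dmr_levels, k = 4L, seed = 1L, nstart = 25L) {
  x <- as.matrix(dmr_levels)
  if (k > nrow(x)) stop_mx("k exceeds the number of DMRs")
  degenerate <- nrow(unique(round(x, 12))) == 1
  if (degenerate && k > 1) {
    warn("all DMR feature vectors identical; clustering is degenerate")
    return(list(labels = rep(1L, nrow(x)), centers = x[1, , drop = FALSE],
                silhouette = NA_real_, degenerate = TRUE))
  }
  set.seed(seed)
  km <- kmeans(x, centers = k, nstart = nstart)
  sil <- if (k == 1) NA_real_ else mean_silhouette(x, km$cluster)
  list(labels = km$cluster, centers = km$centers, silhouette = sil,
       degenerate = degenerate)
}

# plain mean silhouette on Euclidean distances
mean_silhouette <- function(x, labels) {
  dm <- as.matrix(dist(x))
  n <- nrow(x)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    own[i] <- FALSE
    a <- if (any(own)) mean(dm[i, own]) else 0
    bs <- vapply(setdiff(unique(labels), labels[i]),
                 function(l) mean(dm[i, labels == l]), numeric(1))
    if (!length(bs)) return(0)
    b <- min(bs)
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
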