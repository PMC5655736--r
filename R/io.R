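#' Read a genome FASTA file
#'
#' Loads a (small) genome into memory as a named character vector of
#' uppercased DNA sequences. `N` bases are allowed and are skipped during
#' cytosine-context annotation.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences (class
#'   `genome_sequence`); names are chromosome identifiers.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_mx(paste0("file not found: ", path))
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop_mx(paste0("malformed FASTA: ", conditionMessage(e)),
                                class = "methexpress_format_error")
  )
  if (length(seqs) == 0) {
    stop_mx("empty FASTA file", class = "methexpress_format_error")
  }
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(out))) {
    stop_mx("duplicate chromosome names in FASTA",
            class = "methexpress_format_error")
  }
  if (any(nchar(out) == 0)) {
    stop_mx("zero-length sequence in FASTA", class = "methexpress_format_error")
  }
  structure(out, class = "genome_sequence")
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(as.character(genome), names(genome))),
    path, width = width
  )
  invisible(path)
}

#' Read a per-cytosine methylation count table
#'
#' Reads the tab-separated count dialect used throughout the package: one row
#' per cytosine with columns `chrom`, `pos` (1-based), `strand` (+/-),
#' `context` (CG/CHG/CHH), `meth` (methylated reads) and `total` (coverage).
#' A leading `#` header line is optional. Positions are converted to the
#' package's internal 0-based representation.
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `chrom`, `pos` (0-based), `strand`, `context`,
#'   `meth`, `total`.
#' @export
read_methcounts <- function(path) {
  if (!file.exists(path)) stop_mx(paste0("file not found: ", path))
  tab <- readr::read_tsv(
    path, comment = "#", col_names = c("chrom", "pos", "strand", "context", "meth", "total"),
    col_types = readr::cols(
      chrom = readr::col_character(), pos = readr::col_double(),
      strand = readr::col_character(), context = readr::col_character(),
      meth = readr::col_double(), total = readr::col_double()
    ),
    progress = FALSE
  )
  validate_methcounts(tab, one_based = TRUE)
  tab %>%
    mutate(pos = pos_from_disk(.data$pos),
           meth = as.integer(.data$meth), total = as.integer(.data$total))
}

validate_methcounts <- function(tab, one_based = FALSE) {
  if (nrow(tab) == 0) return(invisible(tab))
  if (any(is.na(tab))) stop_mx("NA values in methcounts table")
  if (!all(tab$strand %in% c("+", "-"))) stop_mx("strand must be '+' or '-'")
  if (!all(tab$context %in% METH_CONTEXTS)) {
    stop_mx(paste0("unknown context token(s): ",
                   paste(setdiff(unique(tab$context), METH_CONTEXTS), collapse = ", ")))
  }
  if (any(tab$meth < 0) || any(tab$total < 1)) {
    stop_mx("meth must be >= 0 and total >= 1")
  }
  if (any(tab$meth > tab$total)) stop_mx("meth exceeds total coverage")
  min_pos <- if (one_based) 1 else 0
  if (any(tab$pos < min_pos)) stop_mx("position out of range")
  key <- paste(tab$chrom, tab$pos, tab$strand)
  if (anyDuplicated(key)) stop_mx("duplicate (chrom, pos, strand) rows")
  invisible(tab)
}

#' Write a methylation count table
#'
#' Inverse of [read_methcounts()]: positions are written 1-based, rows sorted
#' by chromosome and position.
#'
#' @param sites Tibble with `chrom`, `pos` (0-based), `strand`, `context`,
#'   `meth`, `total`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_methcounts <- function(sites, path) {
  out <- sites %>%
    arrange(.data$chrom, .data$pos, .data$strand) %>%
    mutate(pos = pos_to_disk(.data$pos)) %>%
    select("chrom", "pos", "strand", "context", "meth", "total")
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read gene models from BED12 or GFF3
#'
#' Coordinates are stored 0-based half-open. Exon blocks are sorted in genomic
#' order and merged, with a warning, if they overlap in the input.
#'
#' @param path Path to a BED12 or GFF3 file; format chosen by extension
#'   (`.bed` vs `.gff`/`.gff3`) unless `format` is given.
#' @param format One of `"auto"`, `"bed"`, `"gff3"`.
#' @return Tibble with columns `gene_id`, `chrom`, `strand`, `start`, `end`
#'   (0-based half-open) and a list-column `exons` of two-column integer
#'   matrices (`start`, `end`, 0-based half-open, sorted).
#' @export
read_gene_models <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_mx(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  if (format == "bed") read_gene_models_bed12(path) else read_gene_models_gff3(path)
}

read_gene_models_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  blocks <- gr$blocks
  if (is.null(blocks)) stop_mx("BED file lacks block (exon) columns; BED12 required")
  n <- length(gr)
  genes <- tibble(
    gene_id = if (!is.null(gr$name)) gr$name else paste0("gene_", seq_len(n)),
    chrom = as.character(GenomeInfoDb_seqnames(gr)),
    strand = as.character(S4Vectors::decode(BiocGenerics::strand(gr))),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    exons = purrr::map(seq_len(n), function(i) {
      b <- blocks[[i]]
      # blocks come back 1-based relative to the feature start
      off <- BiocGenerics::start(gr)[i] - 1L
      cbind(start = off + BiocGenerics::start(b) - 1L,
            end = off + BiocGenerics::end(b))
    })
  )
  finalize_gene_models(genes)
}

# thin indirection so the seqnames accessor is testable without attaching
GenomeInfoDb_seqnames <- function(gr) S4Vectors::decode(GenomicRanges::seqnames(gr))

read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  genes_gr <- gr[type == "gene"]
  exons_gr <- gr[type == "exon"]
  if (length(genes_gr) == 0) stop_mx("no gene features in GFF3")
  gene_ids <- genes_gr$ID
  if (is.null(gene_ids) || any(is.na(gene_ids))) {
    stop_mx("gene features must carry an ID attribute")
  }
  parent <- as.character(S4Vectors::unstrsplit(exons_gr$Parent %||% character(0), ","))
  genes <- tibble(
    gene_id = gene_ids,
    chrom = as.character(GenomeInfoDb_seqnames(genes_gr)),
    strand = as.character(S4Vectors::decode(BiocGenerics::strand(genes_gr))),
    start = BiocGenerics::start(genes_gr) - 1L,
    end = BiocGenerics::end(genes_gr)
  )
  ex_tab <- tibble(
    parent = parent,
    start = BiocGenerics::start(exons_gr) - 1L,
    end = BiocGenerics::end(exons_gr)
  )
  genes$exons <- purrr::map(genes$gene_id, function(id) {
    ex <- ex_tab[ex_tab$parent == id, , drop = FALSE]
    if (nrow(ex) == 0) return(NULL)
    cbind(start = as.integer(ex$start), end = as.integer(ex$end))
  })
  # genes without exon children span their whole coordinate range
  genes$exons <- purrr::pmap(genes[c("exons", "start", "end")], function(exons, start, end) {
    if (is.null(exons)) cbind(start = start, end = end) else exons
  })
  finalize_gene_models(genes)
}

finalize_gene_models <- function(genes) {
  genes$exons <- purrr::pmap(genes[c("gene_id", "start", "end", "exons")],
    function(gene_id, start, end, exons) {
      ex <- exons[order(exons[, "start"]), , drop = FALSE]
      if (any(ex[, "start"] < start) || any(ex[, "end"] > end)) {
        stop_mx(paste0("exon outside gene span for ", gene_id))
      }
      if (any(ex[, "end"] <= ex[, "start"])) {
        stop_mx(paste0("empty exon interval for ", gene_id))
      }
      if (nrow(ex) > 1 && any(ex[-1, "start"] < ex[-nrow(ex), "end"])) {
        warn(paste0("overlapping exons merged for ", gene_id))
        ex <- merge_intervals(ex)
      }
      ex
    })
  if (any(purrr::map_int(genes$exons, ~ sum(.x[, "end"] - .x[, "start"])) < 1)) {
    stop_mx("gene with zero exonic length")
  }
  genes
}

# merge overlapping/touching sorted intervals (matrix with start/end cols)
merge_intervals <- function(x) {
  x <- x[order(x[, "start"]), , drop = FALSE]
  keep_s <- x[1, "start"]; keep_e <- x[1, "end"]
  out <- NULL
  for (i in seq_len(nrow(x))[-1]) {
    if (x[i, "start"] <= keep_e) {
      keep_e <- max(keep_e, x[i, "end"])
    } else {
      out <- rbind(out, c(keep_s, keep_e))
      keep_s <- x[i, "start"]; keep_e <- x[i, "end"]
    }
  }
  out <- rbind(out, c(keep_s, keep_e))
  colnames(out) <- c("start", "end")
  out
}

#' Write genomic regions as BED
#'
#' Regions are written 0-based half-open and sorted by (chrom, start). The
#' score column carries `-log10(p)` capped at 1000 when a `p_value` column is
#' present, 0 otherwise.
#'
#' @param regions Tibble with `chrom`, `start`, `end` and optional `name`,
#'   `p_value` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  writeLines("#chrom\tstart\tend\tname\tscore", path)
  if (nrow(regions) == 0) return(invisible(path))
  score <- if ("p_value" %in% names(regions)) {
    s <- round(-log10(regions$p_value), 3)
    s[!is.finite(s)] <- 1000
    pmin(1000, s)
  } else rep(0, nrow(regions))
  nm <- if ("name" %in% names(regions)) regions$name else paste0("region_", seq_len(nrow(regions)))
  out <- tibble(chrom = regions$chrom, start = regions$start, end = regions$end,
                name = nm, score = score) %>%
    arrange(.data$chrom, .data$start)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE, append = TRUE)
  invisible(path)
}

#' Read a BED file written by [write_bed()]
#'
#' @param path Path to a BED file (0-based half-open).
#' @return Tibble with `chrom`, `start`, `end`, `name`, `score`.
#' @export
read_bed <- function(path) {
  readr::read_tsv(path, comment = "#",
                  col_names = c("chrom", "start", "end", "name", "score"),
                  col_types = "ciicd", progress = FALSE)
}

#' Read a gene-level counts matrix with its sample sheet
#'
#' The counts TSV has a `gene_id` first column, one integer column per sample
#' and an optional `length` column (gene length in bp, needed for RPKM). The
#' sample sheet TSV has columns `sample_id`, `tissue`, `replicate`.
#'
#' @param counts_path Path to the counts TSV.
#' @param samples_path Path to the sample sheet TSV.
#' @return An [expression_matrix()] object.
#' @export
read_counts_matrix <- function(counts_path, samples_path) {
  tab <- readr::read_tsv(counts_path, col_types = readr::cols(), progress = FALSE)
  if (!"gene_id" %in% names(tab)) stop_mx("counts TSV must have a gene_id column")
  samples <- readr::read_tsv(samples_path, col_types = readr::cols(), progress = FALSE)
  req <- c("sample_id", "tissue", "replicate")
  if (!all(req %in% names(samples))) {
    stop_mx("sample sheet must have sample_id, tissue, replicate columns")
  }
  lengths <- NULL
  if ("length" %in% names(tab)) {
    lengths <- setNames(tab$length, tab$gene_id)
    tab$length <- NULL
  }
  cts <- as.matrix(tab[, setdiff(names(tab), "gene_id"), drop = FALSE])
  rownames(cts) <- tab$gene_id
  missing <- setdiff(samples$sample_id, colnames(cts))
  if (length(missing)) stop_mx(paste0("samples absent from counts: ", paste(missing, collapse = ",")))
  cts <- cts[, samples$sample_id, drop = FALSE]
  expression_matrix(cts, lengths = lengths, samples = samples)
}

#' Construct an expression matrix object
#'
#' Bundles gene x sample raw counts with gene lengths and sample metadata;
#' library sizes are the column sums. This is the container consumed by the
#' expression-analysis functions (CPM/RPKM, filtering, differential
#' expression, coexpression).
#'
#' @param counts Integer matrix, genes x samples, with dimnames.
#' @param lengths Named numeric vector of gene lengths in bp, or `NULL`.
#' @param samples Tibble with `sample_id`, `tissue`, `replicate` matching the
#'   matrix columns.
#' @return Object of class `expr_matrix`.
#' @export
expression_matrix <- function(counts, lengths = NULL, samples) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_mx("counts must have gene and sample dimnames")
  }
  if (any(is.na(counts))) stop_mx("NA counts are not allowed")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_mx("counts must be non-negative integers")
  }
  samples <- as_tibble(samples)
  if (!identical(samples$sample_id, colnames(counts))) {
    stop_mx("sample sheet order must match counts columns")
  }
  if (!is.null(lengths)) {
    lengths <- lengths[rownames(counts)]
    if (any(is.na(lengths)) || any(lengths <= 0)) {
      stop_mx("every gene needs a positive length")
    }
  }
  structure(
    list(counts = counts, lengths = lengths, samples = samples,
         lib_sizes = colSums(counts)),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", nrow(x$counts), " genes x ", ncol(x$counts), " samples\n", sep = "")
  cat("tissues: ", paste(unique(x$samples$tissue), collapse = ", "), "\n", sep = "")
  cat("library sizes: ", paste(format(x$lib_sizes, big.mark = ","), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write an expression matrix and its sample sheet
#'
#' @param expr An `expr_matrix`.
#' @param counts_path,samples_path Output paths.
#' @return `counts_path`, invisibly.
#' @export
write_counts_matrix <- function(expr, counts_path, samples_path) {
  tab <- as_tibble(expr$counts, rownames = "gene_id")
  if (!is.null(expr$lengths)) tab$length <- unname(expr$lengths[tab$gene_id])
  readr::write_tsv(tab, counts_path, progress = FALSE)
  readr::write_tsv(expr$samples, samples_path, progress = FALSE)
  invisible(counts_path)
}
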