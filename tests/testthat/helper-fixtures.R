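# Small shared fixtures built in code.

make_sites <- function(chrom, pos, strand = "+", context = "CG", meth, total) {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), strand = strand,
                 context = context, meth = as.integer(meth),
                 total = as.integer(total))
}

# one-row gene-model tibble
make_gene <- function(gene_id = "g1", chrom = "chr1", strand = "+",
                      start, end, exons = NULL) {
  tibble::tibble(
    gene_id = gene_id, chrom = chrom, strand = strand,
    start = as.integer(start), end = as.integer(end),
    exons = list(exons %||% cbind(start = as.integer(start), end = as.integer(end)))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a small pooled-call tibble with every site confidently called
make_calls <- function(chrom, pos, k, n, context = "CG", strand = "+",
                       error_rate = 0.002) {
  pooled <- tibble::tibble(chrom = chrom, pos = as.integer(pos),
                           strand = strand, context = context,
                           k = as.integer(k), n = as.integer(n))
  call_methylation(pooled, error_rate)
}
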