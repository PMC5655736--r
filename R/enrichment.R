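#' Read a gene-to-term association table
#'
#' Minimal GAF-style dialect: tab-separated `gene_id`, `term_id` and an
#' optional third column (aspect or term name). Lines starting with `!` or
#' `#` are comments.
#'
#' @param path Path to the TSV.
#' @return Tibble with `gene_id`, `term_id` (and `aspect` when present).
#' @export
read_associations <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!grepl("^[!#]", lines) & nzchar(lines)]
  if (!length(lines)) stop_mx("empty association file")
  parts <- stringr::str_split(lines, "\t")
  ncol <- min(lengths(parts))
  if (ncol < 2) stop_mx("association file needs gene_id and term_id columns")
  out <- tibble(gene_id = purrr::map_chr(parts, 1),
                term_id = purrr::map_chr(parts, 2))
  if (ncol >= 3) out$aspect <- purrr::map_chr(parts, 3)
  distinct(out)
}

#' GO-term over-representation with Bonferroni correction
#'
#' Per term with at least one study hit, the upper-tail hypergeometric
#' probability (one-sided Fisher) of drawing at least the observed number of
#' annotated study genes; Bonferroni correction over the tested terms. The
#' population universe is the set of genes carrying at least one annotation,
#' intersected with `population_genes` when given.
#'
#' @param study_genes Character vector of study gene ids (must be a subset of
#'   the population).
#' @param annotations Association tibble from [read_associations()].
#' @param population_genes Optional explicit population; default all
#'   annotated genes.
#' @param alpha Bonferroni significance threshold (strict `<`; default 0.05).
#' @return Tibble with `term_id`, `study_hits`, `study_size`,
#'   `population_hits`, `population_size`, `p_value`, `p_bonferroni`,
#'   `enriched`, ordered by p-value.
#' @export
go_enrichment <- function(study_genes, annotations, population_genes = NULL,
                          alpha = 0.05) {
  pop <- population_genes %||% unique(annotations$gene_id)
  ann <- filter(annotations, .data$gene_id %in% pop)
  study <- unique(study_genes)
  if (!length(study)) stop_mx("empty study set")
  if (!all(study %in% pop)) {
    stop_mx("study genes must be a subset of the population universe")
  }
  n_pop <- length(pop)
  n_study <- length(study)
  by_term <- ann %>%
    group_by(.data$term_id) %>%
    summarise(population_hits = dplyr::n_distinct(.data$gene_id),
              study_hits = dplyr::n_distinct(intersect(.data$gene_id, study)),
              .groups = "drop") %>%
    filter(.data$study_hits >= 1)
  m <- nrow(by_term)
  by_term %>%
    mutate(study_size = n_study, population_size = n_pop,
           p_value = phyper(.data$study_hits - 1, .data$population_hits,
                            n_pop - .data$population_hits, n_study,
                            lower.tail = FALSE),
           p_bonferroni = pmin(1, .data$p_value * m),
           enriched = .data$p_bonferroni < alpha) %>%
    select("term_id", "study_hits", "study_size", "population_hits",
           "population_size", "p_value", "p_bonferroni", "enriched") %>%
    arrange(.data$p_value)
}

#' Transcription-factor family enrichment in a focal gene set
#'
#' Per family, a one-sided Fisher exact test asking whether the fraction of
#' family members in the focal set (e.g. vascular-expressed genes) exceeds
#' the genome-wide fraction of focal genes.
#'
#' @param family_map Tibble with `gene_id`, `family`.
#' @param focal_genes Character vector of focal gene ids.
#' @param genome_size Total genes in the genome.
#' @param focal_set_size Total focal genes in the genome; default
#'   `length(unique(focal_genes))`.
#' @return Tibble with `family`, `family_size`, `family_focal`, `p_value`,
#'   ordered by p-value.
#' @export
tf_family_enrichment <- function(family_map, focal_genes, genome_size,
                                 focal_set_size = NULL) {
  focal_set_size <- focal_set_size %||% length(unique(focal_genes))
  if (focal_set_size > genome_size) stop_mx("focal set larger than genome")
  fam <- family_map %>%
    group_by(.data$family) %>%
    summarise(family_size = dplyr::n_distinct(.data$gene_id),
              family_focal = dplyr::n_distinct(intersect(.data$gene_id, focal_genes)),
              .groups = "drop")
  if (any(fam$family_size == 0)) stop_mx("empty transcription-factor family")
  if (any(fam$family_size > genome_size)) stop_mx("family larger than genome")
  fam %>%
    mutate(p_value = phyper(.data$family_focal - 1, focal_set_size,
                            genome_size - focal_set_size, .data$family_size,
                            lower.tail = FALSE)) %>%
    arrange(.data$p_value)
}
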