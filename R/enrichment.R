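#' Hypergeometric term over-representation test
#'
#' For each term with at least one hit in the gene set, computes the
#' upper-tail hypergeometric probability `P(X >= k)` of drawing `k` term
#' members in a sample of `n` genes from a background of `N` genes of which
#' `K` carry the term, and applies a Bonferroni correction over the tested
#' terms (terms with zero hits are not tested and do not enter the
#' Bonferroni denominator).
#'
#' @param gene_set character vector of genes of interest.
#' @param term_map tibble `gene, term` mapping background genes to terms.
#' @param background character vector of background genes; defaults to all
#'   genes in the term map. `gene_set` must be a subset of it.
#' @param alpha significance threshold used for the `significant` flag.
#' @return tibble `term, k, n, K, N, p, p_bonf, significant`, sorted by `p`.
#' @export
hypergeom_enrich <- function(gene_set, term_map, background = NULL,
                             alpha = 0.05) {
  assert_columns(term_map, c("gene", "term"), "term_map")
  gene_set <- unique(gene_set)
  background <- unique(background %||% term_map$gene)
  outside <- setdiff(gene_set, background)
  if (length(outside) > 0) {
    validation_error("gene set member(s) absent from background: %s",
                     paste(sort(outside), collapse = ", "))
  }
  tm <- term_map %>%
    filter(.data$gene %in% background) %>%
    distinct(.data$gene, .data$term)
  N <- length(background)
  n <- length(gene_set)
  stats_tbl <- tm %>%
    group_by(.data$term) %>%
    summarise(K = n(), k = sum(.data$gene %in% gene_set), .groups = "drop") %>%
    filter(.data$k >= 1)
  if (nrow(stats_tbl) == 0) {
    return(tibble(term = character(), k = integer(), n = integer(),
                  K = integer(), N = integer(), p = numeric(),
                  p_bonf = numeric(), significant = logical()))
  }
  m <- nrow(stats_tbl)
  stats_tbl %>%
    mutate(
      n = n, N = N,
      p = phyper(.data$k - 1, .data$K, N - .data$K, n, lower.tail = FALSE),
      p_bonf = pmin(1, .data$p * m),
      significant = .data$p_bonf < alpha
    ) %>%
    select("term", "k", "n", "K", "N", "p", "p_bonf", "significant") %>%
    arrange(.data$p, .data$term)
}
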