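#' Build gene-DMR-miRNA triads
#'
#' One triad per (gene, miRNA) pair where the gene is differentially
#' expressed (direction up/down), carries at least one DMR link with a
#' single methylation direction (genes with mixed hyper/hypo links are
#' excluded and logged), and is a predicted target of a differentially
#' expressed miRNA. A gene targeted by several DERs yields several triads.
#'
#' @param degs DE-gene tibble with `feature_id, direction`.
#' @param dmr_links DMR-gene links from [link_dmrs_to_genes()].
#' @param der_targets tibble `mirna_id, gene_id, mirna_dir` pairing each
#'   differentially expressed miRNA with its predicted target genes and its
#'   expression direction (up/down).
#' @return tibble `gene_id, gene_dir, dmr_dir, dmr_location, mirna_id,
#'   mirna_dir, label` (see [classify_negative()]).
#' @export
build_triads <- function(degs, dmr_links, der_targets) {
  assert_columns(der_targets, c("mirna_id", "gene_id", "mirna_dir"),
                 "der_targets")
  deg_dir <- degs %>%
    filter(.data$direction %in% c("up", "down")) %>%
    select(gene_id = "feature_id", gene_dir = "direction")
  gd <- gene_dmr_directions(dmr_links)
  n_mixed <- sum(gd$dmr_dir == "mixed")
  if (n_mixed > 0) {
    inform(sprintf("excluding %d gene(s) with mixed DMR direction", n_mixed))
  }
  gd <- gd %>% filter(.data$dmr_dir != "mixed")
  triads <- deg_dir %>%
    inner_join(gd, by = "gene_id") %>%
    inner_join(
      der_targets %>% filter(.data$mirna_dir %in% c("up", "down")),
      by = "gene_id", relationship = "many-to-many"
    )
  inform(sprintf(
    "triads: %d DEGs, %d DMR-linked genes, %d DER-target pairs -> %d triads",
    nrow(deg_dir), nrow(gd), nrow(der_targets), nrow(triads)
  ))
  if (nrow(triads) == 0) {
    return(tibble(gene_id = character(), gene_dir = character(),
                  dmr_dir = character(), dmr_location = character(),
                  mirna_id = character(), mirna_dir = character(),
                  label = character()))
  }
  triads %>%
    mutate(label = classify_negative(.data$gene_dir, .data$dmr_dir,
                                     .data$mirna_dir)) %>%
    select("gene_id", "gene_dir", "dmr_dir", dmr_location = "dmr_locations",
           "mirna_id", "mirna_dir", "label") %>%
    arrange(.data$gene_id, .data$mirna_id)
}

#' Classify the correlation pattern of a triad
#'
#' A triad is `fully_negative` when gene expression opposes both regulators:
#' (gene up, DMR hypo, miRNA down) or (gene down, DMR hyper, miRNA up).
#' `meth_negative_only` / `mirna_negative_only` mark triads where only the
#' methylation / only the miRNA direction anti-correlates with the gene;
#' everything else is `non_negative`. The labels partition the 2x2x2
#' direction space.
#'
#' @param gene_dir,dmr_dir,mirna_dir character vectors over
#'   `{up, down}`, `{hyper, hypo}`, `{up, down}` respectively.
#' @return character vector of labels.
#' @export
classify_negative <- function(gene_dir, dmr_dir, mirna_dir) {
  if (any(!gene_dir %in% c("up", "down")) ||
      any(!dmr_dir %in% c("hyper", "hypo")) ||
      any(!mirna_dir %in% c("up", "down"))) {
    validation_error(
      "classify_negative: directions must be up/down (gene, miRNA) and hyper/hypo (DMR); filter ns/mixed records first"
    )
  }
  meth_neg <- (gene_dir == "up" & dmr_dir == "hypo") |
    (gene_dir == "down" & dmr_dir == "hyper")
  mirna_neg <- (gene_dir == "up" & mirna_dir == "down") |
    (gene_dir == "down" & mirna_dir == "up")
  case_when(
    meth_neg & mirna_neg ~ "fully_negative",
    meth_neg ~ "meth_negative_only",
    mirna_neg ~ "mirna_negative_only",
    TRUE ~ "non_negative"
  )
}

#' Key-gene report table
#'
#' Deduplicates triads to one row per (gene, miRNA) pair (DMR locations
#' concatenated), flags `fully_negative` rows as key genes, and sorts
#' deterministically by (label, gene, miRNA).
#'
#' @param triads tibble from [build_triads()].
#' @return tibble `gene_id, gene_dir, dmr_dir, dmr_location, mirna_id,
#'   mirna_dir, label, key_gene`.
#' @export
key_gene_table <- function(triads) {
  if (nrow(triads) == 0) {
    return(tibble(gene_id = character(), gene_dir = character(),
                  dmr_dir = character(), dmr_location = character(),
                  mirna_id = character(), mirna_dir = character(),
                  label = character(), key_gene = logical()))
  }
  triads %>%
    group_by(.data$gene_id, .data$mirna_id) %>%
    summarise(
      across(c("gene_dir", "dmr_dir", "mirna_dir", "label"), first),
      dmr_location = paste(sort(unique(unlist(
        strsplit(.data$dmr_location, ";", fixed = TRUE)
      ))), collapse = ";"),
      .groups = "drop"
    ) %>%
    mutate(key_gene = .data$label == "fully_negative") %>%
    select("gene_id", "gene_dir", "dmr_dir", "dmr_location", "mirna_id",
           "mirna_dir", "label", "key_gene") %>%
    arrange(.data$label, .data$gene_id, .data$mirna_id)
}
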