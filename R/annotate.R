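#' Link DMRs to genes and their sub-features
#'
#' A DMR links to a gene when it overlaps the gene body or its `flank` on
#' either side. Each link is assigned the single sub-feature class (promoter
#' thirds, first/internal/last exon or intron, downstream) with the maximal
#' base overlap; ties are broken by the fixed order promoter > exon >
#' intron > downstream (and distal > intermediate > proximal, first >
#' internal > last within a class group).
#'
#' @param dmrs DMR tibble (needs `chrom, start, end, direction`; a `context`
#'   column is carried through if present).
#' @param genes gene-model tibble from [read_gff3_genes()].
#' @param flank association flank in bp.
#' @return tibble `gene_id, chrom, start, end, context, direction,
#'   feature_class, overlap_bp` with one row per (DMR, gene) link.
#' @export
link_dmrs_to_genes <- function(dmrs, genes, flank = 2000L) {
  empty <- tibble(
    gene_id = character(), chrom = character(), start = integer(),
    end = integer(), context = character(), direction = character(),
    feature_class = character(), overlap_bp = integer()
  )
  if (nrow(dmrs) == 0 || nrow(genes) == 0) return(empty)
  feats <- gene_subfeatures(genes, flank)
  d <- dmrs %>%
    mutate(
      dmr_id = row_number(),
      context = if ("context" %in% names(dmrs)) .data$context else NA_character_
    )
  hits <- overlap_join(
    d %>% select("dmr_id", "chrom", "start", "end", "context", "direction"),
    feats
  )
  if (nrow(hits) == 0) return(empty)
  hits %>%
    mutate(
      overlap_bp = pmin(.data$end, .data$end_y) - pmax(.data$start, .data$start_y),
      class_rank = match(.data$feature_class, .feature_classes)
    ) %>%
    # a class can be split over several intervals (e.g. internal exons)
    group_by(.data$dmr_id, .data$gene_id, .data$feature_class) %>%
    summarise(
      across(c("chrom", "start", "end", "context", "direction", "class_rank"),
             first),
      overlap_bp = sum(.data$overlap_bp), .groups = "drop"
    ) %>%
    group_by(.data$dmr_id, .data$gene_id) %>%
    arrange(dplyr::desc(.data$overlap_bp), .data$class_rank,
            .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    ungroup() %>%
    select("gene_id", "chrom", "start", "end", "context", "direction",
           "feature_class", "overlap_bp") %>%
    arrange(.data$gene_id, .data$chrom, .data$start)
}

#' Gene-level DMR directions
#'
#' Collapses DMR-gene links to one row per gene with its methylation
#' direction; genes linked to both hyper- and hypo-DMRs get direction
#' `"mixed"` (such genes are excluded from the negative-correlation
#' classifier downstream).
#'
#' @param links output of [link_dmrs_to_genes()].
#' @return tibble `gene_id, dmr_dir, dmr_locations, n_links`.
#' @export
gene_dmr_directions <- function(links) {
  if (nrow(links) == 0) {
    return(tibble(gene_id = character(), dmr_dir = character(),
                  dmr_locations = character(), n_links = integer()))
  }
  links %>%
    group_by(.data$gene_id) %>%
    summarise(
      dmr_dir = if (dplyr::n_distinct(.data$direction) > 1) "mixed"
        else first(.data$direction),
      dmr_locations = paste(sort(unique(.data$feature_class)), collapse = ";"),
      n_links = n(), .groups = "drop"
    )
}

#' Associate miRNA loci with methylated cytosines
#'
#' Per precursor locus, counts the overlapping methylated cytosines by
#' context; a locus is "associated" when it contains at least `min_mc`
#' methylated cytosines.
#'
#' @param mirna_loci tibble `mirna_id, chrom, start, end` (BED convention).
#' @param calls cytosine-call tibble (one sample, or both conditions pooled).
#' @param rule,error_rate,alpha methylated-site rule, see [methylated_sites()].
#' @param min_mc association threshold (methylated cytosines per locus).
#' @return tibble `mirna_id, n_mc_CG, n_mc_CHG, n_mc_CHH, n_mc_total,
#'   associated`, with attributes `fraction_associated` and `composition`
#'   (per-context share of all in-locus methylated cytosines).
#' @export
mirna_mc_association <- function(mirna_loci, calls,
                                 rule = c("any", "binomial"),
                                 error_rate = 0.005, alpha = 0.05,
                                 min_mc = 1L) {
  rule <- match.arg(rule)
  mc <- calls[methylated_sites(calls, rule, error_rate, alpha), ]
  hits <- overlap_join(
    mc %>% mutate(start = .data$pos, end = .data$pos + 1L),
    mirna_loci %>% select("mirna_id", "chrom", "start", "end")
  )
  counts <- hits %>%
    count(.data$mirna_id, context = factor(.data$context, levels = .contexts),
          .drop = FALSE) %>%
    tidyr::pivot_wider(names_from = "context", values_from = "n",
                       names_prefix = "n_mc_", values_fill = 0L)
  out <- mirna_loci %>%
    select("mirna_id") %>%
    left_join(counts, by = "mirna_id") %>%
    mutate(across(dplyr::starts_with("n_mc_"), ~ tidyr::replace_na(.x, 0L)))
  for (ctx in .contexts) {
    col <- paste0("n_mc_", ctx)
    if (!col %in% names(out)) out[[col]] <- 0L
  }
  out <- out %>%
    mutate(
      n_mc_total = .data$n_mc_CG + .data$n_mc_CHG + .data$n_mc_CHH,
      associated = .data$n_mc_total >= min_mc
    ) %>%
    select("mirna_id", "n_mc_CG", "n_mc_CHG", "n_mc_CHH", "n_mc_total",
           "associated")
  total_mc <- sum(out$n_mc_total)
  comp <- if (total_mc > 0) {
    c(CG = sum(out$n_mc_CG), CHG = sum(out$n_mc_CHG),
      CHH = sum(out$n_mc_CHH)) / total_mc
  } else c(CG = 0, CHG = 0, CHH = 0)
  attr(out, "fraction_associated") <- mean(out$associated)
  attr(out, "composition") <- comp
  out
}

#' Cross-tabulate DMR direction against gene expression direction
#'
#' Joins gene-level DMR directions with a differential-expression table and
#' counts genes per (hyper | hypo | mixed) x (up | down | ns) cell, with the
#' per-cell median log2FC. Genes without a DE record count as `ns`.
#'
#' @param links output of [link_dmrs_to_genes()].
#' @param degs DE tibble with `feature_id, log2fc, direction`.
#' @return tibble `dmr_dir, gene_dir, n_genes, median_log2fc`.
#' @export
dmr_expression_summary <- function(links, degs) {
  gd <- gene_dmr_directions(links)
  joined <- gd %>%
    left_join(degs %>% select(gene_id = "feature_id", "log2fc", "direction"),
              by = "gene_id") %>%
    mutate(gene_dir = tidyr::replace_na(.data$direction, "ns"))
  joined %>%
    group_by(dmr_dir = factor(.data$dmr_dir,
                              levels = c("hyper", "hypo", "mixed")),
             gene_dir = factor(.data$gene_dir, levels = c("up", "down", "ns"))) %>%
    summarise(n_genes = n(),
              median_log2fc = stats::median(.data$log2fc, na.rm = TRUE),
              .groups = "drop") %>%
    tidyr::complete(dmr_dir, gene_dir,
                    fill = list(n_genes = 0L, median_log2fc = NA_real_)) %>%
    mutate(dmr_dir = as.character(.data$dmr_dir),
           gene_dir = as.character(.data$gene_dir))
}
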