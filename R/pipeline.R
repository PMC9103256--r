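#' Read every pipeline input from a study directory
#'
#' Expects the file layout written by [write_study()] (external datasets can
#' follow the same layout; `truth.json` is optional).
#'
#' @param dir directory with `methylation_treatment.tsv`,
#'   `methylation_control.tsv`, `genes.gff3`, `mirna_loci.bed`,
#'   `mrna_counts.tsv`, `mirna_counts.tsv`, `target_pairs.tsv`,
#'   `term_map.tsv`.
#' @return list of inputs as used by [run_pipeline()].
#' @export
read_study <- function(dir) {
  p <- function(f) file.path(dir, f)
  list(
    meth = list(
      treatment = read_cytosine_report(p("methylation_treatment.tsv"),
                                       "treatment"),
      control = read_cytosine_report(p("methylation_control.tsv"), "control")
    ),
    genes = read_gff3_genes(p("genes.gff3")),
    mirna_loci = read_mirna_bed(p("mirna_loci.bed")),
    mrna_counts = read_count_matrix(p("mrna_counts.tsv")),
    mirna_counts = read_count_matrix(p("mirna_counts.tsv")),
    target_pairs = read_target_pairs(p("target_pairs.tsv")),
    term_map = read_term_map(p("term_map.tsv"))
  )
}

#' Run the full tri-omics integration pipeline
#'
#' Executes every stage on a study: context-level methylation summaries and
#' Fisher comparison, per-context DMR calling, differential expression of
#' miRNAs (CPM + Welch t-test) and genes (external DE table when supplied,
#' otherwise the built-in t-test stand-in with the study thresholds),
#' DMR-gene linking, miRNA-locus methylation association, DMR-expression
#' cross-tabulation, triad building and negative-correlation classification,
#' and term enrichment of the key genes.
#'
#' @param input a study list from [read_study()] or [simulate_study()] (the
#'   latter's extra elements are ignored).
#' @param config a [pipeline_config()].
#' @param deg_table optional externally produced gene DE table
#'   (`feature_id, log2fc, q`); when `NULL` the built-in stand-in test runs
#'   on `input$mrna_counts`.
#' @param outdir optional directory; when given, result tables are written
#'   there as TSV/BED.
#' @return list of class `triomics_result` with elements
#'   `context_comparison, context_summary, dmr, dmr_links,
#'   deg, der, mirna_mc, dmr_expression, triads, key_genes, enrichment`.
#' @export
run_pipeline <- function(input, config = pipeline_config(),
                         deg_table = NULL, outdir = NULL) {
  calls_a <- input$meth$treatment
  calls_b <- input$meth$control

  context_summary <- list(
    treatment = summarize_contexts(calls_a),
    control = summarize_contexts(calls_b)
  )
  context_comparison <- compare_context_methylation(calls_a, calls_b)

  dmr <- call_dmrs(calls_a, calls_b, config)
  dmrs <- dmr$dmrs

  der <- t_test_der(input$mirna_counts,
                    groups = sub("_[0-9]+$", "", colnames(input$mirna_counts)),
                    treatment = "treatment", alpha_q = config$alpha_q)
  if (is.null(deg_table)) {
    deg_table <- t_test_der(input$mrna_counts,
                            groups = sub("_[0-9]+$", "",
                                         colnames(input$mrna_counts)),
                            treatment = "treatment",
                            alpha_q = config$alpha_q)
  }
  deg <- apply_deg_thresholds(deg_table, config)

  dmr_links <- link_dmrs_to_genes(dmrs, input$genes, config$flank)
  mirna_mc <- mirna_mc_association(input$mirna_loci,
                                   bind_rows(calls_a, calls_b))
  dmr_expression <- dmr_expression_summary(dmr_links, deg)

  der_targets <- input$target_pairs %>%
    inner_join(der %>% select(mirna_id = "feature_id",
                              mirna_dir = "direction"),
               by = "mirna_id") %>%
    filter(.data$mirna_dir %in% c("up", "down"))
  triads <- build_triads(deg, dmr_links, der_targets)
  key_genes <- key_gene_table(triads)

  enrichment <- NULL
  key_ids <- unique(key_genes$gene_id[key_genes$key_gene])
  background <- unique(c(input$term_map$gene, rownames(input$mrna_counts)))
  key_in_bg <- intersect(key_ids, background)
  if (length(key_in_bg) > 0) {
    enrichment <- hypergeom_enrich(key_in_bg, input$term_map, background)
  }

  res <- structure(list(
    context_summary = context_summary,
    context_comparison = context_comparison,
    dmr = dmr,
    dmr_links = dmr_links,
    deg = deg,
    der = der,
    mirna_mc = mirna_mc,
    dmr_expression = dmr_expression,
    triads = triads,
    key_genes = key_genes,
    enrichment = enrichment,
    config = config
  ), class = "triomics_result")

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    w <- function(x, f) readr::write_tsv(x, file.path(outdir, f),
                                         progress = FALSE)
    w(res$context_comparison, "context_comparison.tsv")
    w(res$dmr$windows, "window_stats.tsv")
    write_bed(res$dmr$dmrs, file.path(outdir, "dmrs.bed"))
    w(res$dmr_links, "dmr_gene_links.tsv")
    w(res$deg, "deg.tsv")
    w(res$der, "der.tsv")
    w(res$mirna_mc, "mirna_mc.tsv")
    w(res$dmr_expression, "dmr_expression_summary.tsv")
    w(res$triads, "triads.tsv")
    w(res$key_genes, "key_genes.tsv")
    if (!is.null(res$enrichment)) w(res$enrichment, "enrichment.tsv")
  }
  res
}

#' @export
print.triomics_result <- function(x, ...) {
  n_key <- sum(x$key_genes$key_gene)
  cat(sprintf(
    paste0("<triomics_result>\n  DMRs: %d (%d hyper / %d hypo)\n",
           "  DEGs: %d up, %d down\n  DERs: %d up, %d down\n",
           "  triads: %d (gene x miRNA pairs: %d); key genes: %d\n"),
    nrow(x$dmr$dmrs), sum(x$dmr$dmrs$direction == "hyper"),
    sum(x$dmr$dmrs$direction == "hypo"),
    sum(x$deg$direction == "up"), sum(x$deg$direction == "down"),
    sum(x$der$direction == "up"), sum(x$der$direction == "down"),
    nrow(x$triads), nrow(x$key_genes), n_key
  ))
  invisible(x)
}

#' Compare recovered triads with a planted truth
#'
#' Precision and recall of the `fully_negative` (gene, miRNA) pairs against
#' the planted negative triads of a simulation.
#'
#' @param key_genes key-gene table from [key_gene_table()] or a
#'   `triomics_result`.
#' @param truth truth list from [plant_neg_triads()].
#' @return tibble `n_called, n_true, n_hit, precision, recall`.
#' @export
triad_recovery <- function(key_genes, truth) {
  if (inherits(key_genes, "triomics_result")) key_genes <- key_genes$key_genes
  called <- key_genes %>% filter(.data$key_gene) %>%
    mutate(pair = paste(.data$gene_id, .data$mirna_id))
  true_pairs <- paste(truth$neg_triads$gene_id, truth$neg_triads$mirna_id)
  n_hit <- sum(called$pair %in% true_pairs)
  tibble(
    n_called = nrow(called),
    n_true = length(true_pairs),
    n_hit = n_hit,
    precision = if (nrow(called) > 0) n_hit / nrow(called) else NA_real_,
    recall = if (length(true_pairs) > 0) n_hit / length(true_pairs) else NA_real_
  )
}

#' Compare called DMRs with planted intervals
#'
#' Recall is the fraction of planted DMRs overlapped by at least one called
#' DMR of the same direction; the base-level false-positive fraction is the
#' share of called DMR bases (union over contexts) falling outside every
#' planted interval.
#'
#' @param dmrs called DMR tibble.
#' @param truth truth list (uses `dmr_intervals`).
#' @return tibble `n_planted, n_recovered, recall, called_bases,
#'   outside_bases, fp_base_fraction`.
#' @export
dmr_recovery <- function(dmrs, truth) {
  planted <- truth$dmr_intervals
  if (nrow(planted) == 0) {
    return(tibble(n_planted = 0L, n_recovered = 0L, recall = NA_real_,
                  called_bases = 0L, outside_bases = 0L,
                  fp_base_fraction = NA_real_))
  }
  hit <- logical(nrow(planted))
  if (nrow(dmrs) > 0) {
    ov <- overlap_join(
      planted %>% mutate(idx = row_number()),
      dmrs %>% select("chrom", "start", "end", "direction")
    )
    ok <- ov %>% filter(.data$direction == .data$direction_y)
    hit[unique(ok$idx)] <- TRUE
  }
  gr_called <- if (nrow(dmrs) > 0) {
    GenomicRanges::reduce(GenomicRanges::GRanges(
      dmrs$chrom, IRanges::IRanges(dmrs$start + 1L, dmrs$end)
    ))
  } else GenomicRanges::GRanges()
  gr_planted <- GenomicRanges::reduce(GenomicRanges::GRanges(
    planted$chrom, IRanges::IRanges(planted$start + 1L, planted$end)
  ))
  called_bases <- sum(GenomicRanges::width(gr_called))
  outside <- GenomicRanges::setdiff(gr_called, gr_planted)
  outside_bases <- sum(GenomicRanges::width(outside))
  tibble(
    n_planted = nrow(planted),
    n_recovered = sum(hit),
    recall = mean(hit),
    called_bases = called_bases,
    outside_bases = outside_bases,
    fp_base_fraction = if (called_bases > 0) outside_bases / called_bases
      else NA_real_
  )
}
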