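#' Pipeline configuration
#'
#' Bundles every tunable threshold of the analysis. Defaults follow the
#' published protocol for this assay: 1 kb sliding windows with 500 bp step,
#' a pooled read-coverage floor of 30 per sample per window, a methylation
#' level difference of more than 15 percentage points, a fold change above 2
#' or below 0.5, and p/FDR cutoffs of 0.05.
#'
#' @param window_size sliding-window width in bp.
#' @param step_size window step in bp (`window_size >= step_size > 0`).
#' @param min_window_coverage minimum pooled read total per window per sample.
#' @param min_level_diff minimum absolute methylation difference, in
#'   percentage points (strict `>`).
#' @param fc_bounds length-2 numeric, upper and lower methylation fold-change
#'   bounds (strict: keep if `fc > fc_bounds[1]` or `fc < fc_bounds[2]`).
#' @param alpha_p per-window p-value cutoff (strict `<`).
#' @param alpha_q FDR (Benjamini-Hochberg q) cutoff (strict `<`).
#' @param deg_min_abs_log2fc minimum absolute log2 fold change for a gene to
#'   be called differentially expressed (strict `>` by default).
#' @param deg_fc_strict logical; if `FALSE`, the log2FC threshold is inclusive.
#' @param flank promoter/downstream flank width in bp.
#' @param seed integer seed used by pipeline steps that draw random numbers.
#' @return a list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(window_size = 1000L,
                            step_size = 500L,
                            min_window_coverage = 30L,
                            min_level_diff = 15,
                            fc_bounds = c(2.0, 0.5),
                            alpha_p = 0.05,
                            alpha_q = 0.05,
                            deg_min_abs_log2fc = 1.0,
                            deg_fc_strict = TRUE,
                            flank = 2000L,
                            seed = 1L) {
  if (!(window_size >= step_size && step_size > 0)) {
    config_error("window_size (%s) must be >= step_size (%s) > 0",
                 window_size, step_size)
  }
  if (!(alpha_p > 0 && alpha_p <= 1 && alpha_q > 0 && alpha_q <= 1)) {
    config_error("alpha_p and alpha_q must lie in (0, 1]")
  }
  if (!(length(fc_bounds) == 2 && fc_bounds[1] > 1 && fc_bounds[2] < 1 &&
        fc_bounds[2] > 0)) {
    config_error("fc_bounds must satisfy fc_bounds[1] > 1 > fc_bounds[2] > 0")
  }
  structure(list(
    window_size = as.integer(window_size),
    step_size = as.integer(step_size),
    min_window_coverage = as.integer(min_window_coverage),
    min_level_diff = min_level_diff,
    fc_bounds = fc_bounds,
    alpha_p = alpha_p,
    alpha_q = alpha_q,
    deg_min_abs_log2fc = deg_min_abs_log2fc,
    deg_fc_strict = deg_fc_strict,
    flank = as.integer(flank),
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys fall back to the defaults of
#' [pipeline_config()].
#'
#' @param path YAML file with any subset of the `pipeline_config()` arguments.
#' @return a `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    config_error("unknown configuration key(s): %s", paste(bad, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

#' Synthetic-study configuration
#'
#' Parameters of the synthetic data generator. Defaults define the reference
#' simulated study: a 2 x 1 Mb genome, one pooled methylome per condition
#' (beta-binomial counts, mean coverage 40), per-context baseline levels of
#' 0.65/0.35/0.10 (CG/CHG/CHH), twenty planted 2 kb DMRs with a 0.40 level
#' shift, negative-binomial expression counts in 3 + 3 replicates with
#' planted |log2FC| = 2 effects, and five fully-negative gene-DMR-miRNA
#' triads plus five single-direction-flipped distractors.
#'
#' @param seed integer; fully determines all generator output.
#' @param n_chroms,chrom_len genome shape.
#' @param n_genes,n_mirna_loci number of gene models / miRNA precursor loci.
#' @param cytosine_density named fraction of positions that are cytosines of
#'   each context.
#' @param coverage_mean mean per-site read coverage (Poisson, truncated >= 1).
#' @param baseline_levels named per-context baseline methylation means.
#' @param bb_overdispersion beta-binomial concentration; larger is closer to
#'   binomial.
#' @param n_planted_dmrs number of planted intergenic 2 kb DMRs.
#' @param dmr_width planted DMR width in bp.
#' @param dmr_delta planted methylation level shift in `[0, 1]`.
#' @param shift_contexts contexts eligible for the planted shift. CHH is
#'   excluded by default: a 0.4 shift on the 0.10 CHH baseline is outside
#'   the range plant CHH methylation shows.
#' @param nb_dispersion negative-binomial dispersion of expression counts.
#'   The default 0.01 reflects replicate libraries drawn from a shared
#'   microspore pool per condition (near-technical variability).
#' @param n_planted_degs,n_planted_ders planted differentially expressed
#'   genes / miRNAs (totals, including triad members).
#' @param de_log2fc planted expression effect size in log2 units.
#' @param n_planted_neg_triads planted fully-negative triads.
#' @param n_distractor_triads planted triads with exactly one direction
#'   flipped (classifier specificity probes).
#' @param reps_per_condition expression replicates per condition.
#' @param flank intergenic margin kept around genes, bp.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_len = 1e6,
                       n_genes = 200L,
                       n_mirna_loci = 50L,
                       cytosine_density = c(CG = 0.02, CHG = 0.02, CHH = 0.04),
                       coverage_mean = 40,
                       baseline_levels = c(CG = 0.65, CHG = 0.35, CHH = 0.10),
                       bb_overdispersion = 1000,
                       n_planted_dmrs = 20L,
                       dmr_width = 2000L,
                       dmr_delta = 0.4,
                       shift_contexts = c("CG", "CHG"),
                       nb_dispersion = 0.01,
                       n_planted_degs = 30L,
                       n_planted_ders = 10L,
                       de_log2fc = 2.0,
                       n_planted_neg_triads = 5L,
                       n_distractor_triads = 5L,
                       reps_per_condition = 3L,
                       flank = 2000L) {
  counts <- c(n_chroms, n_genes, n_mirna_loci, n_planted_dmrs,
              n_planted_degs, n_planted_ders, n_planted_neg_triads,
              n_distractor_triads, reps_per_condition)
  if (any(counts < 0)) config_error("all counts must be >= 0")
  if (!all(.contexts %in% names(cytosine_density)) ||
      !all(.contexts %in% names(baseline_levels))) {
    config_error("cytosine_density and baseline_levels need CG, CHG and CHH entries")
  }
  if (any(baseline_levels < 0 | baseline_levels > 1) ||
      dmr_delta < 0 || dmr_delta > 1) {
    config_error("baseline levels and dmr_delta must lie in [0, 1]")
  }
  if (sum(cytosine_density[.contexts]) > 1) {
    config_error("cytosine densities sum to more than 1")
  }
  structure(list(
    seed = as.integer(seed),
    n_chroms = as.integer(n_chroms),
    chrom_len = as.integer(chrom_len),
    n_genes = as.integer(n_genes),
    n_mirna_loci = as.integer(n_mirna_loci),
    cytosine_density = cytosine_density[.contexts],
    coverage_mean = coverage_mean,
    baseline_levels = baseline_levels[.contexts],
    bb_overdispersion = bb_overdispersion,
    n_planted_dmrs = as.integer(n_planted_dmrs),
    dmr_width = as.integer(dmr_width),
    dmr_delta = dmr_delta,
    shift_contexts = intersect(.contexts, shift_contexts),
    nb_dispersion = nb_dispersion,
    n_planted_degs = as.integer(n_planted_degs),
    n_planted_ders = as.integer(n_planted_ders),
    de_log2fc = de_log2fc,
    n_planted_neg_triads = as.integer(n_planted_neg_triads),
    n_distractor_triads = as.integer(n_distractor_triads),
    reps_per_condition = as.integer(reps_per_condition),
    flank = as.integer(flank)
  ), class = "sim_config")
}
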