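#' Counts-per-million normalisation
#'
#' Scales each library so its counts sum to one million:
#' `cpm = count * 1e6 / library_total`.
#'
#' @param counts nonnegative count matrix, features x samples.
#' @param library_totals optional per-sample totals (e.g. full-library
#'   depths when `counts` holds a feature subset); column sums by default.
#' @return matrix of the same shape.
#' @export
cpm_normalize <- function(counts, library_totals = NULL) {
  totals <- library_totals %||% colSums(counts)
  zero <- which(totals == 0)
  if (length(zero) > 0) {
    validation_error("library total is zero for sample(s): %s",
                     paste(colnames(counts)[zero] %||% zero, collapse = ", "))
  }
  sweep(counts, 2, totals, "/") * 1e6
}

#' FPKM normalisation
#'
#' `fpkm = count * 1e9 / (length * library_total)`.
#'
#' @param counts count matrix, features x samples.
#' @param feature_lengths numeric vector of feature lengths (bp), one per row.
#' @param library_totals optional per-sample totals; column sums by default.
#' @return matrix of the same shape.
#' @export
fpkm <- function(counts, feature_lengths, library_totals = colSums(counts)) {
  if (any(feature_lengths <= 0)) {
    validation_error("feature lengths must be > 0")
  }
  sweep(sweep(counts, 1, feature_lengths, "/"), 2, library_totals, "/") * 1e9
}

#' Differential expression of miRNAs by CPM + Welch t-test
#'
#' Normalises to CPM, applies a per-feature two-sided Welch t-test between
#' the two replicate groups (on `log2(CPM + 1)` by default), adjusts with
#' Benjamini-Hochberg, and calls direction from the FDR alone (no
#' fold-change filter): `up` if `q < alpha_q` and the treatment mean is
#' higher, `down` if lower, else `ns`. The reported `log2fc` is
#' `log2((mean_cpm_A + 1) / (mean_cpm_B + 1))` (pseudocount 1 avoids
#' infinities). Features that are constant within both groups get `p = 1`
#' when the group means are equal and `p = 0` otherwise.
#'
#' @param counts count matrix, features x samples.
#' @param groups character/factor of length `ncol(counts)` with exactly two
#'   levels; the first level (or `treatment` argument) is the treatment.
#' @param treatment which group label is the treatment (A) condition.
#' @param alpha_q FDR cutoff for direction calls.
#' @param log_transform test on `log2(CPM + 1)` (default) or raw CPM.
#' @param lib_sizes optional per-sample library totals passed to
#'   [cpm_normalize()] (use when `counts` is a subset of the library).
#' @return tibble `feature_id, mean_norm_a, mean_norm_b, log2fc, p, q,
#'   direction, provenance`.
#' @export
t_test_der <- function(counts, groups, treatment = NULL, alpha_q = 0.05,
                       log_transform = TRUE, lib_sizes = NULL) {
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2) config_error("groups must have exactly two levels")
  treatment <- treatment %||% lv[1]
  ia <- which(groups == treatment)
  ib <- which(groups != treatment)
  if (length(ia) < 2 || length(ib) < 2) {
    config_error("each group needs at least 2 replicates")
  }
  cpm <- cpm_normalize(counts, lib_sizes)
  y <- if (log_transform) log2(cpm + 1) else cpm
  pvals <- vapply(seq_len(nrow(y)), function(i) {
    a <- y[i, ia]; b <- y[i, ib]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      return(if (mean(a) == mean(b)) 1 else 0)
    }
    t.test(a, b)$p.value
  }, numeric(1))
  qvals <- bh_adjust(pvals)
  mean_a <- rowMeans(cpm[, ia, drop = FALSE])
  mean_b <- rowMeans(cpm[, ib, drop = FALSE])
  lfc <- log2((mean_a + 1) / (mean_b + 1))
  tibble(
    feature_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    mean_norm_a = mean_a, mean_norm_b = mean_b,
    log2fc = lfc, p = pvals, q = qvals,
    direction = case_when(
      qvals < alpha_q & lfc > 0 ~ "up",
      qvals < alpha_q & lfc < 0 ~ "down",
      TRUE ~ "ns"
    ),
    provenance = "builtin-standin"
  )
}

#' Call differentially expressed genes from a DE table
#'
#' Applies the study thresholds to an externally produced (or built-in
#' stand-in) differential-expression table: `up` if `log2fc` exceeds the
#' threshold and `q < alpha_q`; `down` symmetrically; else `ns`. A fold
#' change of at least 2 corresponds to `|log2fc| >= 1`; the default treats
#' the log2FC boundary strictly (`> 1`).
#'
#' @param de_table tibble with at least `feature_id, log2fc, q`.
#' @param config a [pipeline_config()] (uses `deg_min_abs_log2fc`,
#'   `deg_fc_strict`, `alpha_q`).
#' @return the table with a recomputed `direction` column (and a
#'   `provenance` column, defaulting to `"external"` when absent).
#' @export
apply_deg_thresholds <- function(de_table, config = pipeline_config()) {
  assert_columns(de_table, c("feature_id", "log2fc", "q"), "DE table")
  thr <- config$deg_min_abs_log2fc
  pass_fc <- if (config$deg_fc_strict) {
    abs(de_table$log2fc) > thr
  } else {
    abs(de_table$log2fc) >= thr
  }
  de_table %>%
    mutate(
      direction = case_when(
        pass_fc & .data$q < config$alpha_q & .data$log2fc > 0 ~ "up",
        pass_fc & .data$q < config$alpha_q & .data$log2fc < 0 ~ "down",
        TRUE ~ "ns"
      ),
      provenance = if ("provenance" %in% names(de_table))
        .data$provenance else "external"
    )
}
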