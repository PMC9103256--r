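#' Per-site methylation level
#'
#' The level of a cytosine is the ratio of reads supporting methylation to
#' total reads covering the site.
#'
#' @param meth_count,total_count read counts (vectorised).
#' @return numeric vector of levels in `[0, 1]`.
#' @export
site_level <- function(meth_count, total_count) {
  if (any(total_count < 1)) {
    validation_error("site_level undefined for total_count < 1")
  }
  meth_count / total_count
}

#' Flag methylated cytosines
#'
#' Two rules are available. `"any"` (default): a site is methylated if at
#' least one read supports methylation. `"binomial"`: a site is methylated if
#' a one-sided binomial test of `meth_count` out of `total_count` against a
#' bisulfite conversion-error rate rejects at `alpha` (upper tail).
#'
#' @param calls cytosine-call tibble.
#' @param rule `"any"` or `"binomial"`.
#' @param error_rate assumed conversion-error rate for the binomial rule.
#' @param alpha significance level for the binomial rule.
#' @return logical vector, one entry per call.
#' @export
methylated_sites <- function(calls, rule = c("any", "binomial"),
                             error_rate = 0.005, alpha = 0.05) {
  rule <- match.arg(rule)
  if (rule == "any") {
    calls$meth_count >= 1
  } else {
    p <- pbinom(calls$meth_count - 1, calls$total_count, error_rate,
                lower.tail = FALSE)
    calls$meth_count >= 1 & p < alpha
  }
}

#' Summarise methylation by sequence context
#'
#' For one sample, counts sites and methylated sites per context, each
#' context's share of all methylated cytosines, and the coverage-weighted
#' mean level (pooled meth reads / pooled total reads) per context.
#'
#' @param calls cytosine-call tibble for a single sample.
#' @param rule,error_rate,alpha passed to [methylated_sites()].
#' @return a tibble with one row per context (`CG, CHG, CHH`) and columns
#'   `n_sites, n_methylated, mc_share, mean_level`, plus attribute
#'   `total_mc_fraction` (methylated sites / all sites).
#' @export
summarize_contexts <- function(calls, rule = c("any", "binomial"),
                               error_rate = 0.005, alpha = 0.05) {
  rule <- match.arg(rule)
  if (nrow(calls) == 0) {
    out <- tibble(context = .contexts, n_sites = 0L, n_methylated = 0L,
                  mc_share = 0, mean_level = NA_real_)
    attr(out, "total_mc_fraction") <- 0
    return(out)
  }
  calls$is_mc <- methylated_sites(calls, rule, error_rate, alpha)
  by_ctx <- calls %>%
    group_by(context = factor(.data$context, levels = .contexts)) %>%
    summarise(
      n_sites = n(),
      n_methylated = sum(.data$is_mc),
      meth_reads = sum(.data$meth_count),
      total_reads = sum(.data$total_count),
      .groups = "drop"
    ) %>%
    tidyr::complete(context, fill = list(n_sites = 0L, n_methylated = 0L,
                                         meth_reads = 0, total_reads = 0)) %>%
    mutate(context = as.character(context))
  total_mc <- sum(by_ctx$n_methylated)
  out <- by_ctx %>%
    mutate(
      mc_share = if (total_mc > 0) .data$n_methylated / total_mc else 0,
      mean_level = if_else(.data$total_reads > 0,
                           .data$meth_reads / .data$total_reads, NA_real_)
    ) %>%
    select("context", "n_sites", "n_methylated", "mc_share", "mean_level")
  attr(out, "total_mc_fraction") <- total_mc / sum(by_ctx$n_sites)
  out
}

#' Two-sided Fisher exact test for 2x2 tables
#'
#' Exact two-sided p-value by the point-probability criterion: the sum of
#' hypergeometric probabilities of all tables (with the observed margins)
#' whose probability does not exceed that of the observed table. This is the
#' construction used by `stats::fisher.test`; the implementation is
#' vectorised over tables for window-scale use. The table is
#' `rbind(c(a, b), c(c, d))` with rows = samples and columns =
#' (methylated, unmethylated) counts.
#'
#' @param a,b,c,d nonnegative integer vectors of equal length.
#' @return numeric vector of two-sided p-values.
#' @export
fisher_2x2 <- function(a, b, c, d) {
  n <- length(a)
  stopifnot(length(b) == n, length(c) == n, length(d) == n)
  if (any(a < 0 | b < 0 | c < 0 | d < 0)) {
    validation_error("fisher_2x2: counts must be nonnegative")
  }
  tot <- a + b + c + d
  if (any(tot == 0)) validation_error("fisher_2x2: all-zero table")
  m <- a + c   # methylated margin
  nn <- b + d  # unmethylated margin
  k <- a + b   # sample-A margin
  p <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(0L, k[i] - nn[i])
    hi <- min(k[i], m[i])
    support <- lo:hi
    dens <- dhyper(support, m[i], nn[i], k[i])
    obs <- dens[match(a[i], support)]
    # relative tolerance as in stats::fisher.test
    p[i] <- min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
  }
  p
}

#' Compare context-level methylation between two samples
#'
#' For each context (and for all contexts combined) builds the 2x2 table
#' (methylated sites, unmethylated sites) x (sample A, sample B) and applies
#' [fisher_2x2()]. The site-counting table is an analysis convention: the
#' underlying protocol states a Fisher comparison of methylation numbers but
#' not the table construction.
#'
#' @param calls_a,calls_b cytosine-call tibbles for the two samples.
#' @param rule,error_rate,alpha passed to [methylated_sites()].
#' @return tibble `context, mc_a, sites_a, mc_b, sites_b, p`.
#' @export
compare_context_methylation <- function(calls_a, calls_b,
                                        rule = c("any", "binomial"),
                                        error_rate = 0.005, alpha = 0.05) {
  rule <- match.arg(rule)
  sa <- summarize_contexts(calls_a, rule, error_rate, alpha)
  sb <- summarize_contexts(calls_b, rule, error_rate, alpha)
  per_ctx <- tibble(
    context = sa$context,
    mc_a = sa$n_methylated, sites_a = sa$n_sites,
    mc_b = sb$n_methylated, sites_b = sb$n_sites
  )
  combined <- tibble(
    context = "combined",
    mc_a = sum(sa$n_methylated), sites_a = sum(sa$n_sites),
    mc_b = sum(sb$n_methylated), sites_b = sum(sb$n_sites)
  )
  out <- bind_rows(per_ctx, combined)
  out$p <- NA_real_
  testable <- out$sites_a + out$sites_b > 0
  out$p[testable] <- fisher_2x2(
    out$mc_a[testable], out$sites_a[testable] - out$mc_a[testable],
    out$mc_b[testable], out$sites_b[testable] - out$mc_b[testable]
  )
  out
}

# ---- gene sub-features ------------------------------------------------------

# Partition each gene's neighbourhood into the ten analysis regions:
# promoter thirds (distal/intermediate/proximal, strand-aware, widths
# ceil(f/3)/f-2*ceil(f/3)/ceil(f/3)), first/internal/last exons and introns in
# transcription order, and the downstream flank. Returns 0-based half-open
# intervals; single-exon genes have no internal/last exon and no introns.
gene_subfeatures <- function(genes, flank = 2000L) {
  third <- as.integer(ceiling(flank / 3))
  rows <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ex <- g$exons[[1]] %>% arrange(start)
    k <- nrow(ex)
    introns <- if (k > 1) tibble(start = ex$end[-k], end = ex$start[-1]) else
      tibble(start = integer(), end = integer())
    introns <- introns %>% filter(.data$end > .data$start)
    ki <- nrow(introns)
    fwd <- g$strand == "+"
    ord_class <- function(n, kind) {
      # classes in transcription order for n blocks
      if (n == 0) return(character())
      cls <- rep(paste0("internal_", kind), n)
      cls[1] <- paste0("first_", kind)
      if (n > 1) cls[n] <- paste0("last_", kind)
      cls
    }
    exon_cls <- ord_class(k, "exon")
    intron_cls <- ord_class(ki, "intron")
    if (!fwd) {
      exon_cls <- rev(exon_cls)
      intron_cls <- rev(intron_cls)
    }
    if (fwd) {
      prom <- tibble(
        start = c(g$start - flank, g$start - flank + third, g$start - third),
        end = c(g$start - flank + third, g$start - third, g$start),
        feature_class = c("distal_promoter", "intermediate_promoter",
                          "proximal_promoter")
      )
      down <- tibble(start = g$end, end = g$end + flank,
                     feature_class = "downstream")
    } else {
      prom <- tibble(
        start = c(g$end + flank - third, g$end + third, g$end),
        end = c(g$end + flank, g$end + flank - third, g$end + third),
        feature_class = c("distal_promoter", "intermediate_promoter",
                          "proximal_promoter")
      )
      down <- tibble(start = g$start - flank, end = g$start,
                     feature_class = "downstream")
    }
    rows[[i]] <- bind_rows(
      prom,
      tibble(start = ex$start, end = ex$end, feature_class = exon_cls),
      tibble(start = introns$start, end = introns$end,
             feature_class = intron_cls),
      down
    ) %>%
      mutate(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
             start = pmax(.data$start, 0L))
  }
  bind_rows(rows) %>%
    filter(.data$end > .data$start) %>%
    select("gene_id", "chrom", "start", "end", "strand", "feature_class")
}

#' Regional methylation profile
#'
#' Coverage-weighted mean methylation level per sequence context in each of
#' the ten gene-anchored regions: the upstream flank split into strand-aware
#' thirds (distal, intermediate, proximal promoter), first/internal/last
#' exons and introns, and the downstream flank. Regions a gene does not have
#' (e.g. introns of a single-exon gene) contribute nothing; a region with no
#' covered sites anywhere reports `NA`, not zero.
#'
#' @param calls cytosine-call tibble (one sample).
#' @param genes gene-model tibble from [read_gff3_genes()].
#' @param flank flank width in bp.
#' @return tibble `context, feature_class, n_sites, mean_level`.
#' @export
region_methylation <- function(calls, genes, flank = 2000L) {
  feats <- gene_subfeatures(genes, flank)
  hits <- overlap_join(
    calls %>% mutate(start = .data$pos, end = .data$pos + 1L),
    feats
  )
  out <- hits %>%
    group_by(context = factor(.data$context, levels = .contexts),
             feature_class = factor(.data$feature_class,
                                    levels = .feature_classes)) %>%
    summarise(n_sites = n(),
              mean_level = sum(.data$meth_count) / sum(.data$total_count),
              .groups = "drop") %>%
    tidyr::complete(context, feature_class,
                    fill = list(n_sites = 0L, mean_level = NA_real_)) %>%
    mutate(context = as.character(context),
           feature_class = as.character(feature_class))
  out
}

#' Metagene methylation profile
#'
#' Fixed-bin profile across the upstream flank, the length-scaled gene body
#' and the downstream flank, strand-aware (bin 1 is the 5'-most upstream
#' bin). Within-bin levels are coverage-weighted means.
#'
#' @param calls cytosine-call tibble (one sample).
#' @param genes gene-model tibble.
#' @param flank flank width in bp.
#' @param body_bins,flank_bins bin counts for the gene body and each flank.
#' @return tibble `context, bin, segment, n_sites, mean_level`; `segment` is
#'   `upstream`, `body` or `downstream`.
#' @export
metagene_profile <- function(calls, genes, flank = 2000L,
                             body_bins = 60L, flank_bins = 20L) {
  spans <- bind_rows(
    genes %>% mutate(seg = "upstream",
                     s = if_else(.data$strand == "+", .data$start - flank, .data$end),
                     e = if_else(.data$strand == "+", .data$start, .data$end + flank)),
    genes %>% mutate(seg = "body", s = .data$start, e = .data$end),
    genes %>% mutate(seg = "downstream",
                     s = if_else(.data$strand == "+", .data$end, .data$start - flank),
                     e = if_else(.data$strand == "+", .data$end + flank, .data$start))
  ) %>%
    mutate(s = pmax(.data$s, 0L)) %>%
    select("gene_id", "chrom", "strand", "seg", start = "s", end = "e") %>%
    filter(.data$end > .data$start)
  hits <- overlap_join(
    calls %>% mutate(start = .data$pos, end = .data$pos + 1L),
    spans
  )
  nb <- c(upstream = flank_bins, body = body_bins, downstream = flank_bins)
  off <- c(upstream = 0L, body = flank_bins, downstream = flank_bins + body_bins)
  hits <- hits %>%
    mutate(
      rel = (.data$pos - .data$start_y) / (.data$end_y - .data$start_y),
      rel = if_else(.data$strand_y == "+", .data$rel, 1 - .data$rel),
      within = pmin(nb[.data$seg], floor(.data$rel * nb[.data$seg]) + 1L),
      bin = off[.data$seg] + as.integer(.data$within)
    )
  total_bins <- flank_bins * 2L + body_bins
  seg_of_bin <- rep(c("upstream", "body", "downstream"), times = nb)
  hits %>%
    group_by(context = factor(.data$context, levels = .contexts),
             bin = factor(.data$bin, levels = seq_len(total_bins))) %>%
    summarise(n_sites = n(),
              mean_level = sum(.data$meth_count) / sum(.data$total_count),
              .groups = "drop") %>%
    tidyr::complete(context, bin,
                    fill = list(n_sites = 0L, mean_level = NA_real_)) %>%
    mutate(context = as.character(context),
           bin = as.integer(as.character(bin)),
           segment = seg_of_bin[.data$bin]) %>%
    select("context", "bin", "segment", "n_sites", "mean_level")
}

#' Binned chromosome-wide methylation levels
#'
#' Coverage-weighted mean level per fixed-width genomic bin, per context and
#' overall; the tabular backing of circular genome-wide methylation plots.
#'
#' @param calls cytosine-call tibble (one sample).
#' @param bin_size bin width in bp.
#' @return tibble `chrom, start, end, context, n_sites, mean_level`.
#' @export
binned_levels <- function(calls, bin_size = 100000L) {
  calls %>%
    mutate(start = (.data$pos %/% bin_size) * bin_size) %>%
    group_by(.data$chrom, .data$start, .data$context) %>%
    summarise(n_sites = n(),
              mean_level = sum(.data$meth_count) / sum(.data$total_count),
              .groups = "drop") %>%
    mutate(end = .data$start + bin_size) %>%
    select("chrom", "start", "end", "context", "n_sites", "mean_level") %>%
    arrange(.data$chrom, .data$start, .data$context)
}

# Inner overlap join of two interval tibbles (both with chrom/start/end),
# via IRanges. Returns x's rows joined with y's columns for each overlapping
# pair; y columns whose names collide with x's get a "_y" suffix.
overlap_join <- function(x, y) {
  ycols <- y
  shared <- setdiff(intersect(names(y), names(x)), "chrom")
  names(ycols)[match(shared, names(ycols))] <- paste0(shared, "_y")
  ycols$chrom <- NULL
  if (nrow(x) == 0 || nrow(y) == 0) {
    return(dplyr::bind_cols(x[0, ], ycols[0, , drop = FALSE]))
  }
  gx <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1L, x$end))
  gy <- GenomicRanges::GRanges(y$chrom, IRanges::IRanges(y$start + 1L, y$end))
  ov <- GenomicRanges::findOverlaps(gx, gy)
  xi <- S4Vectors::queryHits(ov)
  yi <- S4Vectors::subjectHits(ov)
  dplyr::bind_cols(x[xi, ], ycols[yi, , drop = FALSE])
}
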