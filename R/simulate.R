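#' Simulate a genome annotation and cytosine site list
#'
#' Places non-overlapping gene models (1-5 exons) with at least `flank` bp
#' of intergenic margin, intersperses longer intergenic gaps to leave room
#' for intergenic features, places miRNA precursor loci in those gaps, and
#' assigns cytosine positions and contexts at the configured densities.
#' Fully deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `genes` (tibble as from [read_gff3_genes()]),
#'   `mirna_loci`, `sites` (tibble `chrom, pos, strand, context`),
#'   `chrom_lengths` (named vector) and `free_zones` (intergenic intervals
#'   at least `flank` away from every gene, available for planting).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "genome"))
  flank <- config$flank
  chroms <- paste0("chr", seq_len(config$n_chroms))
  chrom_lengths <- setNames(rep(config$chrom_len, config$n_chroms), chroms)
  quota <- diff(floor(seq(0, config$n_genes, length.out = config$n_chroms + 1)))

  gene_rows <- list()
  zone_rows <- list()
  gi <- 0L
  for (ci in seq_along(chroms)) {
    cursor <- flank
    for (j in seq_len(quota[ci])) {
      n_ex <- sample(1:5, 1)
      exon_lens <- sample(200:600, n_ex, replace = TRUE)
      intron_lens <- if (n_ex > 1) sample(100:400, n_ex - 1, replace = TRUE)
        else integer(0)
      span <- sum(exon_lens) + sum(intron_lens)
      start <- cursor
      end <- start + span
      if (end + flank > config$chrom_len) {
        config_error(
          "cannot place %d genes on %s at the requested density", quota[ci],
          chroms[ci]
        )
      }
      offs <- cumsum(c(0L, head(as.vector(rbind(exon_lens,
                                                c(intron_lens, 0L))), -1L)))
      ex_starts <- start + offs[seq(1, by = 2, length.out = n_ex)]
      gi <- gi + 1L
      gene_rows[[gi]] <- tibble(
        gene_id = sprintf("gene_%03d", gi),
        chrom = chroms[ci], start = start, end = end,
        strand = sample(c("+", "-"), 1),
        n_exons = n_ex,
        exons = list(tibble(start = as.integer(ex_starts),
                            end = as.integer(ex_starts + exon_lens)))
      )
      # gaps always leave a small intergenic zone (miRNA loci); occasional
      # long gaps leave room for planted intergenic DMRs
      gap_extra <- if (runif(1) < 0.3) sample(4200:5200, 1) else sample(2300:3500, 1)
      zone <- c(end + flank, end + gap_extra)  # >= flank from both genes
      if (zone[2] > zone[1]) {
        zone_rows[[length(zone_rows) + 1L]] <-
          tibble(chrom = chroms[ci], start = as.integer(zone[1]),
                 end = as.integer(zone[2]))
      }
      cursor <- end + flank + gap_extra
    }
  }
  genes <- if (gi == 0) {
    tibble(gene_id = character(), chrom = character(), start = integer(),
           end = integer(), strand = character(), tss = integer(),
           n_exons = integer(), exons = list())
  } else {
    bind_rows(gene_rows) %>%
      mutate(tss = if_else(.data$strand == "+", .data$start,
                           .data$end - 1L)) %>%
      select("gene_id", "chrom", "start", "end", "strand", "tss", "n_exons",
             "exons")
  }
  zones <- if (length(zone_rows) == 0) {
    tibble(chrom = character(), start = integer(), end = integer())
  } else bind_rows(zone_rows)

  # miRNA loci: 120 bp, one per (preferably short) free zone
  mirna_loci <- tibble(mirna_id = character(), chrom = character(),
                       start = integer(), end = integer(), strand = character())
  if (config$n_mirna_loci > 0) {
    cand <- zones %>%
      mutate(width = .data$end - .data$start) %>%
      filter(.data$width >= 200) %>%
      arrange(.data$width)  # leave the widest zones for planted DMRs
    if (nrow(cand) < config$n_mirna_loci) {
      config_error("not enough intergenic room for %d miRNA loci",
                   config$n_mirna_loci)
    }
    cand <- cand[seq_len(config$n_mirna_loci), ]
    s <- cand$start + vapply(cand$width - 120L,
                             function(w) sample.int(w, 1) - 1L, integer(1))
    mirna_loci <- tibble(
      mirna_id = sprintf("mir_%03d", seq_len(config$n_mirna_loci)),
      chrom = cand$chrom, start = as.integer(s), end = as.integer(s + 120L),
      strand = sample(c("+", "-"), config$n_mirna_loci, replace = TRUE)
    )
    zones <- dplyr::anti_join(
      zones, cand %>% select("chrom", "start", "end"),
      by = c("chrom", "start", "end")
    )
  }

  # cytosine sites: contexts at the configured per-position densities
  dens <- config$cytosine_density
  site_rows <- lapply(seq_along(chroms), function(ci) {
    len <- config$chrom_len
    n_ctx <- round(len * dens)
    total <- sum(n_ctx)
    pos <- sample.int(len, total) - 1L
    tibble(
      chrom = chroms[ci],
      pos = pos,
      strand = sample(c("+", "-"), total, replace = TRUE),
      context = rep(names(n_ctx), n_ctx)
    ) %>% arrange(.data$pos)
  })
  sites <- bind_rows(site_rows)

  list(genes = genes, mirna_loci = mirna_loci, sites = sites,
       chrom_lengths = chrom_lengths, free_zones = zones)
}

#' Plant ground-truth effects: DMRs, DE features and negative triads
#'
#' Chooses the planted structure for a simulated study: `n_planted_dmrs`
#' intergenic DMRs in free zones (alternating hyper/hypo),
#' `n_planted_neg_triads` fully-negative gene-DMR-miRNA triads (promoter DMR
#' + DE gene + targeting DE miRNA with coherent opposing directions,
#' alternating the hypo/up/down and hyper/down/up mirror patterns) plus
#' `n_distractor_triads` distractors with exactly one direction flipped, and
#' the remaining DE genes/miRNAs at random. Triad genes are chosen so that
#' no two are adjacent, keeping planted DMR intervals disjoint.
#'
#' @param genome output of [simulate_genome()].
#' @param config a [sim_config()].
#' @return a `truth` list: `dmr_intervals` (tibble `chrom, start, end,
#'   direction, kind, gene_id`), `de_genes` / `de_mirnas` (tibbles
#'   `feature_id, direction`), `neg_triads` and `distractor_triads` (tibbles
#'   `gene_id, gene_dir, dmr_dir, mirna_id, mirna_dir, flipped`),
#'   `target_pairs` (tibble `mirna_id, gene_id`).
#' @export
plant_neg_triads <- function(genome, config) {
  set.seed(stage_seed(config$seed, "plant"))
  grid <- .plant_grid
  genes <- genome$genes
  n_tri <- config$n_planted_neg_triads + config$n_distractor_triads

  # triad genes: shuffled greedy pick, no two adjacent on a chromosome
  ord <- sample(nrow(genes))
  picked <- integer(0)
  for (i in ord) {
    if (length(picked) == n_tri) break
    if (!any(c(i - 1L, i, i + 1L) %in% picked)) picked <- c(picked, i)
  }
  if (length(picked) < n_tri) {
    config_error("not enough non-adjacent genes for %d triads", n_tri)
  }
  if (config$n_planted_ders < n_tri) {
    config_error("n_planted_ders (%d) is below the %d triad miRNAs required",
                 config$n_planted_ders, n_tri)
  }
  if (config$n_planted_degs < n_tri || n_tri > nrow(genes)) {
    config_error("n_planted_degs (%d) is below the %d triad genes required",
                 config$n_planted_degs, n_tri)
  }
  if (nrow(genome$mirna_loci) < config$n_planted_ders) {
    config_error("not enough miRNA loci for %d DERs", config$n_planted_ders)
  }

  tri_genes <- genes[picked, ]
  tri_mirnas <- genome$mirna_loci$mirna_id[
    sample(nrow(genome$mirna_loci), n_tri)
  ]
  # alternate the two fully-negative mirror patterns
  pat_a <- seq_len(n_tri) %% 2 == 1  # hypo DMR, gene up, miRNA down
  tri <- tibble(
    gene_id = tri_genes$gene_id,
    gene_dir = if_else(pat_a, "up", "down"),
    dmr_dir = if_else(pat_a, "hypo", "hyper"),
    mirna_id = tri_mirnas,
    mirna_dir = if_else(pat_a, "down", "up"),
    flipped = "none"
  )
  # distractors: flip exactly one direction, cycling over the three slots
  is_distr <- seq_len(n_tri) > config$n_planted_neg_triads
  flip_slot <- rep(c("gene", "dmr", "mirna"),
                   length.out = sum(is_distr))
  di <- which(is_distr)
  for (j in seq_along(di)) {
    i <- di[j]
    slot <- flip_slot[j]
    if (slot == "gene") {
      tri$gene_dir[i] <- if (tri$gene_dir[i] == "up") "down" else "up"
    } else if (slot == "dmr") {
      tri$dmr_dir[i] <- if (tri$dmr_dir[i] == "hyper") "hypo" else "hyper"
    } else {
      tri$mirna_dir[i] <- if (tri$mirna_dir[i] == "up") "down" else "up"
    }
    tri$flipped[i] <- slot
  }

  # promoter DMR interval for each triad gene, aligned upstream to the
  # 500 bp planting lattice (see .plant_grid)
  tri_dmrs <- tibble(
    chrom = tri_genes$chrom,
    start = if_else(tri_genes$strand == "+",
                    (tri_genes$start %/% grid) * grid - config$dmr_width,
                    ((tri_genes$end + grid - 1L) %/% grid) * grid),
    direction = tri$dmr_dir,
    kind = "triad_promoter",
    gene_id = tri$gene_id
  ) %>%
    mutate(end = .data$start + config$dmr_width)

  # background DMRs in wide free zones
  bg_dmrs <- tibble(chrom = character(), start = integer(), end = integer(),
                    direction = character(), kind = character(),
                    gene_id = NA_character_)
  if (config$n_planted_dmrs > 0) {
    wide <- genome$free_zones %>%
      mutate(
        grid_start = ((.data$start + grid - 1L) %/% grid) * grid,
        room = .data$end - .data$grid_start - config$dmr_width
      ) %>%
      filter(.data$room >= 0) %>%
      arrange(dplyr::desc(.data$room))
    if (nrow(wide) < config$n_planted_dmrs) {
      config_error("only %d intergenic zones can hold a %d bp DMR; %d requested",
                   nrow(wide), config$dmr_width, config$n_planted_dmrs)
    }
    wide <- wide[sample(nrow(wide), config$n_planted_dmrs), ]
    off <- grid * vapply(wide$room %/% grid + 1L,
                         function(w) sample.int(w, 1) - 1L, integer(1))
    bg_dmrs <- tibble(
      chrom = wide$chrom,
      start = as.integer(wide$grid_start + off),
      end = as.integer(wide$grid_start + off + config$dmr_width),
      direction = rep(c("hyper", "hypo"),
                      length.out = config$n_planted_dmrs),
      kind = "background",
      gene_id = NA_character_
    )
  }
  dmr_intervals <- bind_rows(tri_dmrs, bg_dmrs) %>%
    arrange(.data$chrom, .data$start)

  # DE features: triad members plus random extras
  extra_deg_ids <- setdiff(genes$gene_id, tri$gene_id)
  extra_deg_ids <- sample(extra_deg_ids,
                          config$n_planted_degs - n_tri)
  de_genes <- bind_rows(
    tibble(feature_id = tri$gene_id, direction = tri$gene_dir),
    tibble(feature_id = extra_deg_ids,
           direction = rep(c("up", "down"), length.out = length(extra_deg_ids)))
  )
  extra_der_ids <- setdiff(genome$mirna_loci$mirna_id, tri$mirna_id)
  extra_der_ids <- sample(extra_der_ids,
                          config$n_planted_ders - n_tri)
  de_mirnas <- bind_rows(
    tibble(feature_id = tri$mirna_id, direction = tri$mirna_dir),
    tibble(feature_id = extra_der_ids,
           direction = rep(c("up", "down"), length.out = length(extra_der_ids)))
  )

  # target pairs: triad pairs + decoy targets for other miRNAs (decoys avoid
  # triad genes so no unplanted triad can arise from a promoter DMR)
  other_mirnas <- setdiff(genome$mirna_loci$mirna_id, tri$mirna_id)
  decoy_pool <- setdiff(genes$gene_id, tri$gene_id)
  decoys <- tibble(
    mirna_id = rep(other_mirnas, each = 2),
    gene_id = sample(decoy_pool, 2 * length(other_mirnas), replace = TRUE)
  )
  target_pairs <- bind_rows(
    tibble(mirna_id = tri$mirna_id, gene_id = tri$gene_id),
    decoys
  ) %>% distinct()

  list(
    dmr_intervals = dmr_intervals,
    de_genes = de_genes,
    de_mirnas = de_mirnas,
    neg_triads = tri %>% filter(.data$flipped == "none") %>%
      select(-"flipped"),
    distractor_triads = tri %>% filter(.data$flipped != "none"),
    target_pairs = target_pairs
  )
}

#' Simulate two-condition cytosine methylation reports
#'
#' Per site: read coverage is Poisson(`coverage_mean`) truncated at 1 and
#' the methylated count is beta-binomial with concentration
#' `bb_overdispersion` around the context baseline, shifted by
#' `+/- dmr_delta` in the treatment sample inside planted DMRs. The shift is
#' applied per context only where the shifted mean stays inside `[0, 1]`
#' (with the default baselines, hypo DMRs are expressed in the CG context
#' and hyper DMRs in CHG; CHH stays at baseline by design); if no context
#' can absorb the shift a configuration error is raised.
#'
#' @param sites site tibble from [simulate_genome()].
#' @param truth truth list from [plant_neg_triads()] (uses `dmr_intervals`),
#'   or `NULL` for a null simulation without planted effects.
#' @param config a [sim_config()].
#' @return list of two call tibbles, `treatment` and `control`.
#' @export
simulate_methylation <- function(sites, truth, config) {
  set.seed(stage_seed(config$seed, "methylation"))
  base <- config$baseline_levels
  delta <- config$dmr_delta
  dmrs <- if (is.null(truth)) NULL else truth$dmr_intervals
  mu_treat <- unname(base[sites$context])
  if (!is.null(dmrs) && nrow(dmrs) > 0) {
    eligible <- base[config$shift_contexts]
    shiftable <- c(
      hyper = any(eligible + delta <= 1),
      hypo = any(eligible - delta >= 0)
    )
    for (dir in unique(dmrs$direction)) {
      if (!shiftable[[dir]]) {
        config_error(
          "no context baseline can absorb a %s shift of %.2f", dir, delta
        )
      }
    }
    hits <- overlap_join(
      sites %>% mutate(row = row_number(), start = .data$pos,
                       end = .data$pos + 1L),
      dmrs %>% select("chrom", "start", "end", "direction")
    )
    if (nrow(hits) > 0) {
      sgn <- if_else(hits$direction == "hyper", 1, -1)
      shifted <- unname(base[hits$context]) + sgn * delta
      ok <- shifted >= 0 & shifted <= 1 &
        hits$context %in% config$shift_contexts
      mu_treat[hits$row[ok]] <- shifted[ok]
    }
  }
  n <- nrow(sites)
  draw_sample <- function(mu, sample_id) {
    cov <- rpois(n, config$coverage_mean)
    cov[cov == 0L] <- 1L
    meth <- rbetabinom(n, cov, mu, config$bb_overdispersion)
    sites %>%
      select("chrom", "pos", "strand", "context") %>%
      mutate(meth_count = as.integer(meth), total_count = as.integer(cov),
             sample_id = sample_id)
  }
  list(
    treatment = draw_sample(mu_treat, "treatment"),
    control = draw_sample(unname(base[sites$context]), "control")
  )
}

#' Simulate a negative-binomial count matrix with planted effects
#'
#' Baseline per-feature means are log-uniform on `[10, 1e4]` (planted DE
#' features on `[100, 1e4]`, representing effects on genes detectable in the
#' assay); planted features get their treatment-condition mean multiplied by
#' `2^(+/- de_log2fc)`; library sizes are jittered by +/-20%; counts are
#' negative-binomial with dispersion `nb_dispersion`.
#'
#' @param feature_ids character vector of feature identifiers.
#' @param de_truth tibble `feature_id, direction` of planted DE features, or
#'   `NULL` for a null matrix.
#' @param config a [sim_config()].
#' @param layer `"mrna"` or `"mirna"`; selects an independent random stream.
#' @param base_means optional fixed per-feature baseline means (recycled),
#'   overriding the log-uniform draw.
#' @return integer matrix, features x `2 * reps_per_condition`, with
#'   treatment columns first.
#' @export
simulate_counts <- function(feature_ids, de_truth, config, layer = "mrna",
                            base_means = NULL) {
  if (config$reps_per_condition < 1) {
    config_error("reps_per_condition must be >= 1")
  }
  set.seed(stage_seed(config$seed,
                      if (layer == "mrna") "counts_mrna" else "counts_mirna"))
  nf <- length(feature_ids)
  reps <- config$reps_per_condition
  base_mean <- 10^runif(nf, 1, 4)
  planted <- if (is.null(de_truth)) character(0) else de_truth$feature_id
  idx <- match(planted, feature_ids)
  if (any(is.na(idx))) {
    config_error("planted DE feature(s) absent from feature_ids")
  }
  # moderately expressed, so planted effects stay detectable without
  # dominating library composition (normalisation is plain CPM)
  base_mean[idx] <- 10^runif(length(idx), 2, 3)
  if (!is.null(base_means)) base_mean <- rep_len(base_means, nf)
  mult <- rep(1, nf)
  if (length(idx) > 0) {
    sgn <- if_else(de_truth$direction == "up", 1, -1)
    mult[idx] <- 2^(sgn * config$de_log2fc)
  }
  sf <- runif(2 * reps, 0.8, 1.2)
  cols <- c(paste0("treatment_", seq_len(reps)),
            paste0("control_", seq_len(reps)))
  m <- matrix(0L, nf, 2 * reps, dimnames = list(feature_ids, cols))
  for (j in seq_len(2 * reps)) {
    mu_j <- base_mean * (if (j <= reps) mult else 1) * sf[j]
    m[, j] <- rnbinom(nf, mu = mu_j, size = 1 / config$nb_dispersion)
  }
  # true per-library depth factors (baseline mass x jitter): power studies
  # on heavily-planted feature subsets can normalise with these to isolate
  # test power from library-composition shifts
  attr(m, "expected_totals") <- sum(base_mean) * sf
  m
}

#' Simulate a complete two-condition tri-omics study
#'
#' Runs [simulate_genome()], [plant_neg_triads()], [simulate_methylation()]
#' and [simulate_counts()] (both layers) and assembles every pipeline input
#' plus the ground truth. Fully deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `genes, mirna_loci, sites, meth` (list
#'   `treatment`/`control`), `mrna_counts, mirna_counts, target_pairs,
#'   term_map, truth, chrom_lengths, config`.
#' @export
simulate_study <- function(config = sim_config()) {
  genome <- simulate_genome(config)
  truth <- plant_neg_triads(genome, config)
  meth <- simulate_methylation(genome$sites, truth, config)
  mrna_counts <- simulate_counts(genome$genes$gene_id, truth$de_genes,
                                 config, layer = "mrna")
  mirna_counts <- simulate_counts(genome$mirna_loci$mirna_id,
                                  truth$de_mirnas, config, layer = "mirna")
  set.seed(stage_seed(config$seed, "extra"))
  term_pool <- sprintf("T%02d", 1:20)
  term_map <- tibble(
    gene = rep(genome$genes$gene_id,
               times = sample(1:3, nrow(genome$genes), replace = TRUE))
  ) %>%
    mutate(term = sample(term_pool, n(), replace = TRUE)) %>%
    distinct()
  list(
    genes = genome$genes,
    mirna_loci = genome$mirna_loci,
    sites = genome$sites,
    meth = meth,
    mrna_counts = mrna_counts,
    mirna_counts = mirna_counts,
    target_pairs = truth$target_pairs,
    term_map = term_map,
    truth = truth,
    chrom_lengths = genome$chrom_lengths,
    config = config
  )
}

#' Write a simulated study to disk
#'
#' Emits every pipeline input in its external format: two cytosine reports,
#' a GFF3, a miRNA BED, two count-matrix TSVs, target-pair and term-map
#' TSVs, and the ground truth as JSON.
#'
#' @param sim output of [simulate_study()].
#' @param outdir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_study <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_cytosine_report(sim$meth$treatment, p("methylation_treatment.tsv"))
  write_cytosine_report(sim$meth$control, p("methylation_control.tsv"))
  write_gff3_genes(sim$genes, p("genes.gff3"))
  readr::write_tsv(
    sim$mirna_loci %>%
      mutate(score = 0) %>%
      select("chrom", "start", "end", "mirna_id", "score", "strand"),
    p("mirna_loci.bed"), col_names = FALSE, progress = FALSE
  )
  write_count_matrix(sim$mrna_counts, p("mrna_counts.tsv"))
  write_count_matrix(sim$mirna_counts, p("mirna_counts.tsv"))
  readr::write_tsv(sim$target_pairs, p("target_pairs.tsv"), progress = FALSE)
  readr::write_tsv(sim$term_map, p("term_map.tsv"), progress = FALSE)
  truth_json <- sim$truth
  truth_json$chrom_lengths <- as.list(sim$chrom_lengths)
  jsonlite::write_json(truth_json, p("truth.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  paths <- c(
    meth_treatment = p("methylation_treatment.tsv"),
    meth_control = p("methylation_control.tsv"),
    genes = p("genes.gff3"),
    mirna_loci = p("mirna_loci.bed"),
    mrna_counts = p("mrna_counts.tsv"),
    mirna_counts = p("mirna_counts.tsv"),
    target_pairs = p("target_pairs.tsv"),
    term_map = p("term_map.tsv"),
    truth = p("truth.json")
  )
  invisible(paths)
}
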