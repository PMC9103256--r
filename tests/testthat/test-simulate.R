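test_that("the generator is fully deterministic under a fixed seed", {
  s1 <- simulate_study(small_sim_config(seed = 9))
  s2 <- simulate_study(small_sim_config(seed = 9))
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$meth$treatment, s2$meth$treatment)
  expect_identical(s1$mrna_counts, s2$mrna_counts)
  expect_identical(s1$truth, s2$truth)
})

test_that("all simulated features lie within chromosome bounds with margins", {
  cfg <- sim_config(seed = 2)
  g <- simulate_genome(cfg)
  expect_equal(nrow(g$genes), cfg$n_genes)
  expect_true(all(g$genes$start >= cfg$flank))
  expect_true(all(g$genes$end + cfg$flank <= cfg$chrom_len))
  expect_true(all(g$sites$pos >= 0 & g$sites$pos < cfg$chrom_len))
  expect_true(all(g$mirna_loci$start >= 0 &
                    g$mirna_loci$end <= cfg$chrom_len))
  # exhaustive margin scan: consecutive genes on a chromosome
  by_chr <- split(g$genes, g$genes$chrom)
  for (gg in by_chr) {
    gg <- gg[order(gg$start), ]
    if (nrow(gg) > 1) {
      expect_true(all(gg$start[-1] - gg$end[-nrow(gg)] >= cfg$flank))
    }
  }
  # miRNA loci at least flank away from every gene body
  ov <- methtriad:::overlap_join(
    g$mirna_loci,
    g$genes %>% dplyr::transmute(chrom,
                                 start = start - cfg$flank,
                                 end = end + cfg$flank, body = TRUE)
  )
  expect_equal(nrow(ov), 0)
})

test_that("zero genes yields a valid empty annotation", {
  cfg <- sim_config(seed = 1, n_genes = 0, n_mirna_loci = 0,
                    n_planted_dmrs = 0, n_planted_degs = 0,
                    n_planted_ders = 0, n_planted_neg_triads = 0,
                    n_distractor_triads = 0)
  g <- simulate_genome(cfg)
  expect_equal(nrow(g$genes), 0)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3_genes(g$genes, f)
  expect_equal(nrow(read_gff3_genes(f)), 0)
})

test_that("beta-binomial draws approach the binomial limit", {
  set.seed(11)
  n <- 1e4
  x <- rbetabinom(n, size = 40, mu = 0.3, conc = 1e8)
  binom_var <- 40 * 0.3 * 0.7
  expect_lt(abs(var(x) - binom_var) / binom_var, 0.10)
  # and exceed it at strong overdispersion
  y <- rbetabinom(n, size = 40, mu = 0.3, conc = 5)
  expect_gt(var(y), 2 * binom_var)
})

test_that("planted hyper regions shift the treatment mean by delta", {
  cfg <- sim_config(
    seed = 12, n_chroms = 1, chrom_len = 2e5,
    baseline_levels = c(CG = 0.3, CHG = 0.3, CHH = 0.3),
    shift_contexts = c("CG", "CHG", "CHH"), dmr_delta = 0.4
  )
  sites <- tibble::tibble(
    chrom = "chr1", pos = 0:(2e4 - 1), strand = "+",
    context = rep(c("CG", "CHG", "CHH"), length.out = 2e4)
  )
  truth <- list(dmr_intervals = tibble::tibble(
    chrom = "chr1", start = 0L, end = 2e4, direction = "hyper"
  ))
  meth <- simulate_methylation(sites, truth, cfg)
  lev_t <- sum(meth$treatment$meth_count) / sum(meth$treatment$total_count)
  lev_c <- sum(meth$control$meth_count) / sum(meth$control$total_count)
  expect_equal(lev_t, 0.7, tolerance = 0.02 / 0.7)
  expect_equal(lev_c, 0.3, tolerance = 0.02 / 0.3)
})

test_that("a null simulation leaves genome-wide levels equal", {
  cfg <- sim_config(seed = 13, n_chroms = 2, chrom_len = 7e5,
                    n_genes = 100, n_mirna_loci = 10, n_planted_dmrs = 0)
  g <- simulate_genome(cfg)
  expect_gt(nrow(g$sites), 1e5)
  meth <- simulate_methylation(g$sites, NULL, cfg)
  lev <- function(x) sum(x$meth_count) / sum(x$total_count)
  expect_lt(abs(lev(meth$treatment) - lev(meth$control)), 0.01)
})

test_that("an unabsorbable shift is a configuration error", {
  cfg <- sim_config(seed = 1, baseline_levels = c(CG = 0.9, CHG = 0.9,
                                                  CHH = 0.9),
                    shift_contexts = c("CG", "CHG", "CHH"), dmr_delta = 0.4)
  sites <- tibble::tibble(chrom = "chr1", pos = 0:99, strand = "+",
                          context = "CG")
  truth <- list(dmr_intervals = tibble::tibble(
    chrom = "chr1", start = 0L, end = 100L, direction = "hyper"
  ))
  expect_error(simulate_methylation(sites, truth, cfg),
               class = "methtriad_config_error")
})

test_that("planted count effects land near the requested log2 fold change", {
  cfg <- sim_config(seed = 14)
  truth <- tibble::tibble(feature_id = sprintf("p%03d", 1:200),
                          direction = rep(c("up", "down"), 100))
  m <- simulate_counts(truth$feature_id, truth, cfg, layer = "mirna")
  cpm <- cpm_normalize(m, attr(m, "expected_totals"))
  lfc <- log2((rowMeans(cpm[, 1:3]) + 1) / (rowMeans(cpm[, 4:6]) + 1))
  signed <- ifelse(truth$direction == "up", lfc, -lfc)
  expect_gt(mean(signed > 1.5 & signed < 2.5), 0.95)
})

test_that("requesting zero replicates is a configuration error", {
  cfg <- small_sim_config(seed = 1)
  cfg$reps_per_condition <- 0L
  expect_error(simulate_counts(c("a", "b"), NULL, cfg),
               class = "methtriad_config_error")
})

test_that("planted triads are coherent and distractors break one direction", {
  cfg <- small_sim_config(seed = 15)
  g <- simulate_genome(cfg)
  truth <- plant_neg_triads(g, cfg)
  expect_equal(nrow(truth$neg_triads), cfg$n_planted_neg_triads)
  expect_equal(nrow(truth$distractor_triads), cfg$n_distractor_triads)
  lab_neg <- classify_negative(truth$neg_triads$gene_dir,
                               truth$neg_triads$dmr_dir,
                               truth$neg_triads$mirna_dir)
  expect_true(all(lab_neg == "fully_negative"))
  lab_dis <- classify_negative(truth$distractor_triads$gene_dir,
                               truth$distractor_triads$dmr_dir,
                               truth$distractor_triads$mirna_dir)
  expect_true(all(lab_dis != "fully_negative"))
  # planted intervals are pairwise disjoint
  iv <- truth$dmr_intervals %>% dplyr::arrange(chrom, start)
  by_chr <- split(iv, iv$chrom)
  for (x in by_chr) {
    if (nrow(x) > 1) expect_true(all(x$start[-1] >= x$end[-nrow(x)]))
  }
})

test_that("requesting more triads than genes errors", {
  cfg <- small_sim_config(seed = 1)
  cfg$n_planted_neg_triads <- 60L
  cfg$n_distractor_triads <- 60L
  g <- simulate_genome(cfg)
  expect_error(plant_neg_triads(g, cfg), class = "methtriad_config_error")
})

test_that("emitted files re-validate through the readers without warnings", {
  sim <- simulate_study(small_sim_config(seed = 16))
  dir <- withr::local_tempdir()
  write_study(sim, dir)
  expect_no_warning(study <- read_study(dir))
  expect_equal(study$meth$treatment %>% dplyr::select(-sample_id),
               sim$meth$treatment %>% dplyr::select(-sample_id))
  expect_equal(study$genes$start, sim$genes$start)
  expect_equal(study$genes$tss, sim$genes$tss)
  expect_equal(study$mrna_counts, sim$mrna_counts + 0,
               ignore_attr = "expected_totals")
  expect_equal(study$mirna_loci$start, sim$mirna_loci$start)
})
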