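test_that("window tiling follows the stated start/step/truncation rules", {
  w <- tile_windows(c(c1 = 2500), 1000, 500)
  expect_equal(w$start, c(0L, 500L, 1000L, 1500L, 2000L))
  expect_equal(w$end[5], 2500L)

  w2 <- tile_windows(c(c1 = 800), 1000, 500)
  expect_equal(nrow(w2), 2L)  # starts 0 and 500, both truncated at 800
  expect_equal(w2$end, c(800L, 800L))
  expect_equal(tile_windows(c(c1 = 800), 1000, 1000)$end, 800L)
})

test_that("window counts match a brute-force tiling oracle on random lengths", {
  set.seed(3)
  lens <- sample(1000:20000, 6)
  names(lens) <- paste0("c", seq_along(lens))
  for (step in c(500, 1000)) {
    w <- tile_windows(lens, 1000, step)
    expect_equal(nrow(w), sum(ceiling(lens / step)))
    # brute force: every base covered by the window set
    for (ch in names(lens)) {
      ww <- w[w$chrom == ch, ]
      covered <- rep(FALSE, lens[[ch]])
      for (i in seq_len(nrow(ww))) {
        covered[(ww$start[i] + 1):ww$end[i]] <- TRUE
      }
      expect_true(all(covered))
    }
  }
})

test_that("windows with identical pooled tables get p = 1", {
  a <- make_calls(pos = seq(0, 900, 100), meth = 5, total = 10)
  b <- make_calls(pos = seq(0, 900, 100), meth = 5, total = 10)
  w <- window_test(a, b, "CG", pipeline_config(), c(chr1 = 1000))
  expect_equal(w$p, rep(1, nrow(w)), tolerance = 1e-9)
})

test_that("bh_adjust reproduces the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.013), 0.013)
  expect_equal(bh_adjust(numeric()), numeric())
  set.seed(4)
  for (i in 1:200) {
    p <- runif(sample(1:60, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
})

test_that("filters keep and drop windows per the threshold arithmetic", {
  cfg <- pipeline_config()
  calls_a <- make_calls(pos = c(seq(0, 950, 50), seq(3000, 3950, 50)),
                        meth = c(rep(14, 20), rep(8, 20)), total = 20)
  calls_b <- make_calls(pos = c(seq(0, 950, 50), seq(3000, 3950, 50)),
                        meth = c(rep(6, 20), rep(6, 20)), total = 20)
  stats <- tibble::tibble(
    chrom = "chr1", start = c(0L, 3000L), end = c(1000L, 4000L),
    context = "CG",
    meth_a = c(280, 160), total_a = c(400, 400),
    meth_b = c(120, 120), total_b = c(400, 400),
    level_a = c(0.70, 0.40), level_b = c(0.30, 0.30),
    p = c(1e-6, 1e-6), q = c(1e-5, 1e-5)
  )
  dmrs <- filter_and_merge(stats, cfg, calls_a, calls_b)
  # 0.70 vs 0.30: delta 40 pts > 15, FC 2.33 > 2 -> kept
  # 0.40 vs 0.30: delta 10 pts -> dropped regardless of p
  expect_equal(nrow(dmrs), 1)
  expect_equal(dmrs$start, 0L)
  expect_equal(dmrs$direction, "hyper")
  expect_equal(dmrs$fold_change, 0.70 / 0.30, tolerance = 1e-9)
})

test_that("a low fold change with negative delta is kept as hypo", {
  cfg <- pipeline_config()
  calls_a <- make_calls(pos = seq(0, 950, 50), meth = 4, total = 20)
  calls_b <- make_calls(pos = seq(0, 950, 50), meth = 9, total = 20)
  stats <- tibble::tibble(
    chrom = "chr1", start = 0L, end = 1000L, context = "CG",
    meth_a = 80, total_a = 400, meth_b = 180, total_b = 400,
    level_a = 0.20, level_b = 0.45, p = 1e-8, q = 1e-7
  )
  dmrs <- filter_and_merge(stats, cfg, calls_a, calls_b)
  expect_equal(nrow(dmrs), 1)
  expect_equal(dmrs$direction, "hypo")
  expect_lt(dmrs$fold_change, 0.5)
})

test_that("overlapping significant windows merge without double-counting cytosines", {
  cfg <- pipeline_config()
  pos <- seq(0, 1950, 50)  # 40 sites over [0, 2000)
  calls_a <- make_calls(pos = pos, meth = 16, total = 20)
  calls_b <- make_calls(pos = pos, meth = 4, total = 20)
  mk <- function(s, e, na, nb) tibble::tibble(
    chrom = "chr1", start = s, end = e, context = "CG",
    meth_a = na * 16, total_a = na * 20, meth_b = na * 4, total_b = na * 20,
    level_a = 0.8, level_b = 0.2, p = 1e-9, q = 1e-8
  )
  stats <- dplyr::bind_rows(mk(0L, 1000L, 20, 20), mk(500L, 1500L, 20, 20),
                            mk(1000L, 2000L, 20, 20))
  dmrs <- filter_and_merge(stats, cfg, calls_a, calls_b)
  expect_equal(nrow(dmrs), 1)
  expect_equal(dmrs$start, 0L)
  expect_equal(dmrs$end, 2000L)
  expect_equal(dmrs$n_merged_windows, 3L)
  # merged counts = sums over the 40 distinct sites, not over window copies
  expect_equal(dmrs$total_a, 40 * 20)
  expect_equal(dmrs$meth_a, 40 * 16)
  expect_equal(dmrs$q, 1e-8)
})

test_that("swapping conditions maps hyper DMRs to identical hypo DMRs", {
  cfg <- small_sim_config(seed = 5)
  g <- simulate_genome(cfg)
  truth <- plant_neg_triads(g, cfg)
  meth <- simulate_methylation(g$sites, truth, cfg)
  pc <- pipeline_config()
  fwd <- call_dmrs(meth$treatment, meth$control, pc,
                   chrom_lengths = g$chrom_lengths)
  rev <- call_dmrs(meth$control, meth$treatment, pc,
                   chrom_lengths = g$chrom_lengths)
  expect_gt(nrow(fwd$dmrs), 0)
  key <- function(d) d %>%
    dplyr::arrange(chrom, start, context) %>%
    dplyr::select(chrom, start, end, context, p, q) %>%
    dplyr::mutate(p = signif(p, 10), q = signif(q, 10))
  expect_equal(key(rev$dmrs), key(fwd$dmrs))
  m <- dplyr::inner_join(fwd$dmrs, rev$dmrs,
                         by = c("chrom", "start", "end", "context"))
  expect_true(all(ifelse(m$direction.x == "hyper", "hypo", "hyper") ==
                    m$direction.y))
  expect_equal(abs(m$delta.x), abs(m$delta.y), tolerance = 1e-9)
})

test_that("tidy and glance summarise a dmr_result", {
  cfg <- small_sim_config(seed = 6)
  g <- simulate_genome(cfg)
  truth <- plant_neg_triads(g, cfg)
  meth <- simulate_methylation(g$sites, truth, cfg)
  res <- call_dmrs(meth$treatment, meth$control,
                   chrom_lengths = g$chrom_lengths)
  td <- tidy(res)
  gl <- glance(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_dmrs, nrow(td))
  expect_equal(gl$n_hyper + gl$n_hypo, gl$n_dmrs)
})
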