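test_that("site_level is the methylated read fraction", {
  expect_equal(site_level(3, 12), 0.25)
  expect_equal(site_level(0, 10), 0)
  expect_equal(site_level(10, 10), 1)
  expect_error(site_level(0, 0), class = "methtriad_validation_error")
})

test_that("context summaries count mC shares and weighted levels", {
  calls <- dplyr::bind_rows(
    make_calls(pos = 1:3, context = "CG", meth = c(5, 3, 2), total = 10),
    make_calls(pos = 10, context = "CHH", meth = 1, total = 10),
    make_calls(pos = 20, context = "CHG", meth = 0, total = 10)
  )
  s <- summarize_contexts(calls)
  expect_equal(s$mc_share[s$context == "CG"], 0.75)
  expect_equal(s$mc_share[s$context == "CHH"], 0.25)
  expect_equal(s$mc_share[s$context == "CHG"], 0)
  expect_equal(sum(s$mc_share), 1, tolerance = 1e-9)
  expect_equal(s$mean_level[s$context == "CG"], 10 / 30)
  expect_equal(attr(s, "total_mc_fraction"), 4 / 5)

  none <- make_calls(pos = 1:4, meth = 0, total = 10)
  expect_equal(attr(summarize_contexts(none), "total_mc_fraction"), 0)
})

test_that("weighted mean level is invariant to splitting a site's reads", {
  whole <- make_calls(pos = c(1, 2), meth = c(6, 2), total = c(10, 8))
  split <- make_calls(pos = c(1, 1, 2), meth = c(4, 2, 2),
                      total = c(7, 3, 8))
  expect_equal(summarize_contexts(whole)$mean_level,
               summarize_contexts(split)$mean_level)
})

test_that("binomial-rule mC calling requires evidence above the error rate", {
  calls <- make_calls(pos = 1:3, meth = c(0, 1, 10), total = c(30, 30, 30))
  expect_equal(methylated_sites(calls, "any"), c(FALSE, TRUE, TRUE))
  bin <- methylated_sites(calls, "binomial", error_rate = 0.005)
  expect_equal(bin[1], FALSE)
  expect_equal(bin[3], TRUE)
})

test_that("fisher_2x2 matches hand enumeration and stats::fisher.test", {
  expect_equal(fisher_2x2(10, 10, 10, 10), 1)
  # table [[3,0],[0,3]]: P(X=3) = P(X=0) = 1/20 -> p = 0.1
  expect_equal(fisher_2x2(3, 0, 0, 3), 0.1)
  expect_error(fisher_2x2(0, 0, 0, 0), class = "methtriad_validation_error")

  set.seed(1)
  for (i in 1:50) {
    t4 <- rpois(4, 8)
    if (sum(t4) == 0) next
    ours <- fisher_2x2(t4[1], t4[2], t4[3], t4[4])
    ref <- stats::fisher.test(matrix(t4, 2, byrow = TRUE))$p.value
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("fisher_2x2 is symmetric under row and column swaps", {
  set.seed(2)
  for (i in 1:25) {
    t4 <- rpois(4, 6)
    if (sum(t4) == 0) next
    p0 <- fisher_2x2(t4[1], t4[2], t4[3], t4[4])
    expect_equal(fisher_2x2(t4[3], t4[4], t4[1], t4[2]), p0)  # swap rows
    expect_equal(fisher_2x2(t4[2], t4[1], t4[4], t4[3]), p0)  # swap cols
  }
})

test_that("context comparison tests per-context and combined mC tables", {
  a <- make_calls(pos = 1:40, meth = rep(c(0, 5), 20), total = 10)
  b <- make_calls(pos = 1:40, meth = rep(c(5, 5), 20), total = 10)
  cmp <- compare_context_methylation(a, b)
  expect_setequal(cmp$context, c("CG", "CHG", "CHH", "combined"))
  row <- cmp[cmp$context == "CG", ]
  expect_equal(row$p, fisher_2x2(20, 20, 40, 0))
})

test_that("a uniform methylation field gives flat regional and metagene profiles", {
  gene <- make_gene("g1", start = 10000, end = 14000,
                    exon_starts = c(10000, 11000, 12500, 13600),
                    exon_ends = c(10800, 12000, 13000, 14000))
  calls <- uniform_calls(from = 7000, to = 17000, by = 10, level = 0.5)
  reg <- region_methylation(calls, gene)
  cg <- reg[reg$context == "CG", ]
  expect_true(all(cg$n_sites > 0))
  expect_true(all(abs(cg$mean_level - 0.5) < 1e-12))

  prof <- metagene_profile(calls, gene)
  cgp <- prof[prof$context == "CG", ]
  expect_true(all(abs(cgp$mean_level[cgp$n_sites > 0] - 0.5) < 1e-12))
  expect_equal(nrow(cgp), 100)
})

test_that("single-exon genes report intron/internal regions as missing", {
  gene <- make_gene("g1", start = 5000, end = 6000)
  calls <- uniform_calls(from = 2000, to = 9000, by = 20, level = 0.3)
  reg <- region_methylation(calls, gene)
  cg <- reg[reg$context == "CG", ]
  absent <- c("internal_exon", "last_exon", "first_intron",
              "internal_intron", "last_intron")
  expect_true(all(is.na(cg$mean_level[cg$feature_class %in% absent])))
  expect_true(all(cg$n_sites[cg$feature_class %in% absent] == 0))
  expect_equal(cg$mean_level[cg$feature_class == "first_exon"], 0.3,
               tolerance = 1e-12)
})

test_that("minus-strand profiles mirror plus-strand profiles", {
  # same physical layout, gene annotated on opposite strands of mirrored data
  L <- 20000
  gene_fwd <- make_gene("g1", start = 8000, end = 11000, strand = "+",
                        exon_starts = c(8000, 9500),
                        exon_ends = c(9000, 11000))
  gene_rev <- make_gene("g1", start = L - 11000, end = L - 8000, strand = "-",
                        exon_starts = c(L - 11000, L - 9000),
                        exon_ends = c(L - 9500, L - 8000))
  pos <- seq(4000, 15000, by = 25)
  lev <- (pos %% 1000) / 2000  # spatially varying level
  calls_fwd <- make_calls(pos = pos, meth = round(lev * 20), total = 20)
  calls_rev <- make_calls(pos = L - 1 - pos, meth = round(lev * 20),
                          total = 20)
  pf <- metagene_profile(calls_fwd, gene_fwd)
  pr <- metagene_profile(calls_rev, gene_rev)
  cf <- pf[pf$context == "CG", ]
  cr <- pr[pr$context == "CG", ]
  expect_equal(cr$mean_level, cf$mean_level, tolerance = 1e-12)
})

test_that("promoter thirds have widths 667/666/667 on a 2 kb flank", {
  gene <- make_gene("g1", start = 10000, end = 12000)
  feats <- methtriad:::gene_subfeatures(gene, 2000L)
  prom <- feats[grepl("promoter", feats$feature_class), ]
  prom <- prom[order(prom$start), ]
  expect_equal(prom$feature_class,
               c("distal_promoter", "intermediate_promoter",
                 "proximal_promoter"))
  expect_equal(prom$end - prom$start, c(667L, 666L, 667L))
  expect_equal(prom$start[1], 8000L)
  expect_equal(prom$end[3], 10000L)
})
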