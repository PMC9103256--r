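all_tuples <- expand.grid(
  gene_dir = c("up", "down"), dmr_dir = c("hyper", "hypo"),
  mirna_dir = c("up", "down"), stringsAsFactors = FALSE
)

test_that("the classifier partitions the 2x2x2 direction space", {
  labels <- classify_negative(all_tuples$gene_dir, all_tuples$dmr_dir,
                              all_tuples$mirna_dir)
  expect_equal(length(labels), 8)
  expect_true(all(labels %in% c("fully_negative", "meth_negative_only",
                                "mirna_negative_only", "non_negative")))
  expect_equal(sum(labels == "fully_negative"), 2)
  expect_setequal(
    paste(all_tuples$gene_dir, all_tuples$dmr_dir,
          all_tuples$mirna_dir)[labels == "fully_negative"],
    c("up hypo down", "down hyper up")
  )
})

test_that("flipping all three directions preserves the label", {
  flip <- function(x, a, b) ifelse(x == a, b, a)
  l1 <- classify_negative(all_tuples$gene_dir, all_tuples$dmr_dir,
                          all_tuples$mirna_dir)
  l2 <- classify_negative(flip(all_tuples$gene_dir, "up", "down"),
                          flip(all_tuples$dmr_dir, "hyper", "hypo"),
                          flip(all_tuples$mirna_dir, "up", "down"))
  expect_equal(l2, l1)
})

test_that("unresolved directions are rejected", {
  expect_error(classify_negative("ns", "hyper", "down"),
               class = "methtriad_validation_error")
  expect_error(classify_negative("up", "mixed", "down"),
               class = "methtriad_validation_error")
})

test_that("published direction tuples flag exactly the published key genes", {
  # direction tuples recoverable from the study's association table and the
  # surrounding text; the key set is its hypo(up/down) + hyper(down/up) lists
  hypo_key <- c("Bol024133", "Bol044765", "Bol018627", "Bol019334")
  hyper_key <- c("Bol035641", "Bol010698", "Bol016979", "Bol042216",
                 "Bol017014", "Bol021292", "Bol007881")
  tab <- tibble::tibble(
    gene_id = c("Bol007667", "Bol016003", hypo_key, hyper_key),
    gene_dir = c("up", "up", rep("up", 4), rep("down", 7)),
    dmr_dir = c("hyper", "hypo", rep("hypo", 4), rep("hyper", 7)),
    mirna_dir = c("down", "up", rep("down", 4), rep("up", 7))
  )
  tab$label <- classify_negative(tab$gene_dir, tab$dmr_dir, tab$mirna_dir)
  flagged <- tab$gene_id[tab$label == "fully_negative"]
  expect_setequal(flagged, c(hypo_key, hyper_key))
  expect_false("Bol007667" %in% flagged)  # miRNA-only anti-correlation
  expect_false("Bol016003" %in% flagged)  # methylation-only anti-correlation
  expect_equal(tab$label[tab$gene_id == "Bol007667"], "mirna_negative_only")
  expect_equal(tab$label[tab$gene_id == "Bol016003"], "meth_negative_only")
})

test_that("triads form on the three-way join and expand per targeting DER", {
  degs <- tibble::tibble(feature_id = c("g1", "g2", "g3"),
                         direction = c("up", "down", "up"))
  links <- tibble::tibble(
    gene_id = c("g2", "g3", "g4"), chrom = "c1",
    start = c(0L, 5000L, 9000L), end = c(2000L, 7000L, 11000L),
    context = "CG", direction = "hypo",
    feature_class = "proximal_promoter", overlap_bp = 1000L
  )
  der_targets <- tibble::tibble(
    mirna_id = c("m1", "m2", "m3"),
    gene_id = c("g3", "g3", "g5"),
    mirna_dir = c("down", "up", "down")
  )
  tri <- suppressMessages(build_triads(degs, links, der_targets))
  expect_equal(unique(tri$gene_id), "g3")
  expect_equal(nrow(tri), 2)  # one per targeting DER
  expect_setequal(tri$label[tri$mirna_id == "m1"], "fully_negative")
  expect_setequal(tri$label[tri$mirna_id == "m2"], "meth_negative_only")
})

test_that("mixed-direction genes are excluded before classification", {
  degs <- tibble::tibble(feature_id = "g1", direction = "up")
  links <- tibble::tibble(
    gene_id = c("g1", "g1"), chrom = "c1",
    start = c(0L, 5000L), end = c(2000L, 7000L), context = "CG",
    direction = c("hyper", "hypo"),
    feature_class = c("proximal_promoter", "downstream"),
    overlap_bp = c(100L, 100L)
  )
  der_targets <- tibble::tibble(mirna_id = "m1", gene_id = "g1",
                                mirna_dir = "down")
  expect_message(tri <- build_triads(degs, links, der_targets), "mixed")
  expect_equal(nrow(tri), 0)
})

test_that("the key-gene table deduplicates (gene, miRNA) pairs", {
  triads <- tibble::tibble(
    gene_id = c("g1", "g1", "g2"),
    gene_dir = c("up", "up", "down"),
    dmr_dir = c("hypo", "hypo", "hyper"),
    dmr_location = c("proximal_promoter", "first_exon", "downstream"),
    mirna_id = c("m1", "m1", "m2"),
    mirna_dir = c("down", "down", "up"),
    label = c("fully_negative", "fully_negative", "fully_negative")
  )
  kt <- key_gene_table(triads)
  expect_equal(nrow(kt), 2)
  g1 <- kt[kt$gene_id == "g1", ]
  expect_equal(g1$dmr_location, "first_exon;proximal_promoter")
  expect_true(all(kt$key_gene))
})
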