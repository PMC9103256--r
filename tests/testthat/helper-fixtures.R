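# Small in-code fixtures shared across test files.

make_calls <- function(chrom = "chr1", pos, context = "CG", meth, total,
                       strand = "+", sample_id = "s") {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), strand = strand, context = context,
    meth_count = as.integer(meth), total_count = as.integer(total),
    sample_id = sample_id
  )
}

# a gene tibble row in the package's internal shape
make_gene <- function(gene_id = "g1", chrom = "chr1", start, end, strand = "+",
                      exon_starts = start, exon_ends = end) {
  tibble::tibble(
    gene_id = gene_id, chrom = chrom, start = as.integer(start),
    end = as.integer(end), strand = strand,
    tss = if (strand == "+") as.integer(start) else as.integer(end - 1L),
    n_exons = length(exon_starts),
    exons = list(tibble::tibble(start = as.integer(exon_starts),
                                end = as.integer(exon_ends)))
  )
}

# uniform-level calls covering [from, to) every `by` bases
uniform_calls <- function(chrom = "chr1", from, to, by = 50, level = 0.5,
                          total = 20, context = "CG") {
  pos <- seq(from, to - 1, by = by)
  make_calls(chrom, pos, context = context,
             meth = round(level * total), total = total)
}

small_sim_config <- function(seed = 1, ...) {
  sim_config(
    seed = seed, n_chroms = 1, chrom_len = 4e5, n_genes = 50,
    n_mirna_loci = 15, n_planted_dmrs = 6, n_planted_degs = 12,
    n_planted_ders = 6, n_planted_neg_triads = 3, n_distractor_triads = 3,
    ...
  )
}
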