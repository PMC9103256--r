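# Independent reference implementations used as oracles. These deliberately
# avoid the code paths they check (combinatorial enumeration, hand-written
# step-up, per-base interval arithmetic).

# two-sided Fisher p by direct combinatorial enumeration over the support
fisher_oracle <- function(a, b, c, d) {
  m <- a + c
  n <- b + d
  k <- a + b
  xs <- max(0, k - n):min(k, m)
  probs <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  obs <- probs[xs == a]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# hand-written Benjamini-Hochberg step-up
bh_oracle <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric())
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# upper-tail hypergeometric P(X >= k) by direct summation
hyper_tail_oracle <- function(k, K, N, n) {
  xs <- k:min(n, K)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# per-base sub-feature classification for one gene; returns the maximal
# overlap class for a DMR, with the package's tie-break order
subfeature_oracle <- function(gene, dmr_start, dmr_end, flank = 2000) {
  classes <- c("distal_promoter", "intermediate_promoter", "proximal_promoter",
               "first_exon", "internal_exon", "last_exon",
               "first_intron", "internal_intron", "last_intron", "downstream")
  bases <- seq(dmr_start, dmr_end - 1)
  third <- ceiling(flank / 3)
  ex <- gene$exons[[1]]
  ex <- ex[order(ex$start), ]
  k <- nrow(ex)
  classify_base <- function(b) {
    if (gene$strand == "+") {
      o_up <- gene$start - b    # >=1 when upstream
      o_dn <- b - gene$end + 1  # >=1 when downstream
    } else {
      o_up <- b - (gene$end - 1)
      o_dn <- gene$start - b
    }
    if (o_up >= 1 && o_up <= flank) {
      if (o_up <= third) return("proximal_promoter")
      if (o_up <= flank - third) return("intermediate_promoter")
      return("distal_promoter")
    }
    if (o_dn >= 1 && o_dn <= flank) return("downstream")
    if (b < gene$start || b >= gene$end) return(NA_character_)
    exon_idx <- which(b >= ex$start & b < ex$end)
    if (length(exon_idx) == 1) {
      ord <- if (gene$strand == "+") exon_idx else k + 1 - exon_idx
      if (ord == 1) return("first_exon")
      if (ord == k) return("last_exon")
      return("internal_exon")
    }
    intron_idx <- which(b >= ex$end[-k] & b < ex$start[-1])
    ni <- k - 1
    ord <- if (gene$strand == "+") intron_idx else ni + 1 - intron_idx
    if (ord == 1) return("first_intron")
    if (ord == ni) return("last_intron")
    return("internal_intron")
  }
  labels <- vapply(bases, classify_base, character(1))
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0) return(list(class = NA_character_, overlap = 0L))
  tab <- table(factor(labels, levels = classes))
  best <- max(tab)
  winner <- classes[which(tab == best)][1]  # tie-break by fixed order
  list(class = winner, overlap = as.integer(best),
       total_overlap = length(labels))
}
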