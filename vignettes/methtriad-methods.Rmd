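---
title: "Methods: tri-omics integration of methylation, miRNA and mRNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tri-omics integration of methylation, miRNA and mRNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methtriad)
```

## The analysis problem

methtriad implements a two-condition tri-omics integration as used to study
how a heat-shock pre-treatment (32 °C vs 25 °C) reprograms DNA methylation
and small-RNA regulation during microspore embryogenesis. Three data layers
enter the analysis:

* one pooled whole-genome bisulfite methylome per condition, as
  per-cytosine counts (methylated reads / total reads) in the three plant
  sequence contexts CG, CHG and CHH;
* miRNA read counts in 3 + 3 replicate libraries, plus predicted
  miRNA-to-target-gene pairs (target prediction itself is an input, not a
  step of this package);
* mRNA counts in 3 + 3 replicates, or an externally produced
  differential-expression table.

The scientific object of interest is the **triad**: a gene joined to (a)
the direction of a differentially methylated region (DMR) in or near it and
(b) the expression direction of a miRNA that targets it. A triad is *fully
negative* when the gene's expression direction opposes both regulators —
(gene up, DMR hypo, miRNA down) or (gene down, DMR hyper, miRNA up) — and
such genes are reported as *key genes*, the candidates for
methylation-and-miRNA-controlled regulation.

## Models and procedures

### Methylation summaries

The level of a cytosine is `meth_count / total_count`. A site counts as a
methylated cytosine (mC) when it has at least one supporting read (default)
or, optionally, when a one-sided binomial test against a 0.5% bisulfite
conversion-error rate rejects at 0.05. Context summaries report per-context
site counts, each context's share of all mCs and coverage-weighted mean
levels; condition differences in mC counts are tested per context with a
two-sided Fisher exact test on the (methylated, unmethylated) x (condition
A, condition B) table. The table construction is our convention — the assay
protocol names the test but not the table.

### DMR calling

The genome is tiled into 1 kb windows stepping every 500 bp. Per window and
context, counts are pooled over all cytosines on both strands (strand
pooling is our convention) and the two conditions are compared by a
two-sided Fisher exact test using the point-probability criterion — the sum
of hypergeometric table probabilities not exceeding the observed table's,
the same construction `stats::fisher.test` uses; we compute it vectorised
over windows for speed. Benjamini–Hochberg adjustment runs within each
context over all tested windows. A window survives when all of these hold:

| filter | default | boundary |
|---|---|---|
| p-value | 0.05 | strict `<` |
| BH q | 0.05 | strict `<` |
| pooled reads per sample | 30 | inclusive `>=` |
| level difference | 15 percentage points | strict `>` |
| fold change | `> 2` or `< 0.5` | strict |

"Level difference" implements the protocol's "level ratio of average
methylation > 15" as an absolute difference in percentage points; the
separate fold-change filter covers the ratio reading. Fold change is
`level_A / max(level_B, 0.005)`; floored records are flagged. Overlapping or
book-ended surviving windows of the same direction and context merge into
one DMR; merged counts are re-pooled over the *distinct* cytosines of the
merged span (no double counting across overlapping windows) and the Fisher
p is recomputed on that table. The merged q is the minimum member-window q:
the BH family is the window set, and re-running BH after merging would
change the testing family. Direction is hyper when the treatment level is
higher, hypo when lower; all thresholds the protocol writes with ">" are
strict and the coverage ">= 30" is inclusive.

With one pooled methylome per condition there is no replicate-aware model to
fit; Fisher on pooled counts is the defensible test, and replicate-aware or
smoothing-based DMR callers are out of scope.

### Differential expression

miRNAs: counts are CPM-normalised (`count * 1e6 / library_total`; an
explicit library-size argument supports testing feature subsets), and each
feature gets a two-sided Welch t-test on `log2(CPM + 1)` between the 3 + 3
replicate groups, BH adjustment across features, and a direction call from
the FDR alone (q < 0.05, no fold-change filter — the protocol applies only
an FDR cut to miRNAs). `log2fc = log2((mean_A + 1) / (mean_B + 1))`; the
pseudocount avoids infinities. A feature constant in both groups gets p = 1
when the group means are equal and p = 0 otherwise.

mRNAs: the canonical path ingests an externally produced DE table (e.g. an
edgeR run) and applies the study thresholds — up if `log2fc > 1` and
`q < 0.05`, down symmetrically (fold change >= 2 corresponds to
`|log2fc| >= 1`; the boundary is strict by default and configurable). For
fully synthetic end-to-end runs the same Welch-t machinery serves as a
built-in stand-in, labelled `builtin-standin` in the provenance column; it
is not an edgeR re-implementation and does not try to be one. FPKM
(`count * 1e9 / (length * library_total)`) is provided for gene-level
abundance reporting.

### Regional profiles and annotation

Each gene's neighbourhood is partitioned into ten sub-features: the 2 kb
upstream flank split into strand-aware thirds of 667/666/667 bp (distal,
intermediate, proximal promoter — widths are our choice; the protocol names
the bins only), first/internal/last exons and introns in transcription
order, and the 2 kb downstream flank. Regional profiles report the
coverage-weighted mean level per context in each sub-feature; regions a
gene lacks are reported as missing, not zero. Metagene curves use 20 bins
per flank and 60 length-scaled gene-body bins; genes shorter than the bin
count simply map sites through fractional coordinates.

A DMR links to a gene when it overlaps the gene body or its ±2 kb flank
(matching the profiled span). Its feature class is the sub-feature with the
maximal base overlap, ties broken by the fixed order promoter > exon >
intron > downstream. One DMR may link to several genes. Genes linked to
both hyper- and hypo-DMRs get direction "mixed" and are excluded from triad
classification (and logged): the negative-correlation patterns assume one
direction. A miRNA locus is "associated with mCs" when it contains at least
one methylated cytosine (threshold configurable; the protocol states none).

### Triads and key genes

Triads join DEGs (direction up/down), gene-level DMR directions
(non-mixed), and DER-target pairs; a gene targeted by several DERs yields
several triads. The classifier is a pure function on the 2 x 2 x 2
direction space: `fully_negative` for the two patterns above,
`meth_negative_only` / `mirna_negative_only` when only one regulator
anti-correlates, `non_negative` otherwise — every tuple receives exactly
one label, and the labelling is invariant to flipping all three directions
(condition swap). "Negatively correlated" is implemented as this direction
logic, not a numeric correlation: with one methylome per condition a
coefficient is undefined. The key-gene table deduplicates to one row per
(gene, miRNA) with DMR locations concatenated and flags fully-negative rows.

### Enrichment

Gene sets are tested per term with the upper-tail hypergeometric
probability `P(X >= k)` for `k` hits among `n` set genes drawn from `N`
background genes of which `K` carry the term, Bonferroni-corrected over the
tested terms. Terms with zero hits are not tested and do not enter the
Bonferroni denominator (our choice; the protocol is silent). The background
defaults to all genes in the term map and is overridable.

## The synthetic-data generator

`simulate_study()` produces every pipeline input with known ground truth.
What it emulates, and the reference conditions:

* **Genome**: 2 chromosomes x 1 Mb; 200 non-overlapping gene models with
  1–5 exons and >= 2 kb intergenic margin; 50 intergenic miRNA loci of
  120 bp; cytosine sites at per-position densities CG 0.02 / CHG 0.02 /
  CHH 0.04 with random strands.
* **Methylome**: one pooled sample per condition. Coverage is
  Poisson(40) truncated at 1; methylated counts are beta-binomial around
  per-context baselines 0.65 / 0.35 / 0.10 (CG/CHG/CHH) with concentration
  1000. The mild overdispersion reflects that each condition's library is a
  pool of two biological replicates, which averages out between-replicate
  variance; it also keeps the pooled-count Fisher test near its nominal
  size, which is the regime the single-methylome design assumes.
* **Planted DMRs**: twenty intergenic 2 kb regions (alternating
  hyper/hypo) plus one promoter DMR per planted triad, all with a 0.40
  level shift in the treatment sample. The shift applies per context only
  where the shifted mean stays in [0, 1] — with the default baselines hypo
  regions are expressed in CG (0.65 to 0.25) and hyper regions in CHG
  (0.35 to 0.75). CHH is excluded from planting: a 0.40 shift on a 0.10
  baseline is outside the range plant CHH methylation shows. Planted
  intervals sit on a 500 bp lattice matching the caller's step, so that
  truth boundaries are representable by the sliding-window caller; a
  planted region straddling the lattice would make every caller "overhang"
  the truth at the edges by construction.
* **Expression**: negative-binomial counts in 3 + 3 replicates, library
  sizes jittered ±20% (so CPM normalisation is actually exercised),
  dispersion 0.01 — replicate libraries derive from a shared microspore
  pool per condition, so near-technical variability. Background feature
  means are log-uniform on [10, 1e4]; planted DE features (|log2FC| = 2)
  draw means from [100, 1000], i.e. they are detectable and do not dominate
  library composition — under plain CPM (TMM is out of scope) a single
  highly-expressed shifted feature would otherwise move every other
  feature's normalised value.
* **Triads**: five fully-negative triads (alternating the two mirror
  patterns) and five distractors with exactly one direction flipped, as
  classifier-specificity probes. Triad genes are chosen non-adjacent so
  planted promoter DMRs stay disjoint; decoy target pairs avoid triad
  genes so no unplanted triad can arise by construction.

Everything is deterministic given the seed; each generator stage draws from
its own seed offset so stages are individually reproducible.

What the generator does **not** emulate: genome sequence composition,
read-level artefacts (mapping, duplication, conversion errors), strand
asymmetries, correlated site-to-site methylation, isoform structure, and
library composition extremes. Passing recovery tests therefore demonstrates
the pipeline's statistical machinery and bookkeeping, not robustness to
those real-data phenomena.

## Numerical choices and degenerate inputs

* Fisher p-values use the point-probability criterion with the same
  relative tolerance (`1 + 1e-7`) as `stats::fisher.test`; a full-support
  sum can land at `1 - 1e-13`, so tests compare with tolerance.
* Fold change floors the denominator level at 0.005 and flags floored
  records.
* Windows with zero covered cytosines in either sample are dropped before
  testing; an empty window set warns rather than errors.
* All internal coordinates are 0-based half-open; the cytosine report and
  GFF3 readers/writers convert at the boundary, BED is passed through
  unchanged. The BED score is `-log10(q)` capped at 300.
* Empty inputs (empty report, zero genes, empty DEG table) produce empty,
  schema-correct outputs; invalid counts (meth > total), out-of-span exons,
  unknown contexts and zero library totals are errors that name the
  offender.
* Validation sizes: calibration and recovery tests run on 1–2 Mb genomes
  with ~80k cytosines per chromosome and 10 seeds, chosen so the full suite
  exercises every stage at meaningful statistical resolution.

## Known limitations

* With one pooled methylome per condition, between-replicate biological
  variance is invisible to the DMR test; p-values are calibrated for the
  pooled design only.
* The Welch-t stand-in for mRNA DE is a convenience for synthetic runs;
  real analyses should supply an edgeR/DESeq2 table and use the threshold
  path.
* A 3 + 3 Welch t-test has 4 degrees of freedom; FDR-significant calls at
  moderate effect sizes require the low dispersion of near-technical
  replicates or larger families of true effects.
* The promoter thirds, association flank, mC threshold and merged-q rule
  are conventions the underlying protocol leaves unstated; all are
  configurable where that matters.
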