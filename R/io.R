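#' Read a per-cytosine methylation report
#'
#' Reads a Bismark-CX-style 6-column TSV (chrom, 1-based position, strand,
#' context, methylated count, total count; no header) and returns calls in
#' the package's internal 0-based half-open convention.
#'
#' @param path path to a TSV file.
#' @param sample_id identifier attached to every call.
#' @param col_map optional integer vector naming which input columns hold
#'   `chrom, pos, strand, context, meth_count, total_count` (for other report
#'   dialects); defaults to `1:6`.
#' @return a tibble with columns `chrom, pos` (0-based), `strand, context,
#'   meth_count, total_count, sample_id`.
#' @export
read_cytosine_report <- function(path, sample_id,
                                 col_map = c(chrom = 1L, pos = 2L, strand = 3L,
                                             context = 4L, meth_count = 5L,
                                             total_count = 6L)) {
  raw <- readr::read_tsv(
    path,
    col_names = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (nrow(raw) == 0) {
    warn(sprintf("cytosine report '%s' is empty", path))
    return(tibble(
      chrom = character(), pos = integer(), strand = character(),
      context = character(), meth_count = integer(), total_count = integer(),
      sample_id = character()
    ))
  }
  if (ncol(raw) < max(col_map)) {
    validation_error("cytosine report '%s' has %d column(s); %d required",
                     path, ncol(raw), max(col_map))
  }
  calls <- tibble(
    chrom = raw[[col_map[["chrom"]]]],
    pos1 = suppressWarnings(as.integer(raw[[col_map[["pos"]]]])),
    strand = raw[[col_map[["strand"]]]],
    context = raw[[col_map[["context"]]]],
    meth_count = suppressWarnings(as.integer(raw[[col_map[["meth_count"]]]])),
    total_count = suppressWarnings(as.integer(raw[[col_map[["total_count"]]]]))
  )
  bad <- which(is.na(calls$pos1) | is.na(calls$meth_count) |
                 is.na(calls$total_count))
  if (length(bad) > 0) {
    abort(sprintf("cytosine report '%s': malformed line %d", path, bad[1]),
          class = "methtriad_parse_error")
  }
  bad_ctx <- which(!calls$context %in% .contexts)
  if (length(bad_ctx) > 0) {
    validation_error("cytosine report '%s': unknown context '%s' on line %d",
                     path, calls$context[bad_ctx[1]], bad_ctx[1])
  }
  bad_cnt <- which(calls$meth_count < 0 | calls$total_count < 0 |
                     calls$meth_count > calls$total_count)
  if (length(bad_cnt) > 0) {
    validation_error(
      "cytosine report '%s': meth_count > total_count (or negative) on line %d",
      path, bad_cnt[1]
    )
  }
  calls %>%
    mutate(pos = .data$pos1 - 1L, sample_id = sample_id) %>%
    select("chrom", "pos", "strand", "context", "meth_count", "total_count",
           "sample_id")
}

#' Write a per-cytosine methylation report
#'
#' Inverse of [read_cytosine_report()]: emits the 6-column 1-based TSV.
#'
#' @param calls tibble of cytosine calls (internal 0-based `pos`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(calls, path) {
  assert_columns(calls, c("chrom", "pos", "strand", "context", "meth_count",
                          "total_count"), "calls")
  out <- calls %>%
    mutate(pos = .data$pos + 1L) %>%
    select("chrom", "pos", "strand", "context", "meth_count", "total_count")
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Parses `gene` and `exon` features, converts the GFF3 1-based inclusive
#' coordinates to 0-based half-open, sorts exons, and records the TSS
#' (`start` for + genes, `end - 1` for - genes). Genes without a strand are
#' skipped with a warning; an exon outside its gene span is an error.
#'
#' @param path GFF3 file.
#' @return a tibble with columns `gene_id, chrom, start, end, strand, tss,
#'   n_exons, exons`; `exons` is a list-column of tibbles (`start, end`).
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  if (nrow(df) == 0 || !any(df$type == "gene")) {
    return(tibble(
      gene_id = character(), chrom = character(), start = integer(),
      end = integer(), strand = character(), tss = integer(),
      n_exons = integer(), exons = list()
    ))
  }
  ids <- if ("ID" %in% names(df)) df$ID else NA_character_
  parents <- if ("Parent" %in% names(df)) {
    vapply(df$Parent, function(p) if (length(p)) as.character(p[1]) else NA_character_,
           character(1))
  } else rep(NA_character_, nrow(df))
  df <- df %>%
    mutate(
      id = ids, parent = parents,
      chrom = as.character(.data$seqnames),
      start0 = .data$start - 1L, end0 = .data$end,  # to 0-based half-open
      strand = as.character(.data$strand)
    )
  genes <- df %>% filter(.data$type == "gene")
  no_strand <- genes$strand %in% c("*", ".", NA_character_)
  if (any(no_strand)) {
    warn(sprintf("skipping %d gene(s) without strand", sum(no_strand)))
    genes <- genes[!no_strand, ]
  }
  exons <- df %>% filter(.data$type == "exon")
  exon_by_gene <- split(exons, exons$parent)
  out <- genes %>%
    mutate(
      gene_id = .data$id,
      tss = if_else(.data$strand == "+", .data$start0, .data$end0 - 1L)
    )
  exon_list <- lapply(seq_len(nrow(out)), function(i) {
    ex <- exon_by_gene[[out$gene_id[i]]]
    if (is.null(ex) || nrow(ex) == 0) {
      # a gene without annotated exons is treated as single-exon
      return(tibble(start = out$start0[i], end = out$end0[i]))
    }
    if (any(ex$start0 < out$start0[i] | ex$end0 > out$end0[i])) {
      validation_error("gene '%s': exon outside the gene span", out$gene_id[i])
    }
    tibble(start = sort(ex$start0), end = ex$end0[order(ex$start0)])
  })
  tibble(
    gene_id = out$gene_id,
    chrom = out$chrom,
    start = out$start0,
    end = out$end0,
    strand = out$strand,
    tss = out$tss,
    n_exons = vapply(exon_list, nrow, integer(1)),
    exons = exon_list
  ) %>% arrange(.data$chrom, .data$start)
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gff3_genes()] for the fields the package uses.
#'
#' @param genes tibble as returned by [read_gff3_genes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3_genes <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lines <- c(lines, paste(
      g$chrom, "methtriad", "gene", g$start + 1L, g$end, ".", g$strand, ".",
      sprintf("ID=%s", g$gene_id), sep = "\t"
    ))
    ex <- g$exons[[1]]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, paste(
        g$chrom, "methtriad", "exon", ex$start[j] + 1L, ex$end[j], ".",
        g$strand, ".",
        sprintf("ID=%s.exon%d;Parent=%s", g$gene_id, j, g$gene_id), sep = "\t"
      ))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read miRNA precursor loci from a BED file
#'
#' @param path BED file (>= 4 columns; strand taken from column 6 if present).
#' @return a tibble `mirna_id, chrom, start, end, strand` (0-based half-open,
#'   as BED already is).
#' @export
read_mirna_bed <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         comment = "#")
  if (nrow(raw) == 0) {
    return(tibble(mirna_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character()))
  }
  tibble(
    mirna_id = if (ncol(raw) >= 4) raw[[4]] else paste0("mir_", seq_len(nrow(raw))),
    chrom = raw[[1]],
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]]),
    strand = if (ncol(raw) >= 6) raw[[6]] else "*"
  )
}

#' Write intervals (e.g. DMRs) as BED6+
#'
#' Emits BED6 plus `level_a`, `level_b` and `direction` columns for DMR
#' records; the BED score is `-log10(q)` capped at 300. Plain intervals
#' (no `q`) get score 0 and dot placeholders.
#'
#' @param records tibble with `chrom, start, end` and optionally
#'   `direction, level_a, level_b, q, context`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(records, path) {
  assert_columns(records, c("chrom", "start", "end"), "records")
  n <- nrow(records)
  if (n == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  name <- if ("context" %in% names(records)) {
    paste0("dmr_", records$context, "_", seq_len(n))
  } else {
    paste0("region_", seq_len(n))
  }
  score <- if ("q" %in% names(records)) {
    pmin(300, -log10(pmax(records$q, 1e-300)))
  } else rep(0, n)
  score[!is.finite(score)] <- 300
  out <- tibble(
    chrom = records$chrom,
    start = records$start,
    end = records$end,
    name = name,
    score = signif(score, 6),
    strand = if ("strand" %in% names(records)) records$strand else ".",
    level_a = if ("level_a" %in% names(records)) signif(records$level_a, 6) else ".",
    level_b = if ("level_b" %in% names(records)) signif(records$level_b, 6) else ".",
    direction = if ("direction" %in% names(records)) records$direction else "."
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a BED6+3 DMR file written by [write_bed()]
#'
#' @param path BED6+3 file.
#' @return tibble `chrom, start, end, name, score, strand, level_a, level_b,
#'   direction`.
#' @export
read_bed <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (nrow(raw) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = numeric(), strand = character(),
                  level_a = numeric(), level_b = numeric(),
                  direction = character()))
  }
  tibble(
    chrom = raw[[1]], start = as.integer(raw[[2]]), end = as.integer(raw[[3]]),
    name = raw[[4]], score = as.numeric(raw[[5]]), strand = raw[[6]],
    level_a = suppressWarnings(as.numeric(raw[[7]])),
    level_b = suppressWarnings(as.numeric(raw[[8]])),
    direction = raw[[9]]
  )
}

#' Read a count matrix TSV
#'
#' First column is the feature identifier; remaining columns are replicate
#' libraries.
#'
#' @param path TSV with a header row.
#' @return numeric matrix, features x samples.
#' @export
read_count_matrix <- function(path) {
  df <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write a count matrix TSV
#'
#' @param counts matrix with feature rownames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  df <- as_tibble(counts, rownames = "feature_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a two-column gene-to-term map
#'
#' @param path TSV with header columns `gene` and `term` (order-insensitive).
#' @return tibble `gene, term`.
#' @export
read_term_map <- function(path) {
  df <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  assert_columns(df, c("gene", "term"), "term map")
  df %>% select("gene", "term")
}

#' Read miRNA-to-target pairs
#'
#' @param path TSV with header columns `mirna_id` and `gene_id`.
#' @return tibble `mirna_id, gene_id`.
#' @export
read_target_pairs <- function(path) {
  df <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  assert_columns(df, c("mirna_id", "gene_id"), "target pairs")
  df %>% select("mirna_id", "gene_id")
}
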