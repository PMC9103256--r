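#' Tile a genome into sliding windows
#'
#' Windows start at every multiple of `step_size` below the chromosome
#' length; the final windows are truncated at the chromosome end.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param window_size,step_size window width and step in bp
#'   (`window_size >= step_size > 0`).
#' @return tibble `chrom, start, end` (0-based half-open).
#' @export
tile_windows <- function(chrom_lengths, window_size = 1000L, step_size = 500L) {
  if (!(window_size >= step_size && step_size > 0)) {
    config_error("window_size must be >= step_size > 0")
  }
  purrr::imap_dfr(as.list(chrom_lengths), function(len, chrom) {
    starts <- seq(0L, len - 1L, by = step_size)
    tibble(chrom = chrom, start = as.integer(starts),
           end = as.integer(pmin(starts + window_size, len)))
  })
}

# Pool per-window counts for one sample's calls: each site contributes to
# every window covering it. Returns tibble chrom, start, meth, total.
pool_window_counts <- function(calls, window_size, step_size, chrom_lengths) {
  if (nrow(calls) == 0) {
    return(tibble(chrom = character(), start = integer(),
                  meth = numeric(), total = numeric()))
  }
  # window start indices covering position p: k in [floor((p - w)/s) + 1, floor(p/s)]
  kmax <- calls$pos %/% step_size
  kmin <- pmax(0L, (calls$pos - window_size) %/% step_size + 1L)
  reps <- kmax - kmin + 1L
  idx <- rep.int(seq_len(nrow(calls)), reps)
  k <- sequence(reps, from = kmin, by = 1L)
  tibble(
    chrom = calls$chrom[idx],
    start = as.integer(k * step_size),
    meth = calls$meth_count[idx],
    total = calls$total_count[idx]
  ) %>%
    filter(.data$start < chrom_lengths[.data$chrom]) %>%
    group_by(.data$chrom, .data$start) %>%
    summarise(meth = sum(.data$meth), total = sum(.data$total),
              .groups = "drop")
}

#' Sliding-window differential-methylation test
#'
#' Pools methylated/total read counts over all cytosines of the requested
#' context in each window (both strands), tests each window's 2x2 table
#' (meth, unmeth) x (sample A, sample B) with [fisher_2x2()], and adjusts
#' p-values by Benjamini-Hochberg within the context. Windows with zero
#' covered cytosines in either sample are dropped.
#'
#' @param calls_a,calls_b cytosine-call tibbles (treatment, control).
#' @param context one of `"CG", "CHG", "CHH"` or `"combined"` (all contexts
#'   pooled).
#' @param config a [pipeline_config()].
#' @param chrom_lengths named vector of chromosome lengths; inferred from the
#'   calls when `NULL`.
#' @return tibble `chrom, start, end, context, meth_a, total_a, meth_b,
#'   total_b, level_a, level_b, p, q`.
#' @export
window_test <- function(calls_a, calls_b, context = "CG",
                        config = pipeline_config(), chrom_lengths = NULL) {
  stopifnot(context %in% c(.contexts, "combined"))
  if (is.null(chrom_lengths)) {
    chrom_lengths <- infer_chrom_lengths(bind_rows(calls_a, calls_b))
  }
  sel <- function(calls) {
    if (context == "combined") calls else filter(calls, .data$context == !!context)
  }
  wa <- pool_window_counts(sel(calls_a), config$window_size, config$step_size,
                           chrom_lengths)
  wb <- pool_window_counts(sel(calls_b), config$window_size, config$step_size,
                           chrom_lengths)
  stats <- inner_join(wa, wb, by = c("chrom", "start"),
                      suffix = c("_a", "_b")) %>%
    filter(.data$total_a > 0, .data$total_b > 0)
  if (nrow(stats) == 0) {
    warn(sprintf("no windows with coverage in both samples (context %s)", context))
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  context = character(), meth_a = numeric(), total_a = numeric(),
                  meth_b = numeric(), total_b = numeric(), level_a = numeric(),
                  level_b = numeric(), p = numeric(), q = numeric()))
  }
  stats %>%
    mutate(
      end = as.integer(pmin(.data$start + config$window_size,
                            chrom_lengths[.data$chrom])),
      context = !!context,
      level_a = .data$meth_a / .data$total_a,
      level_b = .data$meth_b / .data$total_b,
      p = fisher_2x2(.data$meth_a, .data$total_a - .data$meth_a,
                     .data$meth_b, .data$total_b - .data$meth_b),
      q = bh_adjust(.data$p)
    ) %>%
    select("chrom", "start", "end", "context", "meth_a", "total_a",
           "meth_b", "total_b", "level_a", "level_b", "p", "q") %>%
    arrange(.data$chrom, .data$start)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (delegates to `stats::p.adjust(method = "BH")`).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values of the same length.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric())
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    validation_error("bh_adjust: p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

# fold change with a floor on the denominator level to avoid division by zero
fold_change <- function(level_a, level_b, floor = 0.005) {
  level_a / pmax(level_b, floor)
}

#' Filter tested windows and merge them into DMRs
#'
#' Keeps windows that pass all of: `p < alpha_p`, `q < alpha_q`, pooled read
#' total `>= min_window_coverage` in each sample, `|delta| > min_level_diff`
#' percentage points, and methylation fold change `> fc_bounds[1]` or
#' `< fc_bounds[2]` (denominator level floored at 0.005; floored records are
#' flagged). Overlapping or book-ended surviving windows of the same
#' direction and context are merged; merged counts are re-pooled over the
#' *distinct* cytosines of the merged span (no double counting across
#' overlapping windows) and the Fisher p recomputed on the merged table. The
#' merged q is the minimum member-window q (the BH family is the window set).
#'
#' @param stats window table from [window_test()].
#' @param config a [pipeline_config()].
#' @param calls_a,calls_b the cytosine calls, used to re-pool merged counts.
#' @return tibble of DMR records: `chrom, start, end, context, meth_a,
#'   total_a, meth_b, total_b, level_a, level_b, delta` (percentage points),
#'   `fold_change, fc_floored, direction, p, q, n_merged_windows`.
#' @export
filter_and_merge <- function(stats, config, calls_a, calls_b) {
  empty <- tibble(
    chrom = character(), start = integer(), end = integer(),
    context = character(), meth_a = numeric(), total_a = numeric(),
    meth_b = numeric(), total_b = numeric(), level_a = numeric(),
    level_b = numeric(), delta = numeric(), fold_change = numeric(),
    fc_floored = logical(), direction = character(), p = numeric(),
    q = numeric(), n_merged_windows = integer()
  )
  if (nrow(stats) == 0) return(empty)
  kept <- stats %>%
    mutate(
      delta = (.data$level_a - .data$level_b) * 100,
      fc = fold_change(.data$level_a, .data$level_b),
      direction = if_else(.data$delta > 0, "hyper", "hypo")
    ) %>%
    filter(
      .data$p < config$alpha_p,
      .data$q < config$alpha_q,
      .data$total_a >= config$min_window_coverage,
      .data$total_b >= config$min_window_coverage,
      abs(.data$delta) > config$min_level_diff,
      .data$fc > config$fc_bounds[1] | .data$fc < config$fc_bounds[2]
    )
  if (nrow(kept) == 0) return(empty)
  kept <- kept %>%
    arrange(.data$context, .data$direction, .data$chrom, .data$start) %>%
    group_by(.data$context, .data$direction, .data$chrom) %>%
    mutate(
      new_run = .data$start > dplyr::lag(cummax(.data$end),
                                         default = -1L),
      run = cumsum(.data$new_run)
    ) %>%
    group_by(.data$context, .data$direction, .data$chrom, .data$run)
  merged <- kept %>%
    summarise(
      start = min(.data$start), end = max(.data$end),
      q = min(.data$q), n_merged_windows = n(), .groups = "drop"
    )
  # re-pool counts over distinct cytosines of each merged span
  pool_span <- function(calls, m) {
    ctx_calls <- if (m$context == "combined") calls else
      filter(calls, .data$context == m$context)
    span <- ctx_calls %>%
      filter(.data$chrom == m$chrom, .data$pos >= m$start, .data$pos < m$end)
    c(meth = sum(span$meth_count), total = sum(span$total_count))
  }
  rows <- lapply(seq_len(nrow(merged)), function(i) {
    m <- merged[i, ]
    ca <- pool_span(calls_a, m)
    cb <- pool_span(calls_b, m)
    level_a <- ca[["meth"]] / ca[["total"]]
    level_b <- cb[["meth"]] / cb[["total"]]
    tibble(
      chrom = m$chrom, start = m$start, end = m$end, context = m$context,
      meth_a = ca[["meth"]], total_a = ca[["total"]],
      meth_b = cb[["meth"]], total_b = cb[["total"]],
      level_a = level_a, level_b = level_b,
      delta = (level_a - level_b) * 100,
      fold_change = fold_change(level_a, level_b),
      fc_floored = level_b < 0.005,
      direction = m$direction,
      p = fisher_2x2(ca[["meth"]], ca[["total"]] - ca[["meth"]],
                     cb[["meth"]], cb[["total"]] - cb[["meth"]]),
      q = m$q,
      n_merged_windows = m$n_merged_windows
    )
  })
  bind_rows(rows) %>% arrange(.data$chrom, .data$start, .data$context)
}

#' Call differentially methylated regions
#'
#' End-to-end DMR calling: tiles the genome, tests windows per context,
#' filters on significance/coverage/level-difference/fold-change and merges
#' surviving windows ([filter_and_merge()]).
#'
#' @param calls_a,calls_b cytosine-call tibbles (treatment, control).
#' @param config a [pipeline_config()].
#' @param contexts contexts to call; any of `"CG", "CHG", "CHH", "combined"`.
#' @param chrom_lengths named vector; inferred from the calls when `NULL`.
#' @return an object of class `dmr_result` with elements `windows` (all
#'   tested windows), `dmrs` (the called regions) and `config`. Use
#'   [generics::tidy()] / [generics::glance()] or `$` to access them.
#' @export
call_dmrs <- function(calls_a, calls_b, config = pipeline_config(),
                      contexts = c("CG", "CHG", "CHH"),
                      chrom_lengths = NULL) {
  if (is.null(chrom_lengths)) {
    chrom_lengths <- infer_chrom_lengths(bind_rows(calls_a, calls_b))
  }
  windows <- purrr::map_dfr(contexts, function(ctx) {
    window_test(calls_a, calls_b, ctx, config, chrom_lengths)
  })
  dmrs <- filter_and_merge(windows, config, calls_a, calls_b)
  structure(
    list(windows = windows, dmrs = dmrs, config = config,
         n_in = c(a = nrow(calls_a), b = nrow(calls_b))),
    class = "dmr_result"
  )
}

infer_chrom_lengths <- function(calls) {
  lens <- calls %>%
    group_by(.data$chrom) %>%
    summarise(len = max(.data$pos) + 1L, .groups = "drop")
  setNames(lens$len, lens$chrom)
}

#' @export
print.dmr_result <- function(x, ...) {
  cat(sprintf(
    "<dmr_result> %d windows tested, %d DMRs (%d hyper, %d hypo)\n",
    nrow(x$windows), nrow(x$dmrs),
    sum(x$dmrs$direction == "hyper"), sum(x$dmrs$direction == "hypo")
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a DMR result
#'
#' @param x a `dmr_result`.
#' @param ... unused.
#' @return the DMR tibble (one row per called region).
#' @export
tidy.dmr_result <- function(x, ...) x$dmrs

#' One-row summary of a DMR result
#'
#' @param x a `dmr_result`.
#' @param ... unused.
#' @return tibble with window/DMR counts and the median absolute level
#'   difference of the called regions.
#' @export
glance.dmr_result <- function(x, ...) {
  tibble(
    n_windows_tested = nrow(x$windows),
    n_dmrs = nrow(x$dmrs),
    n_hyper = sum(x$dmrs$direction == "hyper"),
    n_hypo = sum(x$dmrs$direction == "hypo"),
    median_abs_delta = stats::median(abs(x$dmrs$delta)),
    dmr_bases = if (nrow(x$dmrs)) sum(x$dmrs$end - x$dmrs$start) else 0L
  )
}
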