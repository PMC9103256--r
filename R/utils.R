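#' Beta-binomial random deviates
#'
#' Draws overdispersed binomial counts: the per-draw success probability is
#' Beta(mu * conc, (1 - mu) * conc), so `conc` (the concentration) controls
#' overdispersion. As `conc -> Inf` the draws approach Binomial(size, mu);
#' the variance is `size * mu * (1 - mu) * (1 + (size - 1) / (conc + 1))`.
#'
#' @param n number of deviates.
#' @param size number of trials per deviate (vectorised).
#' @param mu mean success probability in `[0, 1]` (vectorised).
#' @param conc concentration (inverse-overdispersion), `> 0`.
#' @return integer vector of length `n`.
#' @export
rbetabinom <- function(n, size, mu, conc) {
  stopifnot(conc > 0, all(mu >= 0), all(mu <= 1))
  mu <- rep_len(mu, n)
  size <- rep_len(size, n)
  p <- numeric(n)
  fixed <- mu <= 0 | mu >= 1  # degenerate beta
  p[fixed] <- mu[fixed]
  if (any(!fixed)) {
    p[!fixed] <- rbeta(sum(!fixed), mu[!fixed] * conc, (1 - mu[!fixed]) * conc)
  }
  rbinom(n, size, p)
}

# Stage-specific seed so each simulate_* call is individually deterministic
# while a full simulate_study() run never reuses a stream.
stage_seed <- function(seed, stage) {
  offsets <- c(
    genome = 11L, methylation = 23L, counts_mrna = 37L,
    counts_mirna = 41L, plant = 53L, extra = 67L
  )
  as.integer((seed + offsets[[stage]]) %% .Machine$integer.max)
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ), class = "methtriad_schema_error")
  }
  invisible(df)
}

config_error <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "methtriad_config_error")
}

validation_error <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "methtriad_validation_error")
}
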