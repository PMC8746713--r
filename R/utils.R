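# internal helpers: structured errors and reproducible sub-seeding

abort_exhet <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("exhet_", class), "exhet_error"), ...)
}

warn_exhet <- function(message, class) {
  rlang::warn(message, class = c(paste0("exhet_", class), "exhet_warning"))
}

#' Derive a deterministic sub-seed from a base seed and structural indices
#'
#' Stochastic operations that are called repeatedly with different structural
#' indices (dataset, family, replicate) each receive their own RNG stream,
#' derived from the base seed by integer mixing. Results are reproducible for
#' a fixed `(seed, indices)` and independent of call order.
#'
#' @param seed Integer base seed.
#' @param ... Non-negative integer indices.
#' @return An integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
mix_seed <- function(seed, ...) {
  idx <- c(...)
  v <- as.numeric(seed) %% 2147483647
  for (i in idx) {
    v <- (v * 69069 + as.numeric(i) + 1) %% 2147483647
  }
  as.integer(v)
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

is_prob <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
}

# analysis variable of a summary table: the chosen `response` when present,
# otherwise excess heterozygosity
response_of <- function(df) {
  if ("response" %in% names(df)) df[["response"]] else df[["excess_het"]]
}

has_col <- function(df, nm) nm %in% names(df)

recombinant_generations <- c("F2", "F3")
all_generations <- c("F0A", "F0B", "F1", "F2", "F3")
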