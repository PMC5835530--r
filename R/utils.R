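# Internal helpers: classed error conditions, seed handling, small numerics.

# Classed conditions so callers (and the CLI wrapper) can map failures to
# exit codes: config errors, data errors, degenerate-statistics errors.
ppn_stop <- function(msg, class = "ppn_error", call. = FALSE) {
  stop(structure(
    class = c(class, "ppn_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

ppn_config_error <- function(msg) ppn_stop(msg, "ppn_config_error")
ppn_data_error <- function(msg) ppn_stop(msg, "ppn_data_error")
ppn_degenerate_error <- function(msg) ppn_stop(msg, "ppn_degenerate_error")

# Derive a child RNG seed from a base seed and an index, staying inside the
# 32-bit integer range R requires for set.seed().
derive_seed <- function(base_seed, index) {
  as.integer((as.double(base_seed) * 48271 + index * 99991) %% 2147483647L)
}

# Run fn() under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards.
with_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  fn()
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Column-standardize to zero mean, unit sd (sd with n-1 denominator).
standardize <- function(x) {
  x <- as.matrix(x)
  x <- sweep(x, 2L, colMeans(x), "-")
  s <- sqrt(colSums(x^2) / (nrow(x) - 1L))
  s[s == 0] <- 1
  sweep(x, 2L, s, "/")
}
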