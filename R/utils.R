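# Internal helpers.

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible sub-seed below 2^31 from a base seed and an offset.
.sub_seed <- function(seed, k) {
  (as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647
}

# Largest-remainder apportionment of `round(frac * sum(n))` across strata of
# sizes `n`: floor each stratum's quota, then hand out the remaining units in
# order of decreasing fractional part (ties to earlier strata).
.stratified_counts <- function(n, frac) {
  total <- round(frac * sum(n))
  quota <- frac * n
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(quota - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  } else if (rem < 0) {
    ord <- order(quota - base)
    take <- ord[base[ord] > 0][seq_len(-rem)]
    base[take] <- base[take] - 1
  }
  as.integer(base)
}
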