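# Internal helpers: deterministic seed fan-out and small numeric utilities.

# Derive a reproducible sub-seed from a base seed and a named stream plus
# optional integer coordinates (epoch, batch, ...). Keeps results < 2^31 so
# they are valid R integer seeds. Streams are separated so that, e.g.,
# toggling dropout does not shift the initialization randomness.
derive_seed <- function(seed, stream, ...) {
  codes <- c(init = 1L, dropout = 2L, shuffle = 3L, data = 4L,
             mask = 5L, feedback = 6L, bp_init = 7L, other = 8L)
  s <- codes[[stream]]
  extra <- c(...)
  h <- (as.double(seed) %% 2147483647) * 48271
  h <- (h + s * 104729) %% 2147483647
  for (e in extra) h <- (h * 69621 + as.double(e) + 1) %% 2147483647
  as.integer(h %% 2147483629 + 1)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

# Pearson correlation with the convention that degenerate (constant or empty)
# inputs give 0 rather than NA.
safe_cor <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  if (length(a) < 2L || stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Memo store for geometry-dependent index tables (im2col gathers, pooling
# windows). Keys encode every dimension they depend on; values are integer
# index vectors, so cached entries are modest.
.hn_cache <- new.env(parent = emptyenv())

cache_get <- function(key, compute) {
  v <- .hn_cache[[key]]
  if (is.null(v)) {
    v <- compute()
    .hn_cache[[key]] <- v
  }
  v
}
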