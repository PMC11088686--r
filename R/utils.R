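# Internal helpers shared across modules.

# Deterministic child seeds: every exported operation that consumes
# randomness takes an explicit `seed` and derives independent sub-seeds from
# it, so a single pipeline seed reproduces every stage byte-for-byte.
# Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, offset) {
  s <- (abs(as.numeric(seed)) %% 1e6) * 1009 + abs(as.numeric(offset)) * 9176
  as.integer(s %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
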