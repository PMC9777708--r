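# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library code never disturbs user RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic substream derivation: one user-facing seed expands into
# per-stage seeds so stages can be re-run independently. Kept below 2^31.
derive_seed <- function(seed, offset) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(offset) * 2654435761
  as.integer(s %% 2147483629) + 1L
}

# FNV-1a hash of a deparsed object, used to stamp output files with the
# configuration that produced them.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ";"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (as.double(h) * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

geometric_mean <- function(x) exp(mean(log(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
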