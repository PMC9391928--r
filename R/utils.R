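#' @keywords internal
"_PACKAGE"

# formatted stop without call noise
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  All stochastic entry points in the
# package route their randomness through this so that a master seed fully
# determines every output without clobbering user RNG state.
with_seed <- function(seed, expr) {
  if (!is_count(seed)) stopf("seed must be a single non-negative integer")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# derive a stage seed from a master seed; keeps results < 2^31
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 1000003 + offset) %% 2147483647)
}
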