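# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.  All simulator entry points route through this
# so that a fixture is a pure function of (scenario, seed).
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# Derive a per-operation sub-seed from a master seed.  Keeps results of one
# stage invariant to how many draws another stage consumed.  The modulus
# keeps the value a valid 32-bit integer seed.
sub_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(stream)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
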