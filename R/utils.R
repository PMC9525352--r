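`%||%` <- function(x, y) if (is.null(x)) y else x

## Run `expr` under a fixed seed without disturbing the caller's RNG stream.
## All randomized operations in the package take explicit seeds; there is no
## hidden global random state.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
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

## Derive a stream-specific child seed from a master seed; keeps results
## decoupled between pipeline stages while remaining reproducible.
childSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483629) + 1L
}

stopIfNot <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

isScalarNumber <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
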