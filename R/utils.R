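#' @keywords internal
"_PACKAGE"

## Run code under a temporary RNG state so stochastic operations take an
## explicit seed without clobbering the caller's stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

## Derive a stream seed from a base seed; keeps results inside 32-bit range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(offset)) %% 2147483629)
}

## Fast data.frame constructor (skips checks; inputs are internally validated).
quick_df <- function(lst) {
  n <- if (length(lst)) length(lst[[1L]]) else 0L
  structure(lst, class = "data.frame", row.names = seq_len(n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
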