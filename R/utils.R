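#' @keywords internal
"_PACKAGE"

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stream-specific seed from a master seed
#'
#' All stochastic steps in the pipeline draw their seed deterministically
#' from one master seed so that a single integer reproduces a whole run.
#' The derivation is `(master * 2654435761 + stream index) mod (2^31 - 1)`,
#' a Knuth-style multiplicative hash kept inside the 32-bit integer range.
#'
#' @param master integer master seed.
#' @param stream small nonnegative integer identifying the consumer
#'   (1 = roster, 2 = pretraining log, 3 = diffusions, 4 = permutation
#'   tests, 5+ = replicate loops).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stream = 1L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.numeric(stream), stream >= 0)
  m <- 2147483647
  s <- (abs(master) %% m) * (2654435761 %% m) + stream + 1
  as.integer(s %% m + (s %% m == 0))
}

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

## Minimal FNV-1a hash of a deparsed object, for run manifests.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
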