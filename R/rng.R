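## Deterministic seed derivation: every stochastic piece of the simulator
## draws from its own substream keyed by (session seed, stream tag, ids), so
## adding units or channels never perturbs already-generated trials.

#' Derive a substream seed from a tuple of integers
#'
#' Small multiplicative hash over the tuple, kept inside 32-bit integer
#' range. Used to key per-(unit, trial) RNG substreams.
#'
#' @param ... Integer components (a string tag is hashed by character codes).
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
mix_seed <- function(...) {
  parts <- list(...)
  m <- 2147483647
  h <- 104729
  for (p in parts) {
    if (is.character(p)) p <- utf8ToInt(p)
    for (x in as.numeric(p)) {
      h <- (h * 69069 + x + 1) %% m
      h <- (h * 3467 + 40503) %% m
    }
  }
  as.integer(h %% (m - 2) + 1)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
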