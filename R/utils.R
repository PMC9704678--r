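# Seed plumbing: every stochastic operation derives a named sub-seed from
# the master seed so that stages are reproducible independently of call
# order, and runs under a locally-scoped RNG state.

#' Derive a deterministic sub-seed from a master seed and a stream name
#'
#' @param seed master integer seed.
#' @param stream character stream label (e.g. `"ale_null"`).
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
sub_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream))) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 69069 + h) %% 2147483647)
}

# run code under a given seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
  invisible(NULL)
}
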