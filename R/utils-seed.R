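# Seeded substreams: every stochastic stage draws from its own named stream
# derived from one root seed, so adding or reordering stages never perturbs
# the randomness of the others.

#' Derive a substream seed from a root seed and a stream name
#'
#' Hashes the stream name and combines it with the root seed modulo
#' \eqn{2^{31} - 1}, yielding an integer seed that is stable across platforms
#' and R sessions. Distinct names give (for practical purposes) independent
#' streams.
#'
#' @param seed Integer root seed.
#' @param name Character stream name, e.g. `"plots"` or `"simex"`.
#' @return A single integer usable with [set.seed()].
#' @export
#' @examples
#' stream_seed(42, "plots")
stream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  m <- 2147483647 # 2^31 - 1, keeps everything in exact double range
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% m
  as.integer((abs(seed) %% m * 48271 + h) %% m)
}

# Run `expr` under `seed` and restore the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}
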