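# Seed plumbing shared across modules.

# Evaluate expr with a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Derive a named sub-seed from a global seed
#'
#' Components that consume randomness (initialization, permutations,
#' bootstraps, K-means restarts) draw their seeds from one global seed via
#' a named substream, so runs are reproducible component by component
#' without seed collisions.
#'
#' @param seed integer global seed.
#' @param tag character name of the substream.
#' @param index optional integer (e.g. a loop index) folded in.
#' @return an integer seed in [0, 2^31).
#' @export
substream_seed <- function(seed, tag, index = 0L) {
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% 2147483647
  as.integer((h + as.numeric(seed) * 7919 + as.numeric(index) * 104729) %%
               2147483647)
}
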