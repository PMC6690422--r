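# Named RNG substreams: every stochastic component draws from a seed derived
# from (master seed, stream name), so adding a new variable to the generator
# never perturbs the draws of existing ones.

substream_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(name))
  h <- 0
  for (cp in utf8ToInt(name)) h <- (h * 31 + cp) %% 1000003
  as.integer((abs(as.numeric(master)) * 7919 + h) %% 2147483647)
}

# Evaluate `expr` under the substream's seed, restoring the caller's RNG
# state afterwards so substreams never interact with ambient randomness.
with_substream <- function(master, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(master, name))
  expr
}
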