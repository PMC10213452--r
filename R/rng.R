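# Deterministic per-operation RNG streams.
#
# Each simulator operation draws from its own stream seeded from
# (seed, operation tag), so re-running one stage reproduces its output
# without replaying the whole pipeline. The tag hash is a small fixed
# polynomial over the tag's bytes; results stay below 2^31 - 1.

tag_seed <- function(seed, tag) {
  b <- utf8ToInt(tag)
  h <- 0
  for (x in b) h <- (h * 131 + x) %% 2147483647
  as.integer((as.numeric(seed) %% 2146483647 * 1000 + h) %% 2147483647)
}

with_op_seed <- function(seed, tag, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(tag_seed(seed, tag))
  code
}
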