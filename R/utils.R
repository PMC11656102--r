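# Evaluate `expr` under a given seed without disturbing the caller's RNG
# state.
local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic stream splitting: a child seed from (parent seed, key),
# kept inside the 32-bit integer range.
derive_seed <- function(seed, key) {
  key_num <- if (is.character(key)) sum(utf8ToInt(key)) else as.numeric(key)
  as.integer((as.numeric(seed) * 48271 + key_num * 16807) %% 2147483647)
}
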