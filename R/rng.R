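# Self-contained RNG stream: deterministic given `seed`, leaves the
# caller's global RNG state untouched.
local_rng <- function(seed) {
  grab <- function() get0(".Random.seed", globalenv(), inherits = FALSE)
  put <- function(s) {
    if (is.null(s)) {
      if (!is.null(grab())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", s, envir = globalenv())
  }
  outer_state <- grab()
  set.seed(seed)
  state <- grab()
  put(outer_state)
  draw <- function(f) {
    outer <- grab()
    put(state)
    r <- f()
    state <<- grab()
    put(outer)
    r
  }
  list(
    runif = function(n, min = 0, max = 1)
      draw(function() stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1)
      draw(function() stats::rnorm(n, mean, sd)),
    sample_int = function(n, size, replace = FALSE)
      draw(function() sample.int(n, size, replace = replace)),
    derive = function(offset) draw(function() sample.int(2^30, 1)) + offset
  )
}
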