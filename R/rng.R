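# Private RNG streams. Generator functions take an explicit stream object
# seeded once, so package output is reproducible from its seeds and the
# caller's .Random.seed is left untouched.

make_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$seed <- as.integer(seed)
  env$state <- NULL
  env
}

with_rng <- function(rng, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  if (is.null(rng$state)) {
    set.seed(rng$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  } else {
    assign(".Random.seed", rng$state, envir = globalenv())
  }
  val <- fn()
  rng$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  val
}

norm_rng <- function(rng, n) with_rng(rng, function() stats::rnorm(n))
unif_rng <- function(rng, n) with_rng(rng, function() stats::runif(n))
sample_rng <- function(rng, x, size)
  with_rng(rng, function() sample(x, size))
# a fresh sub-stream seed (kept below 2^31)
int_rng <- function(rng) with_rng(rng, function() sample.int(2147483646L, 1L))
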