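# Deterministic, self-contained randomness. Every stochastic routine in the
# package draws from an rng handle created by make_rng(seed); the handle keeps
# its own .Random.seed state so package randomness neither disturbs nor is
# disturbed by the caller's RNG stream.

make_rng <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max, kind = "Mersenne-Twister")
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  env
}

# run expr under the handle's RNG state, then capture the advanced state
with_rng <- function(rng, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", rng$state, globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  expr
}

rng_sample <- function(rng, x, size = length(x), replace = FALSE) {
  with_rng(rng, sample(x, size = size, replace = replace))
}

rng_unif <- function(rng, n, min = 0, max = 1) {
  with_rng(rng, stats::runif(n, min, max))
}

rng_norm <- function(rng, n, mean = 0, sd = 1) {
  with_rng(rng, stats::rnorm(n, mean, sd))
}

rng_gamma <- function(rng, n, shape) {
  with_rng(rng, stats::rgamma(n, shape = shape, rate = 1))
}

rng_int <- function(rng, n, max) {
  with_rng(rng, sample.int(max, n, replace = TRUE))
}

# derive a child seed (stable, < 2^31) for an independent sub-stream
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(paste0(tag)) * seq_along(utf8ToInt(paste0(tag))))
  (as.integer(seed) %% 1000003L) * 2027L + (h %% 65521L)
}
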