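# RNG scoping: every stochastic operation takes an explicit seed and restores
# the caller's RNG state, so pipeline stages are individually reproducible.

#' Evaluate an expression under a local RNG seed
#'
#' Sets the seed, evaluates \code{expr}, and restores the global RNG state,
#' so seeded helpers do not perturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return Value of \code{expr}.
#' @export
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive independent child seeds from a master seed (31-bit, R-integer safe).
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}
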