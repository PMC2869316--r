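#' Derive a child seed from a master seed
#'
#' All stochastic functions in the package take a single integer `seed`.
#' Multi-stage generators derive independent sub-streams from it with this
#' deterministic hash, so that one user-supplied seed reproduces an entire
#' simulation while the stages stay decoupled.
#'
#' @param seed master seed (non-negative integer below 2^31).
#' @param i stream index (non-negative integer).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, i = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0, seed < 2^31)
  # multiplicative hash mod the Mersenne prime 2^31 - 1; doubles keep exact
  # integer arithmetic well below 2^53 here
  x <- (as.double(seed) %% 2147483647) * 48271 + (as.double(i) + 1) * 337499
  as.integer(x %% 2147483647)
}

# Run `expr` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
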