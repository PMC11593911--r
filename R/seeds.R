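#' Derive a child seed from a master seed and a sequence of tokens
#'
#' Deterministic counter-based seed splitting so that every stochastic stage
#' of a benchmark (panel simulation, sample draw, pruning, error injection)
#' gets an independent, reproducible random stream.  Any design cell can be
#' re-run in isolation by deriving the same child seed.
#'
#' Tokens may be integers or short strings (strings are hashed by character
#' code).  The result is always a positive integer below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param ... tokens identifying the stage, e.g. `"prune"`, cell index,
#'   replicate index.
#' @return a single integer seed.
#' @examples
#' derive_seed(1, "panel")
#' derive_seed(1, "prune", 3, 7)
#' @export
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  m <- 2147483647 # 2^31 - 1 (prime); products stay below 2^53 in doubles
  h <- (abs(as.double(master)) + 11) %% m
  for (tok in list(...)) {
    v <- if (is.character(tok)) {
      sum(utf8ToInt(tok) * seq_along(utf8ToInt(tok))) %% m
    } else {
      abs(as.double(tok)) %% m
    }
    h <- (h * 48271 + v + 1) %% m
  }
  as.integer(h %% (m - 2L) + 1L)
}

# Evaluate `code` under a fixed RNG seed without touching the caller's RNG
# state.  All exported stochastic operations route through this.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
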