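#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate an expression under a temporary RNG state
#'
#' Saves and restores `.Random.seed` so that seeded internals do not
#' perturb the caller's random number stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    set.seed(seed)
  }
  force(expr)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Counter-based scheme: a master seed plus any number of integer keys
#' (stage number, gene index, ...) map to a seed below 2^31, so each
#' gene/stage gets an independent, order-independent stream.
#'
#' @param seed master seed (integer).
#' @param ... integer keys identifying the stage/unit.
#' @return an integer seed in `[1, 2^31 - 1]`.
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (k in as.numeric(c(...))) {
    h <- (h * 69069 + k * 40503 + 12345) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

# Harmonic sums used throughout the SFS statistics.
harmonic_a1 <- function(n) sum(1 / seq_len(n - 1))
harmonic_a2 <- function(n) sum(1 / seq_len(n - 1)^2)

`%||%` <- function(a, b) if (is.null(a)) b else a
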