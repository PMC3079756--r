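#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the
#' previous RNG state, so seeded helpers do not disturb the caller's stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# integer seed derived from a base seed and stream indices, kept < 2^31
derive_seed <- function(base, ...) {
  parts <- c(base, ...)
  s <- 0
  for (p in parts) s <- (s * 7919 + as.double(p)) %% 2147483587
  as.integer(s + 1)
}
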