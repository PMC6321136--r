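# Internal helpers shared across modules.

#' @noRd
stop_ligfish <- function(msg, class = "ligfish_error", ...) {
  stop(structure(
    class = c(class, "ligfish_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

# Evaluate `code` under a local RNG seeded with `seed`, restoring the
# caller's RNG state afterwards. All stochastic entry points route through
# this so the package never perturbs (or depends on) global random state.
#' @noRd
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# round-half-up: round(3.5) in R is banker's rounding, the split protocol
# needs deterministic half-up.
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
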