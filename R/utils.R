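# Internal helpers shared across modules.

# Round half away from zero (the convention used for every printed percent):
# 0.5 -> 1, -0.5 -> -1, unlike base round()'s round-half-even.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Run code under a fixed RNG seed, restoring the caller's RNG state afterwards
# so simulation functions are deterministic without clobbering the session.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_invalid <- function(...) {
  stop(structure(
    class = c("evidemr_invalid_input", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_conflict <- function(...) {
  stop(structure(
    class = c("evidemr_conflict", "evidemr_invalid_input", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
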