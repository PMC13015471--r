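# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so generators are pure given their seed.
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
  set.seed(as.integer(seed))
  force(code)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Blom-type normal scores of a vector; ties broken at random so the scores
# are continuous even when the input is granular.
normal_scores <- function(x) {
  n <- length(x)
  r <- rank(x, ties.method = "random")
  stats::qnorm((r - 0.375) / (n + 0.25))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(..., call. = FALSE)
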