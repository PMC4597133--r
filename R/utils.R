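# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# stream is restored afterwards so seeded helpers never perturb each other.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

# Clamp tiny floating-point excursions outside [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
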