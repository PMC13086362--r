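# internal helpers shared across modules

# wrap a value into [0, period)
`%mod%` <- function(a, b) a - b * floor(a / b)

# derive a reproducible child seed from a parent seed and an index.
# Simple LCG-style fanout; keeps results extensible without reshuffling
# earlier objects when more are generated.
child_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), is.numeric(index))
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483587L) + 1L
}

with_seed <- function(seed, expr) {
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
  force(expr)
}

stop_if_not_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what), call. = FALSE)
  invisible(x)
}

deg <- function(rad) (rad * 180 / pi) %mod% 360
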