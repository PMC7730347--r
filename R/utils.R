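# internal helpers shared across modules

# Horner evaluation of a polynomial with coefficients in descending powers,
# vectorized over (possibly complex) x.
polyval_c <- function(p, x) {
  out <- rep_len(0 + 0i, length(x))
  for (coef in p) out <- out * x + coef
  out
}

db <- function(mag) 20 * log10(mag)

log_grid <- function(from, to, n) exp(seq(log(from), log(to), length.out = n))

stop_invalid <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == round(x)

# evaluate a block with a private RNG stream, restoring global state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.wearcounts_cache <- new.env(parent = emptyenv())
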