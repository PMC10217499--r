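# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# classed errors so callers/tests can branch on condition class
abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "freshir_error")))
}

# run code under a temporary RNG state; the caller's stream is untouched
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# map a wavenumber axis onto [-1, 1] for numerically stable polynomial fits
rescale_axis <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(0, length(x)))
  2 * (x - r[1]) / (r[2] - r[1]) - 1
}
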