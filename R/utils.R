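# Evaluate code under a temporary RNG seed, restoring global RNG state after.
# A NULL seed means "use the ambient RNG stream" (no isolation).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Normal draw truncated below (resampled), keeping generator parameters in
# their physical range.
rnorm_min <- function(n, mean, sd, min) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x < min)) x[x < min] <- stats::rnorm(sum(x < min), mean, sd)
  x
}
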