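#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the random number generator seeded at `seed`, then restores
#' the caller's RNG state, so seeded helpers do not perturb the session stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Counter-based substream: all replicate-level seeds are derived from one
# top-level seed so runs are reproducible replicate-by-replicate. Kept < 2^31.
substream_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 7919 + as.double(counter) * 104729) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bonespectq <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "bonespectq_error")))
}
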