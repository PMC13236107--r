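# Seed plumbing: every source of randomness takes a seed derived from one
# run-level seed, so whole runs are bit-reproducible and package functions
# never disturb the caller's RNG state.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a component seed from a run seed
#'
#' Deterministically mixes a run-level seed with integer tags (component
#' index, split id, ...) into a new 31-bit seed, so that components draw
#' from independent reproducible streams.
#'
#' @param seed Integer run seed.
#' @param ... Integer tags.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  tags <- c(as.integer(seed), vapply(list(...), as.integer, integer(1)))
  h <- 0
  for (t in tags) h <- (h * 69069 + as.numeric(t) + 12345) %% 2147483629
  as.integer(h) + 1L
}
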