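#' Independent reproducible random-number streams
#'
#' A session derives named child streams from one root seed so that, e.g.,
#' training-phase shuffles, selection tie-breaks, and simulated-listener
#' responses each consume an independent, reproducible stream.  Streams hold a
#' private copy of R's RNG state and never disturb the global
#' \code{.Random.seed} of the caller.
#'
#' @param seed integer seed for the stream.
#' @return an environment of class `qbif_rng`.
#' @keywords internal
new_rng_stream <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- new.env(parent = emptyenv())
  old <- .save_global_seed()
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", envir = globalenv())
  .restore_global_seed(old)
  class(env) <- "qbif_rng"
  env
}

#' Evaluate an expression under a stream's RNG state
#'
#' The stream's state is swapped into the global RNG for the duration of
#' `expr`, then the advanced state is stored back in the stream and the
#' caller's RNG state is restored.
#'
#' @param stream a `qbif_rng` stream.
#' @param expr expression to evaluate.
#' @keywords internal
with_stream <- function(stream, expr) {
  old <- .save_global_seed()
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    .restore_global_seed(old)
  })
  expr
}

.save_global_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_global_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Derive a deterministic child seed from a root seed and a stream name
#'
#' Uses a small multiplicative congruential mix entirely in exactly
#' representable doubles; the result is a valid 32-bit integer seed.
#'
#' @param seed root seed (integer).
#' @param name character stream label.
#' @return integer seed.
#' @keywords internal
child_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(as.character(name))) h <- (h * 131 + ch) %% 1014283
  as.integer(((abs(as.numeric(seed)) %% 2147483629) * 48271 + h * 7919 + 1) %%
               2147483629)
}
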