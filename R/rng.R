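# Named, seeded RNG streams.
#
# Every stochastic step in the package draws from its own named stream so
# that, e.g., changing the number of repeats in a simulation does not
# perturb the stimulus features. A stream seed is derived from the user
# seed and the stream name by a small integer hash, kept within 32-bit
# integer range.

#' Derive a deterministic sub-seed from a base seed and a stream name
#'
#' @param seed integer base seed.
#' @param name character scalar naming the stream (e.g. "features").
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
stream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) %% 2147483647 + h) %% 2147483647)
}

#' Evaluate an expression under a named RNG stream
#'
#' Saves and restores the global RNG state, so streams are isolated from
#' each other and from user code.
#'
#' @param seed integer base seed.
#' @param name stream name.
#' @param expr expression to evaluate.
#' @keywords internal
with_stream <- function(seed, name, expr) {
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
  set.seed(stream_seed(seed, name))
  expr
}

# Structured error helper: all package validation failures carry the
# "visens_error" class plus a specific subclass, so callers can test for
# them without string matching.
visens_stop <- function(subclass, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(subclass, "visens_error", "error", "condition")))
}
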