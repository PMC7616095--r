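#' Derive a reproducible child seed from a master seed
#'
#' Hierarchical seeding: every stochastic stage of the pipeline draws its own
#' seed from the master seed plus a path of small integers (session index,
#' unit index, channel, ...), so regenerating one unit does not disturb the
#' stream of any other.
#'
#' @param seed master seed (integer).
#' @param ... integers identifying the substream (e.g. session, unit).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @examples
#' derive_seed(1, 2, 3)
#' @export
derive_seed <- function(seed, ...) {
  path <- c(seed, ...)
  stopifnot(all(is.finite(path)))
  m <- 2147483647 # 2^31 - 1, Mersenne prime; keeps results in integer range
  h <- 0
  for (k in path) {
    # multiplicative mixing in double precision; (h * mult + k) stays exact
    # because intermediate products are < 2^53 after the modulus
    h <- ((h %% 65536) * 40014 + (h %/% 65536) * 12345 + (k %% m) + 7919) %% m
    h <- (h * 69621) %% m
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed`, so library code never clobbers the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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
  expr
}
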