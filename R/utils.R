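#' Evaluate an expression under a local random seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the previous
#' global RNG state afterwards, so that package functions never leak random
#' state into the caller's session.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
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
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(x, y) if (is.null(x)) y else x

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}
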