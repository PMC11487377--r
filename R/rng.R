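# Named random substreams.
#
# One global seed fans out into independent, name-keyed substreams so that
# toggling one randomized stage (augmentation, fold assignment, weight init,
# ...) does not shift the draws of any other stage.

.substream_seed <- function(seed, name) {
  h <- 0
  for (code in utf8ToInt(name)) h <- (h * 31 + code) %% 2147483647
  as.integer((as.numeric(seed) * 7919 + h + 1) %% 2147483647)
}

#' Evaluate an expression under a named random substream
#'
#' Derives a deterministic sub-seed from \code{(seed, name)}, evaluates
#' \code{expr} under it, and restores the caller's RNG state afterwards.
#'
#' @param seed integer master seed.
#' @param name substream label, e.g. \code{"augment"} or \code{"init"}.
#' @param expr expression to evaluate.
#' @return The value of \code{expr}.
#' @examples
#' a <- withSubstream(1, "a", runif(2))
#' b <- withSubstream(1, "a", runif(2))
#' stopifnot(identical(a, b))
#' @export
withSubstream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(.substream_seed(seed, name))
  expr
}
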