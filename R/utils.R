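#' Derive a stage-specific seed from a global seed
#'
#' Sub-seeds are derived by hashing the stage name into an offset, so adding a
#' stage to a pipeline never perturbs the random stream of any other stage.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return an integer seed in `[0, 2^31)`.
#' @export
#' @examples
#' deriveSeed(1L, "splits") != deriveSeed(1L, "mlp")
deriveSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647  # 2^31 - 1, keeps the result a valid 32-bit integer
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% m
  as.integer((abs(seed) + h) %% m)
}

#' Evaluate an expression under a local, seeded RNG state
#'
#' Seeds the random number generator, evaluates `expr`, and restores the
#' caller's RNG state afterwards, so package functions never clobber user
#' randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assertScalarNumber <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be a finite number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}
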