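#' Derive a reproducible sub-stream seed from a master seed and a stage name
#'
#' Every stochastic stage of the pipeline draws its own seed from the single
#' master seed and a stage label, so that adding or reordering stages does not
#' shift the random streams of the others.
#'
#' @param seed master integer seed.
#' @param stage character stage label (e.g. `"landmarks/GMB"`).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' stage_seed(1, "mantel") != stage_seed(1, "permanova")
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647  # 2^31 - 1, Mersenne prime; keeps seeds in integer range
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(stage)) h <- (h * 31 + b) %% m
  as.integer(h)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state, so
#' seeded package functions do not disturb the global random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream unchanged.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
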