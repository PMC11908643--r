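#' @importFrom e1071 svm
#' @importFrom rpart rpart
#' @importFrom glmnet glmnet cv.glmnet
#' @importFrom MASS ginv
#' @importFrom stats predict
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Derive a stream-specific seed from a base seed; stays in 32-bit range.
.deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483629) + 1L
}

## Run `expr` under `seed` without clobbering the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## sample() is unsafe on a length-1 vector (it samples 1:x); always index.
.sampleFrom <- function(x, size) {
  x[sample.int(length(x), size)]
}

.assertScalarNumber <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
}
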