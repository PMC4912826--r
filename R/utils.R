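#' @useDynLib qtlwin, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rbinom rbeta median pchisq qchisq pt optimize var sd setNames
#' @importFrom utils write.table read.table packageVersion head modifyList
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Population variance (denominator n) of a finite vector.
pop_var <- function(x) {
  mu <- mean(x)
  mean((x - mu)^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
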