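## Internal helpers: conditions, seeded RNG scopes, log-space arithmetic.

inputError <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("rm_input_error", "error")))
}

usageError <- function(msg) {
  stop(errorCondition(msg, class = c("rm_usage_error", "error")))
}

## Evaluate `expr` under a fixed seed without disturbing the caller's RNG
## stream. seed = NULL means "use the current stream".
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    inputError("seed must be a single number")
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hasSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hasSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

## Derive a reproducible child seed (kept below 2^31).
childSeed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 48271 + 10007 * k) %% 2147483647
}

## log(sum(exp(x))) for natural-log inputs, safe for very small terms.
logSumExp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnotScalarNum <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    inputError(sprintf("%s must be a single number", name))
  if (positive && x <= 0)
    inputError(sprintf("%s must be > 0", name))
  invisible(x)
}
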