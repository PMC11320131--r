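# Internal helpers shared across modules.

#' Dispersion statistic
#'
#' The dispersion used throughout the model as both the firefly
#' "brightness" ingredient and the variance-style gate activation:
#' `sum((x - mean(x))^2) / (length(x) + 1)`. Note the `n + 1` divisor,
#' which is neither the population (`n`) nor the sample (`n - 1`)
#' normalisation; it is kept exactly as the model defines it.
#'
#' @param x Numeric vector (finite values).
#' @return A single non-negative number; `0` for a constant vector.
#' @examples
#' dispersion(c(0, 2)) # (1 + 1) / 3
#' @export
dispersion <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1L)
  if (anyNA(x) || any(!is.finite(x))) stop("dispersion(): non-finite input")
  sum((x - mean(x))^2) / (length(x) + 1)
}

# Run `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so seeded package functions do not clobber user code.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialise .Random.seed
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Stable row-wise softmax.
softmax_rows <- function(logits) {
  logits <- as.matrix(logits)
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

# argmax with ties broken by lowest index (which.max's contract).
argmax_row <- function(p) apply(as.matrix(p), 1L, which.max)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)
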