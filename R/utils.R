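# Internal numerical and bookkeeping helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Log-sum-exp of a numeric vector
#'
#' Computes `log(sum(exp(x)))` without forming raw exponentials, so that
#' Bayes-factor accumulation never overflows.
#'
#' @param x numeric vector (may contain `-Inf`).
#' @return scalar, `-Inf` for an empty vector.
#' @keywords internal
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf when the difference vanishes.
logdiffexp <- function(a, b) {
  if (b == -Inf) return(a)
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Derive a child random seed from a master seed and a stream label
#'
#' Each simulation operation consumes its own stream so that runs driven by a
#' single master seed stay reproducible operation by operation.
#'
#' @param seed integer master seed.
#' @param label character stream label.
#' @return integer seed below 2^31.
#' @export
child_seed <- function(seed, label) {
  stopifnot(is.character(label), length(label) == 1L)
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 2654435.0) %% 2147483647)
}

# single-number formatting for messages
fmt <- function(x) format(x, digits = 4, trim = TRUE)

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
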