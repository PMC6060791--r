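# Small numerical helpers shared across the package.

#' Probability floor applied before any logarithm
#' @keywords internal
P_FLOOR <- 1e-16

#' Floored natural logarithm
#'
#' @param x numeric vector or matrix of probabilities.
#' @return log of `x` with entries floored at 1e-16 so that impossible
#'   outcomes map to a large-but-finite negative number.
#' @keywords internal
ln_floor <- function(x) log(pmax(x, P_FLOOR))

#' Softmax with overflow protection
#'
#' @param v numeric vector of log-weights.
#' @return categorical distribution proportional to exp(v).
#' @export
softmax <- function(v) {
  w <- exp(v - max(v))
  w / sum(w)
}

#' Normalize a nonnegative vector to a categorical distribution
#' @keywords internal
normalize <- function(x) {
  s <- sum(x)
  if (!is.finite(s) || s <= 0) {
    stop("numerical degeneracy: cannot normalize an all-zero message",
         call. = FALSE)
  }
  x / s
}

#' Discrete KL divergence sum(p log p/q) with floors
#' @keywords internal
kl_cat <- function(p, q) sum(p * (ln_floor(p) - ln_floor(q)))

stopf <- function(...) stop(sprintf(...), call. = FALSE)
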