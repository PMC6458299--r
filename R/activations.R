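#' Saturated linear activation
#'
#' The bounded nonlinearity used throughout the trainer,
#' \eqn{\sigma(h) = \min(\max(h, -1), 1)}. Unlike a rectifier it saturates on
#' both sides, which is what lets a unit's error gate shut completely when its
#' input is too large in either direction.
#'
#' @param h Numeric vector, matrix or array of pre-activations.
#' @return Object of the same shape with values clamped to \eqn{[-1, 1]}.
#' @seealso [satlin_gate()] for the derivative gate.
#' @export
#' @examples
#' satlin(c(-3, -0.5, 0.5, 2))  # -1 -0.5 0.5 1
satlin <- function(h) {
  pmin(pmax(h, -1), 1)
}

#' Derivative gate of the saturated linearity
#'
#' Returns 1 where \eqn{|h| \le 1} (the linear region, boundary inclusive) and
#' 0 where the unit is saturated. Saturated units transmit no error signal:
#' the top-down activity at such a unit is zeroed.
#'
#' @param h Numeric vector, matrix or array of pre-activations.
#' @return Numeric 0/1 object of the same shape.
#' @export
satlin_gate <- function(h) {
  g <- (abs(h) <= 1)
  storage.mode(g) <- "double"
  g
}

#' Multi-class hinge loss
#'
#' One-vs-all margin loss over output-layer activities \code{x_L} (a column
#' per example, no nonlinearity applied at the output layer). For an example
#' of class \eqn{c}:
#' \deqn{L = \max(1 - x_{L,c}, 0) + \mu \sum_{i \ne c} \max(1 + x_{L,i}, 0).}
#' The loss is zero exactly when the correct class output exceeds the margin 1
#' and every other output lies below \eqn{-1}.
#'
#' @param scores Numeric matrix \code{C x n} of output activities (a single
#'   vector is treated as one example).
#' @param labels Integer class labels in \code{1..C}, one per example.
#' @param mu Nonnegative off-class balancing weight \eqn{\mu}; default 1.
#' @return Numeric vector of per-example losses.
#' @export
hinge_loss <- function(scores, labels, mu = 1) {
  scores <- as.matrix(scores)
  C <- nrow(scores); n <- ncol(scores)
  stopifnot(C >= 2, mu >= 0, length(labels) == n)
  if (any(labels < 1L | labels > C)) stop("invalid label: class index out of range")
  idx <- cbind(labels, seq_len(n))
  xc <- scores[idx]
  off <- pmax(1 + scores, 0)
  off[idx] <- 0
  pmax(1 - xc, 0) + mu * colSums(off)
}

#' Local top-layer error signal of the hinge loss
#'
#' The feedback activity substituted for the output layer during learning,
#' \eqn{\delta_L = -\partial L / \partial x_L}:
#' \deqn{\delta_{L,i} = 1 \text{ if } i = c, x_{L,i} \le 1; \quad
#'       -\mu \text{ if } i \ne c, x_{L,i} \ge \theta; \quad 0 \text{ otherwise},}
#' with boundary values taking the nonzero branch. Each entry depends only on
#' that unit's own input and the target — no cross-unit computation — which is
#' what makes the resulting synaptic updates purely Hebbian.
#'
#' @inheritParams hinge_loss
#' @param off_threshold Gate threshold for off-class units; the printed loss
#'   derivative uses \code{-1} (the default) regardless of \code{mu}.
#' @return Numeric matrix \code{C x n} of error signals.
#' @export
hinge_top_error <- function(scores, labels, mu = 1, off_threshold = -1) {
  scores <- as.matrix(scores)
  C <- nrow(scores); n <- ncol(scores)
  stopifnot(C >= 2, mu >= 0, length(labels) == n)
  if (any(labels < 1L | labels > C)) stop("invalid label: class index out of range")
  idx <- cbind(labels, seq_len(n))
  onehot <- matrix(FALSE, C, n); onehot[idx] <- TRUE
  delta <- matrix(0, C, n)
  delta[onehot & scores <= 1] <- 1
  off <- (!onehot) & (scores >= off_threshold)
  delta[off] <- -mu
  delta
}

#' Softmax / cross-entropy comparator error signal
#'
#' The standard top-layer error \eqn{\delta_L = y - \mathrm{softmax}(x_L)}
#' used by the cross-entropy comparator. Computed with max-subtraction for
#' numerical stability. Unlike the hinge signal this requires every output
#' unit's activity (the softmax normalizer), so it is not a local computation.
#'
#' @inheritParams hinge_loss
#' @return Numeric matrix \code{C x n}; each column sums to 0.
#' @export
softmax_ce_error <- function(scores, labels) {
  scores <- as.matrix(scores)
  C <- nrow(scores); n <- ncol(scores)
  stopifnot(length(labels) == n)
  if (any(labels < 1L | labels > C)) stop("invalid label: class index out of range")
  z <- sweep(scores, 2, apply(scores, 2, max))
  ez <- exp(z)
  p <- sweep(ez, 2, colSums(ez), "/")
  y <- matrix(0, C, n)
  y[cbind(labels, seq_len(n))] <- 1
  y - p
}

#' Softmax cross-entropy loss (comparator)
#'
#' @inheritParams hinge_loss
#' @return Numeric vector of per-example negative log-likelihoods.
#' @export
softmax_ce_loss <- function(scores, labels) {
  scores <- as.matrix(scores)
  n <- ncol(scores)
  z <- sweep(scores, 2, apply(scores, 2, max))
  lse <- log(colSums(exp(z)))
  -z[cbind(labels, seq_len(n))] + lse
}
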