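# Dense (fully connected) layer primitives.
#
# A trainable layer owns a weight pair: the feedforward matrix W
# [n_l x n_{l-1}], a *separate* feedback matrix R stored as [n_{l-1} x n_l]
# (so R %*% delta maps layer-l errors down to layer l-1), and fixed binary
# connectivity masks for each. Entries masked to 0 stay exactly 0 forever.

#' Create a dense weight pair
#'
#' @param n_out,n_in Layer sizes (units above / below).
#' @param W,R Optional explicit matrices; defaults are zeros.
#' @param mask_W,mask_R Optional binary masks (defaults all-ones).
#' @return A list of class \code{"weight_pair"} with elements \code{W}
#'   (\code{n_out x n_in}), \code{R} (\code{n_in x n_out}), \code{mask_W},
#'   \code{mask_R}.
#' @export
weight_pair <- function(n_out, n_in, W = NULL, R = NULL,
                        mask_W = NULL, mask_R = NULL) {
  W <- W %||% matrix(0, n_out, n_in)
  R <- R %||% matrix(0, n_in, n_out)
  mask_W <- mask_W %||% matrix(1, n_out, n_in)
  mask_R <- mask_R %||% matrix(1, n_in, n_out)
  stopifnot(all(dim(W) == c(n_out, n_in)), all(dim(R) == c(n_in, n_out)),
            all(dim(mask_W) == dim(W)), all(dim(mask_R) == dim(R)))
  structure(list(W = W * mask_W, R = R * mask_R,
                 mask_W = mask_W, mask_R = mask_R),
            class = "weight_pair")
}

#' Dense forward map
#'
#' \code{h = (W * mask_W) \%*\% x_prev}; columns of \code{x_prev} are batch
#' examples.
#'
#' @param pair A [weight_pair()].
#' @param x_prev Numeric matrix \code{n_in x batch} (or a vector).
#' @return Pre-activation matrix \code{n_out x batch}.
#' @export
dense_forward <- function(pair, x_prev) {
  x_prev <- as.matrix(x_prev)
  if (nrow(x_prev) != ncol(pair$W))
    stop("dense_forward: input length ", nrow(x_prev),
         " does not match fan-in ", ncol(pair$W))
  (pair$W * pair$mask_W) %*% x_prev
}

#' Dense feedback map
#'
#' Propagates the layer-above error down one layer:
#' \code{delta_here = satlin_gate(h_here) * ((R * mask_R) \%*\% delta_above)}.
#' Saturated units (\code{|h| > 1}) pass no error. With \code{use_transpose}
#' the feedforward transpose \code{t(W * mask_W)} is used instead of R —
#' exact back-propagation.
#'
#' @param pair_above Weight pair of the layer above.
#' @param delta_above Error matrix \code{n_above x batch}.
#' @param h_here Pre-activations of this layer (same shape as the result);
#'   pass \code{NULL} to skip gating (linear layer).
#' @param use_transpose Logical; feedback through \code{t(W)} (bp mode).
#' @return Error matrix for this layer.
#' @export
dense_feedback <- function(pair_above, delta_above, h_here,
                           use_transpose = FALSE) {
  delta_above <- as.matrix(delta_above)
  if (nrow(delta_above) != nrow(pair_above$W))
    stop("dense_feedback: delta length mismatch")
  back <- if (use_transpose) t(pair_above$W * pair_above$mask_W)
          else pair_above$R * pair_above$mask_R
  d <- back %*% delta_above
  if (!is.null(h_here)) d <- satlin_gate(h_here) * d
  d
}

#' Hebbian weight increments for a dense layer
#'
#' \code{dW[i, j] = mean over the batch of delta[i] * x_prev[j]}; the feedback
#' increment is its transpose (both weights see the same pre/post-synaptic
#' activity). \code{x_prev} must be the layer's *original feedforward* input
#' activity — the top-down pass replaces activities top-to-bottom, so the
#' lower layer still holds its feedforward value when this layer updates.
#'
#' @param delta Error matrix \code{n_out x batch} for this layer.
#' @param x_prev Feedforward input matrix \code{n_in x batch}.
#' @param average Average over the batch (default) or sum.
#' @return List with \code{dW} (\code{n_out x n_in}) and \code{dR} =
#'   \code{t(dW)}. Connectivity masks are applied by the caller on update.
#' @export
hebbian_increments <- function(delta, x_prev, average = TRUE) {
  delta <- as.matrix(delta); x_prev <- as.matrix(x_prev)
  stopifnot(ncol(delta) == ncol(x_prev))
  dW <- tcrossprod(delta, x_prev)
  if (average) dW <- dW / ncol(delta)
  list(dW = dW, dR = t(dW))
}
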