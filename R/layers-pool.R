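# Parameter-free stages: max-pooling with argmax routing, dropout, and the
# residual SUM stage.

#' Max-pooling forward map
#'
#' At each retained grid point the maximum over a \code{window x window}
#' region is taken per channel, with zero padding outside the grid (so
#' boundary windows over all-negative inputs return 0). For odd windows the
#' region is centered on the pixel; grid points are retained every
#' \code{stride} pixels starting from the first, giving output size
#' \code{ceiling(H / stride)}. The winning input location is recorded for
#' error routing; ties go to the first candidate in row-major window scan
#' order, and a win by a padding cell records no location.
#'
#' @param x_prev Input stack \code{(H, W, C, batch)}.
#' @param window Window size (the architecture strings use 2 or 3).
#' @param stride Subsampling stride (2 or 3).
#' @return List with \code{x} — pooled stack \code{(Ho, Wo, C, batch)} — and
#'   \code{argmax} — integer array of the same shape holding the linear
#'   pixel index (into \code{H*W}) of each winner, \code{NA} for padding.
#' @export
maxpool_forward <- function(x_prev, window = 3L, stride = 2L) {
  if (length(dim(x_prev)) == 3L) dim(x_prev) <- c(dim(x_prev), 1L)
  d <- dim(x_prev); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  w <- as.integer(window); s <- as.integer(stride)
  pb <- (w - 1L) %/% 2L
  Hp <- H + w - 1L; Wp <- W + w - 1L
  xp <- array(0, c(Hp, Wp, C, N))
  xp[pb + seq_len(H), pb + seq_len(W), , ] <- x_prev
  ip <- seq.int(1L, H, by = s); jp <- seq.int(1L, W, by = s)
  no <- length(ip); mo <- length(jp)
  ncell <- no * mo * C * N
  # padded linear base index of each output cell's window origin
  b0 <- rep(ip, times = mo) + rep(jp - 1L, each = no) * Hp
  base <- rep(b0, times = C * N) +
    rep(seq_len(C * N) - 1L, each = no * mo) * (Hp * Wp)
  cand <- matrix(0, ncell, w * w)
  pix <- matrix(NA_integer_, no * mo, w * w)   # unpadded winner pixel or NA
  t <- 0L
  for (di in seq_len(w)) for (dj in seq_len(w)) {   # row-major window scan
    t <- t + 1L
    cand[, t] <- xp[base + (di - 1L) + (dj - 1L) * Hp]
    oi <- rep(ip, times = mo) + di - 1L - pb
    oj <- rep(jp, each = no) + dj - 1L - pb
    ok <- oi >= 1L & oi <= H & oj >= 1L & oj <= W
    pix[ok, t] <- oi[ok] + (oj[ok] - 1L) * H
  }
  mx <- max.col(cand, ties.method = "first")
  best <- array(cand[cbind(seq_len(ncell), mx)], c(no, mo, C, N))
  besti <- array(pix[cbind(rep(seq_len(no * mo), times = C * N), mx)],
                 c(no, mo, C, N))
  list(x = best, argmax = besti)
}

#' Max-pooling feedback routing
#'
#' Each pooled unit's error is added at the input location that won its
#' window (winner-take-all, consistent with the forward max); overlapping
#' windows sharing a winner accumulate by summation. Units whose winner was
#' a padding cell pass no error.
#'
#' @param delta Error stack on the pooled grid \code{(Ho, Wo, C, batch)}.
#' @param argmax The \code{argmax} array from the matching
#'   [maxpool_forward()] call.
#' @param input_shape Integer \code{c(H, W, C)} of the pre-pooling grid.
#' @return Error stack \code{(H, W, C, batch)}.
#' @export
maxpool_feedback <- function(delta, argmax, input_shape) {
  if (length(dim(delta)) == 3L) dim(delta) <- c(dim(delta), 1L)
  if (!all(dim(delta) == dim(argmax)))
    stop("stale argmax: shape does not match delta (sequencing violation)")
  H <- input_shape[1]; W <- input_shape[2]; C <- input_shape[3]
  N <- dim(delta)[4]
  ci <- slice.index(delta, 3L); ni <- slice.index(delta, 4L)
  full <- argmax + (ci - 1L) * H * W + (ni - 1L) * H * W * C
  ok <- !is.na(argmax)
  out <- numeric(H * W * C * N)
  if (any(ok)) {
    agg <- rowsum(as.vector(delta[ok]), group = as.vector(full[ok]))
    out[as.integer(rownames(agg))] <- agg[, 1]
  }
  array(out, c(H, W, C, N))
}

#' Dropout
#'
#' Zeroes a random fraction \code{rate} of units. Following the training
#' protocol ("for each training batch, a random subset ... set to 0"), the
#' default draws one mask per batch, shared by all examples in it
#' (\code{per_example = TRUE} draws fresh masks per example). No activation
#' rescaling is applied, and evaluation simply skips the stage.
#'
#' @param x Activation array; last dimension is the batch.
#' @param rate Fraction of units zeroed, in \code{[0, 1)}.
#' @param per_example Draw an independent mask per batch example.
#' @return List with \code{x} (masked activations) and \code{mask} (0/1
#'   array of the full shape).
#' @export
dropout_apply <- function(x, rate, per_example = FALSE) {
  stopifnot(rate >= 0, rate < 1)
  d <- dim(x) %||% length(x)
  if (per_example || length(d) == 1L) {
    mask <- array(as.double(stats::runif(prod(d)) >= rate), d)
  } else {
    nu <- prod(d[-length(d)])
    m1 <- as.double(stats::runif(nu) >= rate)
    mask <- array(rep(m1, d[length(d)]), d)
  }
  list(x = x * mask, mask = mask)
}

#' Dropout feedback
#'
#' Multiplies the error by the forward mask, so dropped units contribute no
#' update to their outgoing synapses.
#'
#' @param delta Error array.
#' @param mask Mask from the matching [dropout_apply()] call.
#' @return Masked error array.
#' @export
dropout_feedback <- function(delta, mask) delta * mask

#' Residual (SUM) stage
#'
#' Parameter-free elementwise sum of two same-shape stages; the error passes
#' unchanged to both addends.
#'
#' @param x_a,x_b Same-shape activation arrays.
#' @return Their elementwise sum.
#' @export
residual_sum_forward <- function(x_a, x_b) {
  if (!identical(dim(x_a) %||% length(x_a), dim(x_b) %||% length(x_b)))
    stop("SUM: operand shapes differ")
  x_a + x_b
}

#' @rdname residual_sum_forward
#' @param delta Error array at the sum's output.
#' @return List \code{(delta_a, delta_b)}, both equal to \code{delta}.
#' @export
residual_sum_feedback <- function(delta) list(delta_a = delta, delta_b = delta)
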