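# Tied convolutional layer primitives, implemented via im2col so that the
# forward map, the feedback map and the Hebbian filter update are ordinary
# matrix products. Zero "same" padding throughout: spatial size is preserved.
#
# Conventions: feature-map stacks are 4-d arrays (H, W, channels, batch);
# filter banks are 4-d arrays (kh, kw, in_channels, out_channels).

#' Convolution geometry descriptor
#'
#' @param in_h,in_w Input spatial size.
#' @param in_c,out_c Input / output channel counts.
#' @param kh,kw Kernel size (height, width).
#' @return List of class \code{"conv_geometry"}; includes the zero-padding
#'   offsets implied by "same" padding (\code{floor((k-1)/2)} before).
#' @export
conv_geometry <- function(in_h, in_w, in_c, out_c, kh, kw = kh) {
  stopifnot(in_h >= 1, in_w >= 1, kh >= 1, kw >= 1, in_c >= 1, out_c >= 1)
  structure(list(in_h = in_h, in_w = in_w, in_c = in_c, out_c = out_c,
                 kh = kh, kw = kw,
                 pb_h = (kh - 1L) %/% 2L, pb_w = (kw - 1L) %/% 2L),
            class = "conv_geometry")
}

# Promote a single example (H,W,C) to a batch of one.
as_batch4 <- function(x, geom = NULL) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 4L)
  if (!is.null(geom) &&
      !all(dim(x)[1:3] == c(geom$in_h, geom$in_w, geom$in_c)))
    stop("geometry mismatch: input is ", paste(dim(x)[1:3], collapse = "x"),
         ", geometry expects ",
         paste(c(geom$in_h, geom$in_w, geom$in_c), collapse = "x"))
  x
}

# Unfold (H,W,C,N) into the (kh*kw*C) x (H*W*N) patch matrix whose row order
# matches matrix(filter_bank, kh*kw*C, out_c). Implemented as one gather
# from the zero-padded input with precomputed linear offsets.
im2col <- function(x, geom) {
  x <- as_batch4(x, geom)
  H <- geom$in_h; W <- geom$in_w; C <- geom$in_c; N <- dim(x)[4]
  kh <- geom$kh; kw <- geom$kw
  Hp <- H + kh - 1L; Wp <- W + kw - 1L
  xp <- array(0, c(Hp, Wp, C, N))
  xp[geom$pb_h + seq_len(H), geom$pb_w + seq_len(W), , ] <- x
  key <- paste("i2c", H, W, C, N, kh, kw, sep = "_")
  idx <- cache_get(key, function() {
    # row offsets, order (di, dj, c); column bases, order (i, j, n)
    di <- rep(seq_len(kh) - 1L, times = kw * C)
    dj <- rep(rep(seq_len(kw) - 1L, each = kh), times = C)
    cc <- rep(seq_len(C) - 1L, each = kh * kw)
    row_off <- di + dj * Hp + cc * (Hp * Wp)
    b0 <- rep(seq_len(H), times = W) + rep(seq_len(W) - 1L, each = H) * Hp
    col_base <- rep(b0, times = N) +
      rep(seq_len(N) - 1L, each = H * W) * (Hp * Wp * C)
    rep(col_base, each = kh * kw * C) + row_off
  })
  matrix(xp[idx], kh * kw * C, H * W * N)
}

# Adjoint of im2col: scatter-add a patch matrix back onto the input grid.
col2im <- function(M, geom, n_batch) {
  H <- geom$in_h; W <- geom$in_w; C <- geom$in_c
  kh <- geom$kh; kw <- geom$kw
  B <- aperm(array(M, c(kh * kw, C, H, W, n_batch)), c(3L, 4L, 2L, 5L, 1L))
  gp <- array(0, c(H + kh - 1L, W + kw - 1L, C, n_batch))
  t <- 0L
  for (dj in seq_len(kw)) for (di in seq_len(kh)) {
    t <- t + 1L
    gp[di:(di + H - 1L), dj:(dj + W - 1L), , ] <-
      gp[di:(di + H - 1L), dj:(dj + W - 1L), , , drop = FALSE] + B[, , , , t]
  }
  gp[geom$pb_h + seq_len(H), geom$pb_w + seq_len(W), , , drop = FALSE]
}

#' Tied convolution forward map
#'
#' 2-D cross-correlation of each filter with the input stack, summed over
#' input channels, with zero "same" padding.
#'
#' @param filterbank Array \code{(kh, kw, in_c, out_c)}.
#' @param geom A [conv_geometry()].
#' @param x_prev Input stack \code{(H, W, in_c, batch)} (3-d treated as one
#'   example).
#' @param xcol Optional precomputed \code{im2col(x_prev, geom)} patch matrix.
#' @return Pre-activation stack \code{(H, W, out_c, batch)}.
#' @export
conv_forward <- function(filterbank, geom, x_prev, xcol = NULL) {
  x_prev <- as_batch4(x_prev, geom)
  K <- geom$kh * geom$kw * geom$in_c
  stopifnot(length(filterbank) == K * geom$out_c)
  N <- dim(x_prev)[4]
  Wm <- t(matrix(filterbank, K, geom$out_c))        # out_c x K
  Hm <- Wm %*% (xcol %||% im2col(x_prev, geom))     # out_c x (H*W*N)
  aperm(array(Hm, c(geom$out_c, geom$in_h, geom$in_w, N)), c(2L, 3L, 1L, 4L))
}

#' Tied convolution feedback map
#'
#' Maps a layer's error stack down to its input grid through a feedback
#' filter bank (the adjoint of [conv_forward()] when the feedback bank equals
#' the feedforward bank).
#'
#' @param feedback_bank Array \code{(kh, kw, in_c, out_c)} of feedback taps.
#' @param geom A [conv_geometry()].
#' @param delta Error stack \code{(H, W, out_c, batch)}.
#' @return Error stack on the input grid \code{(H, W, in_c, batch)}.
#' @export
conv_feedback <- function(feedback_bank, geom, delta) {
  if (length(dim(delta)) == 3L) dim(delta) <- c(dim(delta), 1L)
  N <- dim(delta)[4]
  K <- geom$kh * geom$kw * geom$in_c
  Rm <- matrix(feedback_bank, K, geom$out_c)        # K x out_c
  Dm <- matrix(aperm(delta, c(3L, 1L, 2L, 4L)), geom$out_c,
               geom$in_h * geom$in_w * N)
  col2im(Rm %*% Dm, geom, N)
}

#' Tied (shared-weight) convolution filter update
#'
#' Each filter tap accumulates the sum over all spatial positions of the
#' product of the error at a position with the input at the displaced
#' position (then the mean over the batch). This cross-location summation is
#' exactly what the untied layer [local_update()] does *not* do.
#'
#' @param delta Error stack \code{(H, W, out_c, batch)} for this layer.
#' @param x_prev Original feedforward input stack \code{(H, W, in_c, batch)}.
#' @param geom A [conv_geometry()].
#' @param average Average over the batch (default) or sum.
#' @param xcol Optional precomputed \code{im2col(x_prev, geom)} patch matrix
#'   (reused from the forward pass).
#' @return List with \code{dW} (array like the filter bank) and \code{dR},
#'   the identical increment for the tied feedback bank.
#' @export
conv_update_tied <- function(delta, x_prev, geom, average = TRUE,
                             xcol = NULL) {
  x_prev <- as_batch4(x_prev, geom)
  if (length(dim(delta)) == 3L) dim(delta) <- c(dim(delta), 1L)
  N <- dim(x_prev)[4]
  Dm <- matrix(aperm(delta, c(3L, 1L, 2L, 4L)), geom$out_c,
               geom$in_h * geom$in_w * N)
  dWm <- tcrossprod(Dm, xcol %||% im2col(x_prev, geom))   # out_c x K
  if (average) dWm <- dWm / N
  bank_dim <- c(geom$kh, geom$kw, geom$in_c, geom$out_c)
  dW <- array(t(dWm), bank_dim)
  list(dW = dW, dR = dW)
}
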