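# Untied locally connected layers. A convolution is multiplication by a
# sparse matrix whose entry values repeat across rows with a displacement;
# the untied layer keeps that sparsity pattern but stores and updates every
# entry separately, with the plain Hebbian product for that one synapse.

# Enumerate the sparse pattern implied by a convolution geometry.
# Entries are (row = output unit, col = input unit, tap = linear index into
# the (kh,kw,in_c,out_c) filter bank). No duplicates by construction.
local_pattern <- function(geom) {
  H <- geom$in_h; W <- geom$in_w
  kh <- geom$kh; kw <- geom$kw
  oi <- rep(seq_len(H), times = W)
  oj <- rep(seq_len(W), each = H)
  out_pix <- oi + (oj - 1L) * H
  rows <- cols <- taps <- vector("list", kh * kw)
  t <- 0L
  for (dj in seq_len(kw)) for (di in seq_len(kh)) {
    t <- t + 1L
    ii <- oi + di - 1L - geom$pb_h
    jj <- oj + dj - 1L - geom$pb_w
    ok <- ii >= 1L & ii <= H & jj >= 1L & jj <= W
    rows[[t]] <- out_pix[ok]
    cols[[t]] <- ii[ok] + (jj[ok] - 1L) * H
    taps[[t]] <- rep.int(di + (dj - 1L) * kh, sum(ok))
  }
  r0 <- unlist(rows); c0 <- unlist(cols); t0 <- unlist(taps)
  # replicate over channel pairs: ci varies fastest, then co, matching the
  # (kh, kw, in_c, out_c) flattening of a filter bank
  npix <- H * W
  n0 <- length(r0)
  ci <- rep(rep(seq_len(geom$in_c), each = n0), times = geom$out_c)
  co <- rep(seq_len(geom$out_c), each = n0 * geom$in_c)
  r <- rep(r0, times = geom$in_c * geom$out_c) + (co - 1L) * npix
  cc <- rep(c0, times = geom$in_c * geom$out_c) + (ci - 1L) * npix
  tap_full <- rep(t0, times = geom$in_c * geom$out_c) +
    (ci - 1L) * kh * kw + (co - 1L) * kh * kw * geom$in_c
  list(row = r, col = cc, tap = tap_full,
       n_out = npix * geom$out_c, n_in = npix * geom$in_c,
       geom = geom)
}

#' Create an untied locally connected layer
#'
#' @param geom A [conv_geometry()].
#' @param values Optional numeric vector of entry values, one per stored
#'   connection (order given by the pattern); default zeros.
#' @param values_R Optional feedback entry values (same entries, transposed
#'   pattern); default a copy of \code{values}.
#' @param mask_W,mask_R Optional binary vectors over the stored entries.
#' @return Object of class \code{"local_weights"} holding the fixed pattern,
#'   the free values for W and R, masks, and cached sparse-matrix templates.
#' @export
local_weights <- function(geom, values = NULL, values_R = NULL,
                          mask_W = NULL, mask_R = NULL) {
  pat <- local_pattern(geom)
  ne <- length(pat$row)
  values <- values %||% numeric(ne)
  values_R <- values_R %||% values
  mask_W <- mask_W %||% rep(1, ne)
  mask_R <- mask_R %||% rep(1, ne)
  stopifnot(length(values) == ne, length(values_R) == ne,
            length(mask_W) == ne, length(mask_R) == ne)
  tmpl_W <- Matrix::sparseMatrix(i = pat$row, j = pat$col,
                                 x = as.double(seq_len(ne)),
                                 dims = c(pat$n_out, pat$n_in))
  tmpl_R <- Matrix::sparseMatrix(i = pat$col, j = pat$row,
                                 x = as.double(seq_len(ne)),
                                 dims = c(pat$n_in, pat$n_out))
  structure(list(pattern = pat, geom = geom,
                 vals_W = as.double(values) * mask_W,
                 vals_R = as.double(values_R) * mask_R,
                 mask_W = as.double(mask_W), mask_R = as.double(mask_R),
                 perm_W = as.integer(tmpl_W@x), perm_R = as.integer(tmpl_R@x),
                 tmpl_W = tmpl_W, tmpl_R = tmpl_R),
            class = "local_weights")
}

#' Replicate a filter bank into an untied layer
#'
#' Builds the sparse connectivity matrix whose pattern and values reproduce
#' the convolution exactly: \code{local_forward()} on the result equals
#' [conv_forward()] with the bank, and every location carries an identical
#' copy of its tap vector (cross-location filter correlation 1) until the
#' per-entry updates break the tie.
#'
#' @param filterbank Array \code{(kh, kw, in_c, out_c)}.
#' @param geom A [conv_geometry()].
#' @param feedback_bank Optional feedback bank to replicate into the R
#'   values; defaults to \code{filterbank}.
#' @return A [local_weights()] object.
#' @export
conv_to_local <- function(filterbank, geom, feedback_bank = filterbank) {
  lw <- local_weights(geom)
  lw$vals_W <- as.double(filterbank)[lw$pattern$tap]
  lw$vals_R <- as.double(feedback_bank)[lw$pattern$tap]
  lw
}

sparse_W <- function(lw, use_R = FALSE, transpose_W = FALSE) {
  if (use_R) {
    M <- lw$tmpl_R
    M@x <- (lw$vals_R * lw$mask_R)[lw$perm_R]
  } else if (transpose_W) {
    M <- lw$tmpl_R                       # transposed pattern, W values
    M@x <- (lw$vals_W * lw$mask_W)[lw$perm_R]
  } else {
    M <- lw$tmpl_W
    M@x <- (lw$vals_W * lw$mask_W)[lw$perm_W]
  }
  M
}

#' Untied layer forward map
#'
#' Sparse matrix-vector product with the layer's stored W values; the
#' sparsity pattern is fixed, the values are free.
#'
#' @param lw A [local_weights()] object.
#' @param x_prev Input stack \code{(H, W, in_c, batch)}.
#' @return Pre-activation stack \code{(H, W, out_c, batch)}.
#' @export
local_forward <- function(lw, x_prev) {
  g <- lw$geom
  x_prev <- as_batch4(x_prev, g)
  N <- dim(x_prev)[4]
  xm <- matrix(x_prev, lw$pattern$n_in, N)
  hm <- as.matrix(sparse_W(lw) %*% xm)
  array(hm, c(g$in_h, g$in_w, g$out_c, N))
}

#' Untied layer feedback map
#'
#' @param lw A [local_weights()] object.
#' @param delta Error stack \code{(H, W, out_c, batch)}.
#' @param use_transpose Feedback through the transpose of the W values (bp
#'   mode) instead of the separate R values.
#' @return Error stack on the input grid \code{(H, W, in_c, batch)}.
#' @export
local_feedback <- function(lw, delta, use_transpose = FALSE) {
  g <- lw$geom
  if (length(dim(delta)) == 3L) dim(delta) <- c(dim(delta), 1L)
  N <- dim(delta)[4]
  dm <- matrix(delta, lw$pattern$n_out, N)
  M <- if (use_transpose) sparse_W(lw, transpose_W = TRUE)
       else sparse_W(lw, use_R = TRUE)
  array(as.matrix(M %*% dm), c(g$in_h, g$in_w, g$in_c, N))
}

#' Per-entry Hebbian update of an untied layer
#'
#' Every stored connection (i, j) is updated separately with the batch mean
#' of \code{delta[i] * x_prev[j]} — no summation across spatial locations.
#' The feedback entry connecting the same two units receives the identical
#' increment.
#'
#' @param lw A [local_weights()] object.
#' @param delta Error stack \code{(H, W, out_c, batch)}.
#' @param x_prev Original feedforward input stack.
#' @param average Average over the batch (default) or sum.
#' @return List with \code{dvals}: one increment per stored entry (applies
#'   to both the W value and the transposed-pattern R value).
#' @export
local_update <- function(lw, delta, x_prev, average = TRUE) {
  g <- lw$geom
  x_prev <- as_batch4(x_prev, g)
  if (length(dim(delta)) == 3L) dim(delta) <- c(dim(delta), 1L)
  N <- dim(x_prev)[4]
  xm <- matrix(x_prev, lw$pattern$n_in, N)
  dm <- matrix(delta, lw$pattern$n_out, N)
  dv <- rowSums(dm[lw$pattern$row, , drop = FALSE] *
                xm[lw$pattern$col, , drop = FALSE])
  if (average) dv <- dv / N
  list(dvals = dv)
}

#' Reconstruct the local filter at a grid location
#'
#' @param lw A [local_weights()] object.
#' @param i,j Interior grid location (the full window must fit).
#' @param channel Output channel, or \code{NULL} to concatenate all output
#'   channels' tap vectors.
#' @param which Extract \code{"W"} or \code{"R"} values.
#' @return Numeric tap vector ordered like the flattened filter bank.
#' @export
filter_at_location <- function(lw, i, j, channel = NULL, which = "W") {
  g <- lw$geom
  lo_i <- g$pb_h + 1L; hi_i <- g$in_h - (g$kh - 1L - g$pb_h)
  lo_j <- g$pb_w + 1L; hi_j <- g$in_w - (g$kw - 1L - g$pb_w)
  if (i < lo_i || i > hi_i || j < lo_j || j > hi_j)
    stop("boundary location (", i, ",", j, "): window is truncated")
  out_pix <- i + (j - 1L) * g$in_h
  kk <- g$kh * g$kw * g$in_c
  co_of_tap <- (lw$pattern$tap - 1L) %/% kk + 1L
  co_of_row <- (lw$pattern$row - 1L) %/% (g$in_h * g$in_w) + 1L
  sel <- (lw$pattern$row - (co_of_row - 1L) * g$in_h * g$in_w) == out_pix
  if (!is.null(channel)) sel <- sel & co_of_tap == channel
  vals <- if (which == "R") lw$vals_R else lw$vals_W
  v <- vals[sel]
  v[order(lw$pattern$tap[sel])]
}
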