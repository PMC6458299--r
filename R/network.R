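# Network assembly and the strictly sequenced forward / feedback / update
# loop.
#
# Training modes:
#   bp    feedback travels through t(W) (exact back-propagation; no separate
#         feedback weights are consulted)
#   urfb  feedback travels through a separately initialized R, and R gets
#         the same Hebbian increment as its W counterpart every step
#   frfb  feedback travels through R, which stays at its random initial
#         value (feedback alignment)

glorot_b <- function(fan_in, fan_out) sqrt(6 / (fan_in + fan_out))

#' Build a network from a specification
#'
#' Feedforward weights are drawn uniformly on \code{[-b_l, b_l]} with
#' \code{b_l = sqrt(6 / (fan_in + fan_out))}. Feedback weights are drawn
#' independently from the same law (\code{init = "independent"}) or set to
#' \code{t(W)} (\code{"mirrored"}). Connectivity masks are drawn
#' independently for W and R at the spec's sparsity, so pruned connectivity
#' is itself asymmetric. All randomness comes from the seed's "init" stream.
#'
#' @param spec A [parse_architecture()] result.
#' @param seed Integer seed.
#' @return Object of class \code{"hebbnet_network"}.
#' @export
build_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  net <- list(spec = spec, mode = spec$mode, n_classes = spec$n_classes,
              seed = as.integer(seed), stages = spec$stages)
  keep <- 1 - spec$sparsity
  with_seed(derive_seed(seed, "init"), {
    for (s in seq_along(net$stages)) {
      st <- net$stages[[s]]
      if (st$kind %in% c("dense", "output")) {
        b <- glorot_b(st$n_in, st$n)
        W <- matrix(stats::runif(st$n * st$n_in, -b, b), st$n, st$n_in)
        R <- if (spec$init == "mirrored") t(W)
             else matrix(stats::runif(st$n_in * st$n, -b, b), st$n_in, st$n)
        mW <- matrix(stats::rbinom(st$n * st$n_in, 1, keep), st$n, st$n_in)
        mR <- if (spec$init == "mirrored") t(mW)
              else matrix(stats::rbinom(st$n_in * st$n, 1, keep), st$n_in, st$n)
        st$pair <- weight_pair(st$n, st$n_in, W, R, mW, mR)
      } else if (st$kind == "conv") {
        g <- st$geom
        fan_in <- g$kh * g$kw * g$in_c; fan_out <- g$kh * g$kw * g$out_c
        b <- glorot_b(fan_in, fan_out)
        nb <- g$kh * g$kw * g$in_c * g$out_c
        Wb <- array(stats::runif(nb, -b, b), c(g$kh, g$kw, g$in_c, g$out_c))
        Rb <- if (spec$init == "mirrored") Wb
              else array(stats::runif(nb, -b, b), dim(Wb))
        mW <- array(stats::rbinom(nb, 1, keep), dim(Wb))
        mR <- if (spec$init == "mirrored") mW
              else array(stats::rbinom(nb, 1, keep), dim(Wb))
        st$W_bank <- Wb * mW; st$R_bank <- Rb * mR
        st$mask_W <- mW; st$mask_R <- mR
      } else if (st$kind == "local") {
        g <- st$geom
        fan_in <- g$kh * g$kw * g$in_c; fan_out <- g$kh * g$kw * g$out_c
        b <- glorot_b(fan_in, fan_out)
        lw <- local_weights(g)
        ne <- length(lw$pattern$row)
        vW <- stats::runif(ne, -b, b)
        vR <- if (spec$init == "mirrored") vW else stats::runif(ne, -b, b)
        mW <- stats::rbinom(ne, 1, keep)
        mR <- if (spec$init == "mirrored") mW else stats::rbinom(ne, 1, keep)
        st$lw <- local_weights(g, vW, vR, mW, mR)
      }
      net$stages[[s]] <- st
    }
  })
  structure(net, class = "hebbnet_network")
}

trainable_stages <- function(net)
  which(vapply(net$stages, function(s)
    s$kind %in% c("dense", "output", "conv", "local"), logical(1)))

#' @export
print.hebbnet_network <- function(x, ...) {
  cat("<hebbnet_network> mode=", x$mode, "\n", sep = "")
  print(x$spec)
  invisible(x)
}

flatten2 <- function(x) {
  if (is.matrix(x)) return(x)
  d <- dim(x)
  matrix(x, prod(d[-length(d)]), d[length(d)])
}

#' Forward pass
#'
#' Runs a batch bottom-up through every stage. Hidden trainable layers apply
#' the saturated linearity; the output layer applies none. Dropout is active
#' only with \code{train = TRUE} (masks drawn from the current RNG state).
#'
#' @param net A [build_network()] result.
#' @param x Input batch: array \code{(H, W, C, n)} or matrix
#'   \code{features x n}.
#' @param train Logical; training mode (dropout on, bookkeeping for
#'   feedback retained).
#' @param dropout_per_example Draw dropout masks per example instead of per
#'   batch.
#' @return A forward trace: list with \code{xs} (stage outputs;
#'   \code{xs[[1]]} is the input), \code{h} (pre-activations of trainable
#'   stages), \code{argmax}, \code{drop_mask}, and \code{scores}
#'   (\code{C x n} output activities).
#' @export
forward_pass <- function(net, x, train = FALSE, dropout_per_example = FALSE) {
  ns <- length(net$stages)
  xs <- vector("list", ns + 1L)
  h <- argmax <- drop_mask <- xcol <- vector("list", ns)
  if (length(net$spec$input_shape) == 3L && is.matrix(x))
    stop("shape mismatch: network expects image input")
  xs[[1]] <- x
  for (s in seq_len(ns)) {
    st <- net$stages[[s]]
    xin <- xs[[st$in_idx + 1L]]
    if (st$kind %in% c("dense", "output")) {
      hm <- dense_forward(st$pair, flatten2(xin))
      h[[s]] <- hm
      xs[[s + 1L]] <- if (st$kind == "output") hm else satlin(hm)
    } else if (st$kind == "conv") {
      if (train) {
        xcol[[s]] <- im2col(as_batch4(xin, st$geom), st$geom)
        hm <- conv_forward(st$W_bank * st$mask_W, st$geom, xin, xcol[[s]])
      } else {
        hm <- conv_forward(st$W_bank * st$mask_W, st$geom, xin)
      }
      h[[s]] <- hm
      xs[[s + 1L]] <- satlin(hm)
    } else if (st$kind == "local") {
      hm <- local_forward(st$lw, xin)
      h[[s]] <- hm
      xs[[s + 1L]] <- satlin(hm)
    } else if (st$kind == "pool") {
      p <- maxpool_forward(xin, st$window, st$stride)
      argmax[[s]] <- p$argmax
      xs[[s + 1L]] <- p$x
    } else if (st$kind == "drop") {
      if (train) {
        dp <- dropout_apply(xin, st$rate, dropout_per_example)
        drop_mask[[s]] <- dp$mask
        xs[[s + 1L]] <- dp$x
      } else xs[[s + 1L]] <- xin
    } else if (st$kind == "sum") {
      xs[[s + 1L]] <- residual_sum_forward(xin, xs[[st$in_idx2 + 1L]])
    }
  }
  scores <- flatten2(xs[[ns + 1L]])
  list(xs = xs, h = h, argmax = argmax, drop_mask = drop_mask,
       xcol = xcol, scores = scores, train = train)
}

top_error <- function(net, scores, labels, mu) {
  if (net$spec$loss == "hinge") hinge_top_error(scores, labels, mu)
  else softmax_ce_error(scores, labels)
}

#' Feedback pass
#'
#' Produces every trainable layer's error signal strictly top-down: the
#' output layer's signal comes from the loss; each lower layer's signal is
#' the gated feedback combination of the signals above, computed before
#' anything below moves. The trace's feedforward activities are left intact
#' — they are the pre-synaptic factors of the coming Hebbian updates.
#'
#' @param net Network.
#' @param trace Forward trace from the same batch, run with
#'   \code{train = TRUE}.
#' @param labels Integer class labels for the batch.
#' @param mu Hinge off-class weight.
#' @return A feedback trace: list \code{delta} with one error array per
#'   trainable stage.
#' @export
feedback_pass <- function(net, trace, labels, mu = 1) {
  if (!isTRUE(trace$train))
    stop("sequencing violation: feedback_pass needs a training-mode forward trace")
  ns <- length(net$stages)
  bp <- net$mode == "bp"
  acc <- vector("list", ns)        # error arriving at each stage's output
  delta <- vector("list", ns)      # finalized error signal per trainable stage
  dL <- top_error(net, trace$scores, labels, mu)
  acc[[ns]] <- dL
  add_acc <- function(acc, idx, d) {
    if (idx == 0L) return(acc)     # error at the input layer is discarded
    acc[[idx]] <- if (is.null(acc[[idx]])) d else acc[[idx]] + d
    acc
  }
  for (s in ns:1) {
    st <- net$stages[[s]]
    d <- acc[[s]]
    if (is.null(d)) next
    if (st$kind %in% c("dense", "output")) {
      dmat <- flatten2(d)
      ds <- if (st$kind == "dense") satlin_gate(trace$h[[s]]) * dmat else dmat
      delta[[s]] <- ds
      down <- dense_feedback(st$pair, ds, h_here = NULL, use_transpose = bp)
      if (length(st$in_shape) == 3L)
        down <- array(down, c(st$in_shape, ncol(dmat)))
      acc <- add_acc(acc, st$in_idx, down)
    } else if (st$kind == "conv") {
      ds <- satlin_gate(trace$h[[s]]) * d
      delta[[s]] <- ds
      bank <- if (bp) st$W_bank * st$mask_W else st$R_bank * st$mask_R
      acc <- add_acc(acc, st$in_idx, conv_feedback(bank, st$geom, ds))
    } else if (st$kind == "local") {
      ds <- satlin_gate(trace$h[[s]]) * d
      delta[[s]] <- ds
      acc <- add_acc(acc, st$in_idx,
                     local_feedback(st$lw, ds, use_transpose = bp))
    } else if (st$kind == "pool") {
      acc <- add_acc(acc, st$in_idx,
                     maxpool_feedback(d, trace$argmax[[s]], st$in_shape))
    } else if (st$kind == "drop") {
      acc <- add_acc(acc, st$in_idx,
                     dropout_feedback(d, trace$drop_mask[[s]]))
    } else if (st$kind == "sum") {
      rb <- residual_sum_feedback(d)
      acc <- add_acc(acc, st$in_idx, rb$delta_a)
      acc <- add_acc(acc, st$in_idx2, rb$delta_b)
    }
  }
  list(delta = delta)
}

#' Apply one step of Hebbian updates
#'
#' Every trainable layer's W moves by \code{eta} times the batch-mean outer
#' product of its error signal with its (original feedforward) input
#' activity. In \code{urfb} mode the separate feedback weights receive the
#' identical increment; in \code{frfb} they stay fixed; in \code{bp} mode
#' feedback is the transpose of W by construction, so only W is stored.
#' Connectivity masks are re-applied to every increment.
#'
#' @param net Network.
#' @param trace Forward trace of the batch.
#' @param fb Feedback trace of the same batch.
#' @param eta Learning rate.
#' @return The updated network.
#' @export
apply_updates <- function(net, trace, fb, eta = 0.1) {
  urfb <- net$mode == "urfb"
  for (s in trainable_stages(net)) {
    ds <- fb$delta[[s]]
    if (is.null(ds)) next
    st <- net$stages[[s]]
    xin <- trace$xs[[st$in_idx + 1L]]
    if (st$kind %in% c("dense", "output")) {
      inc <- hebbian_increments(ds, flatten2(xin))
      st$pair$W <- st$pair$W + eta * inc$dW * st$pair$mask_W
      if (urfb) st$pair$R <- st$pair$R + eta * inc$dR * st$pair$mask_R
    } else if (st$kind == "conv") {
      inc <- conv_update_tied(ds, xin, st$geom, xcol = trace$xcol[[s]])
      st$W_bank <- st$W_bank + eta * inc$dW * st$mask_W
      if (urfb) st$R_bank <- st$R_bank + eta * inc$dR * st$mask_R
    } else if (st$kind == "local") {
      inc <- local_update(st$lw, ds, xin)
      st$lw$vals_W <- st$lw$vals_W + eta * inc$dvals * st$lw$mask_W
      if (urfb) st$lw$vals_R <- st$lw$vals_R + eta * inc$dvals * st$lw$mask_R
    }
    net$stages[[s]] <- st
  }
  net
}

#' Classify and measure the error rate
#'
#' The classifier is the argmax over output activities; ties break to the
#' lowest class index. Dropout is disabled.
#'
#' @param net Network.
#' @param dataset List with \code{x} (inputs, batch last) and \code{y}
#'   (integer labels in \code{1..C}).
#' @param batch_size Evaluation batch size.
#' @return Misclassification rate in \code{[0, 1]}.
#' @export
evaluate <- function(net, dataset, batch_size = 500L) {
  n <- length(dataset$y)
  if (n == 0L) stop("empty dataset")
  wrong <- 0L
  for (ix in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    tr <- forward_pass(net, ds_index(dataset$x, ix), train = FALSE)
    pred <- max.col(t(tr$scores), ties.method = "first")
    wrong <- wrong + sum(pred != dataset$y[ix])
  }
  wrong / n
}

mean_loss <- function(net, dataset, mu = 1, batch_size = 500L) {
  eval_metrics(net, dataset, mu, batch_size)$loss
}

# Error rate and mean loss in one evaluation pass (dropout disabled).
eval_metrics <- function(net, dataset, mu = 1, batch_size = 500L) {
  n <- length(dataset$y)
  if (n == 0L) stop("empty dataset")
  wrong <- 0L; tot <- 0
  for (ix in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    tr <- forward_pass(net, ds_index(dataset$x, ix), train = FALSE)
    pred <- max.col(t(tr$scores), ties.method = "first")
    wrong <- wrong + sum(pred != dataset$y[ix])
    l <- if (net$spec$loss == "hinge") hinge_loss(tr$scores, dataset$y[ix], mu)
         else softmax_ce_loss(tr$scores, dataset$y[ix])
    tot <- tot + sum(l)
  }
  list(error = wrong / n, loss = tot / n)
}

# Index the batch (last) dimension of an input container.
ds_index <- function(x, ix) {
  if (is.matrix(x)) return(x[, ix, drop = FALSE])
  d <- dim(x)
  stopifnot(length(d) == 4L)
  x[, , , ix, drop = FALSE]
}

#' Train a network
#'
#' Runs seeded shuffled epochs of the forward / feedback / update loop and
#' records, per epoch, the training and validation error (dropout
#' disabled), the mean training loss, and each trainable layer's alignment
#' correlation between W and the transpose of its feedback matrix. Fully
#' deterministic given the config seed: initialization, dropout, and
#' shuffling each use their own derived stream.
#'
#' @param net Network from [build_network()].
#' @param train_set,val_set Datasets (lists with \code{x}, \code{y});
#'   \code{val_set} may be \code{NULL}.
#' @param config List of training parameters: \code{eta} (default 0.1),
#'   \code{batch_size} (default 500), \code{epochs}, \code{seed},
#'   \code{mu} (default 1), \code{dropout_per_example} (default FALSE),
#'   \code{eval_train} (default TRUE; set FALSE to skip the per-epoch
#'   training-set evaluation and report NA train metrics), \code{verbose}.
#' @return List with the trained \code{network} and a \code{metrics} data
#'   frame (one row per epoch: epoch, train_error, val_error, train_loss,
#'   align_corr_layer_k...).
#' @export
train_network <- function(net, train_set, val_set = NULL, config = list()) {
  eta <- config$eta %||% 0.1
  batch_size <- as.integer(config$batch_size %||% 500L)
  epochs <- as.integer(config$epochs %||% 1L)
  seed <- as.integer(config$seed %||% net$seed)
  mu <- config$mu %||% 1
  per_ex <- isTRUE(config$dropout_per_example)
  eval_train <- config$eval_train %||% TRUE
  verbose <- isTRUE(config$verbose)
  stopifnot(eta >= 0, batch_size >= 1L)
  n <- length(train_set$y)
  tr_idx <- trainable_stages(net)
  rows <- vector("list", epochs)
  if (epochs >= 1L) for (ep in seq_len(epochs)) {
    perm <- with_seed(derive_seed(seed, "shuffle", ep), sample.int(n))
    batches <- split(perm, ceiling(seq_along(perm) / batch_size))
    for (b in seq_along(batches)) {
      ix <- batches[[b]]
      trace <- with_seed(derive_seed(seed, "dropout", ep, b),
        forward_pass(net, ds_index(train_set$x, ix), train = TRUE,
                     dropout_per_example = per_ex))
      fb <- feedback_pass(net, trace, train_set$y[ix], mu)
      net <- apply_updates(net, trace, fb, eta)
    }
    ali <- vapply(tr_idx, function(s)
      alignment_correlation(net$stages[[s]], mode = net$mode), numeric(1))
    names(ali) <- paste0("align_corr_layer_", seq_along(tr_idx))
    em <- if (eval_train) eval_metrics(net, train_set, mu, batch_size)
          else list(error = NA_real_, loss = NA_real_)
    row <- data.frame(epoch = ep,
                      train_error = em$error,
                      val_error = if (is.null(val_set)) NA_real_
                                  else evaluate(net, val_set, batch_size),
                      train_loss = em$loss)
    rows[[ep]] <- cbind(row, as.data.frame(as.list(ali)))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %s  loss %.4f", ep,
                      row$train_error,
                      ifelse(is.na(row$val_error), "-",
                             sprintf("%.4f", row$val_error)),
                      row$train_loss))
  }
  list(network = net,
       metrics = if (epochs >= 1L) do.call(rbind, rows) else
         data.frame(epoch = integer(), train_error = numeric(),
                    val_error = numeric(), train_loss = numeric()))
}
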