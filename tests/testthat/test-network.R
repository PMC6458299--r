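# Assembly, forward/feedback sequencing, update modes.

test_that("build_network: Glorot range, sparsity, determinism", {
  spec <- parse_architecture("Full 20; Output", 30L, 4L, sparsity = 0.5)
  net <- build_network(spec, seed = 5)
  W <- net$stages[[1]]$pair$W
  b <- sqrt(6 / (30 + 20))
  expect_true(all(abs(W) <= b))
  # ~50% pruned (binomial check, 600 entries)
  frac <- mean(net$stages[[1]]$pair$mask_W == 0)
  expect_gt(frac, 0.42); expect_lt(frac, 0.58)
  # masks for W and R are drawn independently (asymmetric connectivity)
  expect_false(identical(net$stages[[1]]$pair$mask_W,
                         t(net$stages[[1]]$pair$mask_R)))
  # determinism
  net2 <- build_network(spec, seed = 5)
  expect_identical(all_W(net), all_W(net2))
  expect_identical(all_R(net), all_R(net2))
  # mirrored init aligns perfectly at step 0
  specm <- parse_architecture("Full 20; Output", 30L, 4L, init = "mirrored")
  netm <- build_network(specm, seed = 5)
  expect_equal(unname(alignment_correlation(netm)), c(1, 1))
})

test_that("forward_pass: clamping, output linearity, zero cases", {
  net <- tiny_dense_net()
  z <- forward_pass(net, matrix(0, 8, 3))
  expect_equal(z$scores, matrix(0, 3, 3))
  set.seed(6)
  x <- matrix(rnorm(8 * 5, sd = 4), 8, 5)
  tr <- forward_pass(net, x)
  expect_true(all(abs(tr$xs[[2]]) <= 1))  # hidden activations clamped
  expect_true(all(abs(tr$xs[[3]]) <= 1))
  # output layer applies no nonlinearity: scores = W_out %*% x_hidden
  expect_equal(tr$scores,
               net$stages[[3]]$pair$W %*% tr$xs[[3]])
})

test_that("feedback_pass: top signal, saturation shut-off, sequencing guard", {
  net <- tiny_dense_net()
  set.seed(7)
  x <- matrix(runif(8 * 4, -0.3, 0.3), 8, 4)
  y <- c(1L, 2L, 3L, 1L)
  tr <- forward_pass(net, x, train = TRUE)
  fb <- feedback_pass(net, tr, y)
  expect_equal(fb$delta[[3]], hinge_top_error(tr$scores, y))
  # evaluation-mode trace is rejected
  expect_error(feedback_pass(net, forward_pass(net, x), y),
               "sequencing violation")
  # saturating every hidden unit kills all lower error signals
  net_sat <- net
  net_sat$stages[[1]]$pair$W <- net_sat$stages[[1]]$pair$W * 1e4
  tr2 <- forward_pass(net_sat, x, train = TRUE)
  fb2 <- feedback_pass(net_sat, tr2, y)
  expect_true(all(fb2$delta[[1]] == 0))
  # satisfied loss -> all-zero top error -> no update anywhere
  big <- net
  tr3 <- forward_pass(net, x, train = TRUE)
  sc <- tr3$scores
  done <- vapply(seq_len(4), function(i) {
    s <- rep(-2, 3); s[y[i]] <- 2; all(hinge_top_error(s, y[i]) == 0)
  }, logical(1))
  expect_true(all(done))
})

test_that("apply_updates respects the three modes", {
  set.seed(8)
  x <- matrix(runif(8 * 6, -0.4, 0.4), 8, 6)
  y <- rep(1:3, 2)
  for (mode in c("bp", "urfb", "frfb")) {
    spec <- parse_architecture("Full 6; Full 4; Output", 8L, 3L, mode = mode)
    net <- build_network(spec, seed = 77)
    R0 <- all_R(net)
    net1 <- one_step(net, x, y)
    if (mode == "urfb") {
      expect_false(identical(all_R(net1), R0))
      # R moved by the transpose of W's increment
      dW <- net1$stages[[2]]$pair$W - net$stages[[2]]$pair$W
      dR <- net1$stages[[2]]$pair$R - net$stages[[2]]$pair$R
      mR <- net$stages[[2]]$pair$mask_R
      expect_equal(dR, t(dW * net$stages[[2]]$pair$mask_W) * mR
                   , tolerance = 1e-12)
    } else {
      expect_identical(all_R(net1), R0)   # frfb fixed; bp ignores R
    }
  }
})

test_that("frfb and urfb share init and first W increment, then diverge via R", {
  set.seed(9)
  x <- matrix(runif(8 * 6, -0.4, 0.4), 8, 6)
  y <- rep(1:3, 2)
  nu <- build_network(parse_architecture("Full 6; Full 4; Output", 8L, 3L,
                                         mode = "urfb"), seed = 12)
  nf <- build_network(parse_architecture("Full 6; Full 4; Output", 8L, 3L,
                                         mode = "frfb"), seed = 12)
  expect_identical(all_W(nu), all_W(nf))
  expect_identical(all_R(nu), all_R(nf))
  nu1 <- one_step(nu, x, y); nf1 <- one_step(nf, x, y)
  expect_identical(all_W(nu1), all_W(nf1))  # first step: same feedback values
  nu2 <- one_step(nu1, x, y); nf2 <- one_step(nf1, x, y)
  expect_false(identical(all_W(nu2), all_W(nf2)))  # R has moved only in urfb
})

test_that("update locality: batch-mean increments are linear per example", {
  net <- tiny_dense_net(mode = "urfb", seed = 21)
  set.seed(10)
  x <- matrix(runif(8 * 4, -0.4, 0.4), 8, 4)
  y <- c(1L, 2L, 3L, 2L)
  tr <- forward_pass(net, x, train = TRUE)
  fb <- feedback_pass(net, tr, y)
  full <- apply_updates(net, tr, fb, eta = 1)
  # zero one example's delta: increment drops by exactly its contribution
  fb0 <- fb
  for (s in seq_along(fb0$delta))
    if (!is.null(fb0$delta[[s]])) fb0$delta[[s]][, 2] <- 0
  part <- apply_updates(net, tr, fb0, eta = 1)
  s <- 1
  contrib <- (fb$delta[[s]][, 2] %o% x[, 2]) / 4
  expect_equal(part$stages[[s]]$pair$W,
               full$stages[[s]]$pair$W - contrib, tolerance = 1e-12)
})

test_that("mask invariance: pruned entries stay exactly zero through training", {
  ds <- linearly_separable_dataset(8, 3, margin = 2, n = 90, seed = 31)
  spec <- parse_architecture("Full 10; Output", 8L, 3L, mode = "urfb",
                             sparsity = 0.5)
  net <- build_network(spec, seed = 31)
  fit <- train_network(net, ds, NULL,
                       list(eta = 0.1, batch_size = 30, epochs = 3, seed = 31))
  for (s in trainable_idx(fit$network)) {
    p <- fit$network$stages[[s]]$pair
    expect_true(all(p$W[p$mask_W == 0] == 0))
    expect_true(all(p$R[p$mask_R == 0] == 0))
    expect_identical(p$mask_W, net$stages[[s]]$pair$mask_W)
  }
})

test_that("evaluate: argmax classification with first-index tie-break", {
  net <- tiny_dense_net()
  # constant zero scores on a balanced 4-way problem -> everything class 1
  spec <- parse_architecture("Output", 4L, 4L)
  nz <- build_network(spec, seed = 1)
  nz$stages[[1]]$pair$W[] <- 0
  ds <- list(x = matrix(rnorm(4 * 40), 4, 40), y = rep(1:4, 10))
  expect_equal(evaluate(nz, ds), 0.75)
  expect_error(evaluate(nz, list(x = matrix(0, 4, 0), y = integer())),
               "empty")
})

test_that("training loop: zero epochs / zero lr / seeded determinism", {
  ds <- linearly_separable_dataset(6, 3, margin = 2, n = 60, seed = 41)
  spec <- parse_architecture("Full 8; Output", 6L, 3L, mode = "urfb")
  net <- build_network(spec, seed = 41)
  f0 <- train_network(net, ds, NULL, list(epochs = 0, seed = 41))
  expect_equal(nrow(f0$metrics), 0)
  expect_identical(all_W(f0$network), all_W(net))
  fz <- train_network(net, ds, NULL, list(epochs = 3, eta = 0, seed = 41))
  expect_equal(length(unique(fz$metrics$train_error)), 1L)
  fa <- train_network(net, ds, NULL,
                      list(epochs = 10, batch_size = 30, seed = 41))
  fb <- train_network(net, ds, NULL,
                      list(epochs = 10, batch_size = 30, seed = 41))
  expect_identical(fa$metrics, fb$metrics)
  # and the hinge rule actually drives a separable task to (near) zero error
  expect_lte(tail(fa$metrics$train_error, 1), 0.02)
})
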