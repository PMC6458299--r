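test_that("satlin clamps to [-1, 1], preserves shape, is idempotent", {
  expect_equal(satlin(c(0.5, 2, -3)), c(0.5, 1, -1))
  m <- matrix(seq(-2, 2, length.out = 6), 2)
  expect_equal(dim(satlin(m)), dim(m))
  set.seed(1)
  h <- array(rnorm(40, sd = 3), c(2, 5, 4))
  expect_identical(satlin(satlin(h)), satlin(h))
  expect_true(all(abs(satlin(h)) <= 1))
})

test_that("satlin_gate is 1 on |h| <= 1 (boundary inclusive), 0 outside", {
  expect_equal(satlin_gate(c(0, 1, -1, 1.5, -2)), c(1, 1, 1, 0, 0))
  # the gate is exactly the set where satlin is locally the identity
  h <- seq(-3, 3, by = 0.25)
  expect_equal(satlin_gate(h), as.double(satlin(h) == h))
})

test_that("hinge loss matches direct evaluation and its zero set", {
  expect_equal(hinge_loss(c(2, -2, -2), 1L, mu = 1), 0)
  expect_equal(hinge_loss(c(0, 0, 0), 1L, mu = 1), 3)
  expect_equal(hinge_loss(c(0.5, -0.5), 1L, mu = 0.5), 0.75)
  # batch form: columns are examples
  sc <- cbind(c(2, -2, -2), c(0, 0, 0))
  expect_equal(hinge_loss(sc, c(1L, 1L)), c(0, 3))
  # zero iff x_c >= 1 and all off-class <= -1
  set.seed(4)
  for (i in 1:50) {
    x <- runif(4, -2, 2); c0 <- sample(4, 1)
    z <- hinge_loss(x, c0) == 0
    expect_identical(z, x[c0] >= 1 && all(x[-c0] <= -1))
  }
  expect_error(hinge_loss(c(0, 0), 3L), "invalid label")
})

test_that("hinge_top_error matches the printed gating rules", {
  expect_equal(hinge_top_error(c(0, 0, 0), 1L, mu = 1)[, 1], c(1, -1, -1))
  expect_equal(hinge_top_error(c(1.5, -1.5), 1L, mu = 1)[, 1], c(0, 0))
  expect_equal(hinge_top_error(c(0.9, -0.9, -2), 1L, mu = 1)[, 1], c(1, -1, 0))
  # boundary values take the nonzero branch
  expect_equal(hinge_top_error(c(1, -1), 1L, mu = 0.5)[, 1], c(1, -0.5))
  # configurable off-class threshold
  expect_equal(hinge_top_error(c(2, -0.4), 1L, mu = 1,
                               off_threshold = -0.5)[, 1], c(0, -1))
  expect_equal(hinge_top_error(c(2, -0.6), 1L, mu = 1,
                               off_threshold = -0.5)[, 1], c(0, 0))
})

test_that("hinge_top_error equals minus the loss gradient off the margins", {
  set.seed(11)
  h <- 1e-6
  for (i in 1:30) {
    x <- runif(5, -2, 2)
    # keep every coordinate away from its margin
    x[abs(x - 1) < 0.05] <- x[abs(x - 1) < 0.05] + 0.1
    x[abs(x + 1) < 0.05] <- x[abs(x + 1) < 0.05] + 0.1
    c0 <- sample(5, 1); mu <- runif(1, 0.2, 2)
    num <- vapply(1:5, function(k) {
      xp <- x; xp[k] <- xp[k] + h
      xm <- x; xm[k] <- xm[k] - h
      (hinge_loss(xp, c0, mu) - hinge_loss(xm, c0, mu)) / (2 * h)
    }, numeric(1))
    expect_equal(hinge_top_error(x, c0, mu)[, 1], -num, tolerance = 1e-4)
  }
})

test_that("hinge_top_error is invariant to joint class/score permutation", {
  set.seed(21)
  x <- runif(6, -2, 2); c0 <- 4L
  d <- hinge_top_error(x, c0)[, 1]
  for (i in 1:10) {
    p <- sample(6)
    dp <- hinge_top_error(x[p], which(p == c0))[, 1]
    expect_equal(dp, d[p])
  }
})

test_that("softmax comparator error is y - p, stable, and sums to zero", {
  expect_equal(softmax_ce_error(c(0, 0), 1L)[, 1], c(0.5, -0.5))
  expect_equal(softmax_ce_error(c(0, 0, 0, 0), 3L)[, 1],
               c(-0.25, -0.25, 0.75, -0.25))
  e <- exp(1)
  expect_equal(softmax_ce_error(c(1, 0), 1L)[, 1],
               c(1 - e / (e + 1), -1 / (e + 1)))
  # large scores do not overflow thanks to max-subtraction
  big <- softmax_ce_error(c(1000, 999, -1000), 2L)
  expect_true(all(is.finite(big)))
  set.seed(5)
  sc <- matrix(rnorm(40, sd = 5), 4)
  expect_equal(colSums(softmax_ce_error(sc, rep(2L, 10))), rep(0, 10))
})
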