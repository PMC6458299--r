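# Max-pooling, dropout, residual sum.

test_that("maxpool takes centered zero-padded window maxima every stride", {
  # constant positive input: constant output
  p <- maxpool_forward(array(2, c(6, 6, 1, 1)), 3, 2)
  expect_equal(dim(p$x), c(3, 3, 1, 1))
  expect_true(all(p$x == 2))
  # single spike at the corner survives into the first retained cell
  x <- array(0, c(4, 4, 1, 1)); x[1, 1, 1, 1] <- 5
  p2 <- maxpool_forward(x, 3, 2)
  expect_equal(p2$x[1, 1, 1, 1], 5)
  expect_equal(p2$argmax[1, 1, 1, 1], 1L)
  # all-negative input: boundary windows see the zero padding
  p3 <- maxpool_forward(array(-1, c(4, 4, 1, 1)), 3, 2)
  expect_equal(p3$x[1, 1, 1, 1], 0)
  expect_true(is.na(p3$argmax[1, 1, 1, 1]))
  # output sizes follow ceiling(H / stride)
  expect_equal(dim(maxpool_forward(array(0, c(32, 32, 2, 1)), 3, 2)$x),
               c(16, 16, 2, 1))
  expect_equal(dim(maxpool_forward(array(0, c(11, 11, 1, 1)), 3, 3)$x),
               c(4, 4, 1, 1))
})

test_that("maxpool agrees with a brute-force window oracle", {
  set.seed(51)
  x <- array(rnorm(7 * 7 * 2 * 2), c(7, 7, 2, 2))
  for (cfg in list(c(3L, 2L), c(3L, 3L), c(2L, 2L))) {
    w <- cfg[1]; s <- cfg[2]; pb <- (w - 1L) %/% 2L
    p <- maxpool_forward(x, w, s)
    ip <- seq(1, 7, by = s)
    for (n in 1:2) for (ch in 1:2) for (a in seq_along(ip)) for (b in seq_along(ip)) {
      vals <- numeric(0); pad <- FALSE
      for (di in 1:w) for (dj in 1:w) {
        ii <- ip[a] + di - 1 - pb; jj <- ip[b] + dj - 1 - pb
        if (ii >= 1 && ii <= 7 && jj >= 1 && jj <= 7)
          vals <- c(vals, x[ii, jj, ch, n])
        else pad <- TRUE
      }
      if (pad) vals <- c(vals, 0)  # zero padding competes at the border
      expect_equal(p$x[a, b, ch, n], max(vals))
    }
  }
})

test_that("maxpool feedback routes to the argmax and accumulates overlaps", {
  x <- array(0, c(4, 4, 1, 1)); x[2, 2, 1, 1] <- 9
  p <- maxpool_forward(x, 3, 2)   # (2,2) wins several overlapping windows
  d <- p$x; d[] <- 1
  back <- maxpool_feedback(d, p$argmax, c(4, 4, 1))
  shared <- sum(p$argmax == 6L, na.rm = TRUE)   # linear index of (2,2)
  expect_gt(shared, 1)                           # genuinely overlapping
  expect_equal(back[2, 2, 1, 1], shared)
  # zero delta -> zero everywhere; mass conservation for valid winners
  expect_equal(maxpool_feedback(d * 0, p$argmax, c(4, 4, 1)),
               array(0, c(4, 4, 1, 1)))
  set.seed(52)
  xr <- array(rnorm(8 * 8 * 2 * 3), c(8, 8, 2, 3))
  pr <- maxpool_forward(xr, 3, 2)
  dr <- array(rnorm(length(pr$x)), dim(pr$x))
  fb <- maxpool_feedback(dr, pr$argmax, c(8, 8, 2))
  expect_equal(sum(fb), sum(dr[!is.na(pr$argmax)]), tolerance = 1e-12)
  expect_error(maxpool_feedback(dr[1:2, , , , drop = FALSE], pr$argmax,
                                c(8, 8, 2)), "stale argmax")
})

test_that("dropout zeroes the stated fraction and blocks feedback", {
  x <- array(1, c(10, 10, 1, 4))
  set.seed(53)
  z <- dropout_apply(x, 0)
  expect_identical(z$x, x)
  expect_true(all(z$mask == 1))
  # statistical rate check over many units
  big <- array(1, c(50, 50, 1, 1))
  surv <- replicate(20, mean(dropout_apply(big, 0.8)$mask))
  expect_equal(mean(surv), 0.2, tolerance = 0.02)
  # per-batch mask is shared across examples; per-example is not
  m <- dropout_apply(x, 0.5)$mask
  expect_equal(m[, , , 1], m[, , , 2])
  me <- dropout_apply(x, 0.5, per_example = TRUE)$mask
  expect_false(identical(me[, , , 1], me[, , , 2]))
  # no rescaling of survivors; dropped units pass no error
  d <- array(rnorm(400), dim(x))
  expect_true(all(dropout_feedback(d, m)[m == 0] == 0))
  expect_equal(z$x[1], 1)
})

test_that("residual sum forwards the sum and copies the error to both", {
  a <- array(rnorm(12), c(2, 3, 2, 1)); b <- array(rnorm(12), c(2, 3, 2, 1))
  expect_equal(residual_sum_forward(a, b), a + b)
  expect_equal(residual_sum_forward(a, b * 0), a)
  d <- array(rnorm(12), c(2, 3, 2, 1))
  fb <- residual_sum_feedback(d)
  expect_identical(fb$delta_a, d)
  expect_identical(fb$delta_b, d)
  expect_error(residual_sum_forward(a, array(0, c(3, 2, 2, 1))), "shapes")
})
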