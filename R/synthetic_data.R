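# Synthetic labeled datasets.
#
# The image generator stamps a distinct small oriented motif per class at
# several jittered positions in each image. That gives the data the one
# statistical property the untied-layer experiments rely on: class-relevant
# local structure is repeated (approximately identically) across spatial
# locations, so independently updated location filters are pulled toward
# the same shape.

class_motif <- function(k, size = 5L) {
  m <- matrix(0, size, size)
  mid <- (size + 1L) %/% 2L
  switch(((k - 1L) %% 6L) + 1L,
    { m[mid, ] <- 1 ; m },                       # horizontal bar
    { m[, mid] <- 1 ; m },                       # vertical bar
    { diag(m) <- 1 ; m },                        # diagonal
    { m[cbind(seq_len(size), size:1)] <- 1 ; m },# anti-diagonal
    { m[mid, ] <- 1; m[, mid] <- 1 ; m },        # cross
    { m[c(1, size), ] <- 1; m[, c(1, size)] <- 1 ; m }) # box
}

#' Generate a toy image classification dataset
#'
#' Each class is defined by a distinct oriented 5x5 motif (bar, diagonal,
#' cross, ...) stamped at a coarse grid of positions, each independently
#' jittered by up to \code{jitter} pixels, plus i.i.d. Gaussian pixel noise;
#' values are clipped to \code{[0, 1]} and no standardization is applied.
#' Classes are exactly balanced and the dataset is bitwise reproducible
#' under its seed.
#'
#' @param n_classes Number of classes (>= 2); default 3.
#' @param image_size Square image side; default 16.
#' @param channels Channels; the motif is stamped in every channel.
#' @param n_per_class Images per class; default 500.
#' @param jitter Maximum stamp displacement in pixels; default 1.
#' @param noise_sd Pixel noise standard deviation; default 0.1.
#' @param seed Integer seed.
#' @return List with \code{x} — array \code{(H, W, C, n)} — \code{y} —
#'   integer labels \code{1..n_classes} — and \code{config}.
#' @export
make_toy_dataset <- function(n_classes = 3L, image_size = 16L, channels = 1L,
                             n_per_class = 500L, jitter = 1L, noise_sd = 0.1,
                             seed = 1L) {
  stopifnot(n_classes >= 2L, n_per_class >= 0L)
  msz <- 5L
  stopifnot(image_size >= msz + 2L * jitter)
  n <- n_classes * n_per_class
  H <- image_size
  # coarse stamp grid: anchors spaced one motif apart, kept off the border
  # by the maximal jitter so every stamp fits entirely inside the image
  anchors <- seq.int(1L + jitter, H - msz + 1L - jitter, by = msz + 1L)
  x <- array(0, c(H, H, channels, max(n, 1L)))
  y <- rep(seq_len(n_classes), each = n_per_class)
  if (n > 0L) with_seed(derive_seed(seed, "data"), {
    motifs <- lapply(seq_len(n_classes), class_motif, size = msz)
    for (img in seq_len(n)) {
      canvas <- matrix(0, H, H)
      for (ai in anchors) for (aj in anchors) {
        di <- if (jitter > 0L) sample.int(2L * jitter + 1L, 1L) - jitter - 1L else 0L
        dj <- if (jitter > 0L) sample.int(2L * jitter + 1L, 1L) - jitter - 1L else 0L
        r <- ai + di; cc <- aj + dj
        canvas[r:(r + msz - 1L), cc:(cc + msz - 1L)] <-
          canvas[r:(r + msz - 1L), cc:(cc + msz - 1L)] + motifs[[y[img]]]
      }
      for (ch in seq_len(channels)) {
        noisy <- canvas + matrix(stats::rnorm(H * H, 0, noise_sd), H, H)
        x[, , ch, img] <- pmin(pmax(noisy, 0), 1)
      }
    }
  })
  if (n == 0L) x <- array(0, c(H, H, channels, 0L))
  list(x = x, y = y,
       config = list(n_classes = n_classes, image_size = image_size,
                     channels = channels, n_per_class = n_per_class,
                     jitter = jitter, noise_sd = noise_sd, seed = seed))
}

#' Linearly separable vector dataset
#'
#' Class means sit at scaled one-hot directions (\code{margin} apart from
#' the origin) with small isotropic Gaussian spread, so the Bayes error is
#' essentially zero. Used for dense-only unit tests of the margin loss.
#'
#' @param n_features Input dimension (>= n_classes).
#' @param n_classes Number of classes.
#' @param margin Scale of the class means (> 0).
#' @param n Total number of examples (balanced as evenly as possible).
#' @param spread Gaussian sd around each mean; default \code{margin / 8}.
#' @param seed Integer seed.
#' @return List with \code{x} (matrix \code{n_features x n}), \code{y},
#'   \code{means}.
#' @export
linearly_separable_dataset <- function(n_features, n_classes, margin, n,
                                       spread = margin / 8, seed = 1L) {
  stopifnot(margin > 0, n_features >= n_classes, n >= 0)
  means <- matrix(0, n_features, n_classes)
  means[cbind(seq_len(n_classes), seq_len(n_classes))] <- margin
  y <- rep_len(seq_len(n_classes), n)
  x <- with_seed(derive_seed(seed, "data"),
    means[, y, drop = FALSE] +
      matrix(stats::rnorm(n_features * n, 0, spread), n_features, n))
  if (n == 0L) x <- matrix(0, n_features, 0L)
  list(x = x, y = y, means = means)
}

#' Stratified train/validation split
#'
#' Seeded, disjoint, class-stratified: within each class a fraction
#' \code{val_fraction} (rounded) is held out.
#'
#' @param dataset List with \code{x} (batch-last) and \code{y}.
#' @param val_fraction Held-out fraction, strictly between 0 and 1.
#' @param seed Integer seed.
#' @return List with \code{train} and \code{val} datasets.
#' @export
split_dataset <- function(dataset, val_fraction, seed = 1L) {
  if (!(val_fraction > 0 && val_fraction < 1))
    stop("val_fraction must be in (0, 1)")
  y <- dataset$y
  val_idx <- with_seed(derive_seed(seed, "data"),
    unlist(lapply(unique(y), function(cl) {
      ix <- which(y == cl)
      sample(ix, round(length(ix) * val_fraction))
    })))
  val_idx <- sort(val_idx)
  tr_idx <- setdiff(seq_along(y), val_idx)
  take <- function(ix) list(x = ds_index(dataset$x, ix), y = y[ix])
  list(train = take(tr_idx), val = take(val_idx))
}

#' Nearest-centroid baseline error
#'
#' Sanity floor showing the toy task is learnable: classifies by pixel-space
#' distance to the class centroids of a training set.
#'
#' @param train_set,test_set Datasets (lists with \code{x}, \code{y}).
#' @return Misclassification rate on \code{test_set}.
#' @export
nearest_centroid_error <- function(train_set, test_set) {
  xm <- flatten2(train_set$x)
  classes <- sort(unique(train_set$y))
  cent <- vapply(classes, function(cl)
    rowMeans(xm[, train_set$y == cl, drop = FALSE]), numeric(nrow(xm)))
  xt <- flatten2(test_set$x)
  d2 <- vapply(seq_along(classes), function(k)
    colSums((xt - cent[, k])^2), numeric(ncol(xt)))
  pred <- classes[max.col(-d2, ties.method = "first")]
  mean(pred != test_set$y)
}
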