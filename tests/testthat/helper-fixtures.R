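# Shared fixtures built in code.

# A tiny dense-only spec/network for oracle checks.
tiny_dense_net <- function(mode = "bp", seed = 7L, init = "independent",
                           sparsity = 0) {
  spec <- parse_architecture("Full 6; Full 4; Output", 8L, 3L, mode = mode,
                             init = init, sparsity = sparsity)
  build_network(spec, seed = seed)
}

# Small toy image set shared across tests (cheap to rebuild; seeded).
small_toy <- function(n_per_class = 60L, seed = 3L) {
  ds <- make_toy_dataset(n_per_class = n_per_class, seed = seed)
  split_dataset(ds, 0.2, seed = seed)
}

# Extract the feedforward weights of every trainable stage as a list.
all_W <- function(net) {
  lapply(trainable_idx(net), function(s) {
    st <- net$stages[[s]]
    if (!is.null(st$pair)) st$pair$W
    else if (!is.null(st$W_bank)) st$W_bank
    else st$lw$vals_W
  })
}

all_R <- function(net) {
  lapply(trainable_idx(net), function(s) {
    st <- net$stages[[s]]
    if (!is.null(st$pair)) st$pair$R
    else if (!is.null(st$R_bank)) st$R_bank
    else st$lw$vals_R
  })
}

trainable_idx <- function(net) {
  which(vapply(net$stages, function(s)
    s$kind %in% c("dense", "output", "conv", "local"), logical(1)))
}

# Central finite-difference gradient of the mean batch hinge loss with
# respect to one stage's dense W (independent oracle for the update rule).
numeric_grad_dense <- function(net, s, x, y, mu = 1, h = 1e-6) {
  W <- net$stages[[s]]$pair$W
  g <- W * 0
  for (k in seq_along(W)) {
    np <- net; np$stages[[s]]$pair$W[k] <- W[k] + h
    nm <- net; nm$stages[[s]]$pair$W[k] <- W[k] - h
    lp <- mean(hinge_loss(forward_pass(np, x)$scores, y, mu))
    lm <- mean(hinge_loss(forward_pass(nm, x)$scores, y, mu))
    g[k] <- (lp - lm) / (2 * h)
  }
  g
}

# One full training step (forward / feedback / update) on a batch.
one_step <- function(net, x, y, eta = 0.1, mu = 1) {
  tr <- forward_pass(net, x, train = TRUE)
  fb <- feedback_pass(net, tr, y, mu)
  apply_updates(net, tr, fb, eta)
}
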