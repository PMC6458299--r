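# Linear-network learning dynamics.
#
# For a linear network y = W_k ... W_1 x with quadratic loss and whitened
# input (X X^t = I), gradient flow couples the factors through the residual
# E = T - W_k...W_1. Replacing the transported transposes by separate
# feedback matrices R_i, updated at rate epsilon times the Hebbian
# increment, interpolates between fixed random feedback (epsilon = 0) and
# the fully updated rule (epsilon = 1). With all W_i started at 0 the
# feedback matrices satisfy R_i(t) = R_i(0) + epsilon * t(W_i(t)) exactly,
# so the flow closes over the W_i alone:
#
#   dW_i/dt = [prod_{j=i+1..k} (R_j(0) + eps t(W_j))] E [t(W_1)...t(W_{i-1})]
#
# The simulator integrates this with explicit Euler steps and records the
# squared error e = tr(E^t E) and the per-layer correlation between W_i and
# t(R_i).

#' Configuration for the linear-dynamics simulator
#'
#' @param dims Layer widths \code{c(n_0, ..., n_k)}; default
#'   \code{c(40, 100, 100, 10)}.
#' @param epsilon Feedback update rate in \code{[0, 1]}: 0 is fixed random
#'   feedback, 1 the fully updated rule.
#' @param sd Entry standard deviation of the random target factors (and of
#'   the random feedback initialization); default 0.2.
#' @param steps Euler steps; default 1000.
#' @param dt Euler step size; default 0.005 (chosen once so the default
#'   configuration converges within the step budget at every epsilon).
#' @param seed Integer seed (target and R(0) draws).
#' @param init \code{"zero"} (W starts at 0; the closed-form R(t) holds) or
#'   \code{"random"} (back-propagation comparator).
#' @return List of class \code{"linear_sim_config"}.
#' @export
linear_sim_config <- function(dims = c(40L, 100L, 100L, 10L), epsilon = 1,
                              sd = 0.2, steps = 1000L, dt = 0.005,
                              seed = 1L, init = c("zero", "random")) {
  init <- match.arg(init)
  stopifnot(length(dims) >= 3L, dt > 0, epsilon >= 0, epsilon <= 1,
            steps >= 0, sd >= 0)
  structure(list(dims = as.integer(dims), epsilon = epsilon, sd = sd,
                 steps = as.integer(steps), dt = dt, seed = as.integer(seed),
                 init = init),
            class = "linear_sim_config")
}

#' Random low-depth factor target
#'
#' \code{T = W*_k ... W*_1} with each factor's entries i.i.d. normal with
#' the given sd; the input covariance is taken as the identity.
#'
#' @param dims Layer widths \code{c(n_0, ..., n_k)}.
#' @param sd Entry standard deviation of each factor.
#' @param seed Integer seed.
#' @return Target matrix \code{n_k x n_0}.
#' @export
make_target <- function(dims, sd = 0.2, seed = 1L) {
  k <- length(dims) - 1L
  with_seed(derive_seed(seed, "data"), {
    Tm <- diag(nrow = dims[1])
    for (i in seq_len(k)) {
      Wi <- matrix(stats::rnorm(dims[i + 1] * dims[i], 0, sd),
                   dims[i + 1], dims[i])
      Tm <- Wi %*% Tm
    }
    Tm
  })
}

# Random feedback initialization, one R_i(0) per factor (R_1 is never used
# to propagate an error but is kept so the diagnostic matches the per-layer
# correlation traces of the experiments).
make_R0 <- function(dims, sd = 0.2, seed = 1L) {
  k <- length(dims) - 1L
  with_seed(derive_seed(seed, "feedback"),
    lapply(seq_len(k), function(i)
      matrix(stats::rnorm(dims[i] * dims[i + 1], 0, sd),
             dims[i], dims[i + 1])))
}

residual <- function(W, Tm) {
  P <- W[[1]]
  for (i in seq_along(W)[-1]) P <- W[[i]] %*% P
  Tm - P
}

#' One explicit-Euler step of the deep linear feedback flow
#'
#' @param state List with \code{W} (list of factor matrices) and \code{R0}
#'   (list of feedback initializations; ignored for \code{bp = TRUE}).
#' @param Tm Target matrix.
#' @param epsilon Feedback update rate.
#' @param dt Step size.
#' @param bp Use plain gradient flow (feedback through \code{t(W)}).
#' @return Updated state.
#' @export
step_deep <- function(state, Tm, epsilon, dt, bp = FALSE) {
  W <- state$W; k <- length(W)
  E <- residual(W, Tm)
  dW <- vector("list", k)
  for (i in seq_len(k)) {
    D <- E
    if (i < k) for (j in k:(i + 1L)) {
      Fj <- if (bp) t(W[[j]]) else state$R0[[j]] + epsilon * t(W[[j]])
      D <- Fj %*% D
    }
    if (i > 1L) for (j in seq_len(i - 1L)) D <- D %*% t(W[[j]])
    dW[[i]] <- D
  }
  for (i in seq_len(k)) W[[i]] <- W[[i]] + dt * dW[[i]]
  state$W <- W
  state
}

#' Integrate the linear feedback dynamics
#'
#' Runs the configured number of Euler steps, recording the squared error
#' \code{e = tr(t(E) E)} and, per layer, the Pearson correlation between
#' \code{W_i} and \code{t(R_i)} where \code{R_i(t) = R_i(0) + epsilon *
#' t(W_i(t))} (for the bp comparator the correlation is 1 by definition and
#' reported as such). A guard aborts with an error if \code{e} exceeds
#' \code{1e6} times its initial value, the symptom of a too-large \code{dt}.
#'
#' @param config A [linear_sim_config()].
#' @param Tm,R0 Optional precomputed target and feedback initialization
#'   (shared across a sweep); defaults derive from the config seed.
#' @return List of class \code{"linear_sim_trace"}: \code{e} (length
#'   steps+1), \code{corr} (matrix (steps+1) x k), \code{W} (final
#'   factors), \code{config}.
#' @export
simulate_linear <- function(config, Tm = NULL, R0 = NULL) {
  stopifnot(inherits(config, "linear_sim_config"))
  dims <- config$dims; k <- length(dims) - 1L
  Tm <- Tm %||% make_target(dims, config$sd, config$seed)
  R0 <- R0 %||% make_R0(dims, config$sd, config$seed)
  bp <- config$init == "random"
  W <- if (bp) {
    with_seed(derive_seed(config$seed, "bp_init"),
      lapply(seq_len(k), function(i)
        matrix(stats::rnorm(dims[i + 1] * dims[i], 0, config$sd),
               dims[i + 1], dims[i])))
  } else {
    lapply(seq_len(k), function(i) matrix(0, dims[i + 1], dims[i]))
  }
  state <- list(W = W, R0 = R0)
  e <- numeric(config$steps + 1L)
  corr <- matrix(NA_real_, config$steps + 1L, k,
                 dimnames = list(NULL, paste0("corr_layer_", seq_len(k))))
  layer_corr <- function(W) {
    if (bp) return(rep(1, k))
    vapply(seq_len(k), function(i)
      safe_cor(W[[i]], t(R0[[i]] + config$epsilon * t(W[[i]]))), numeric(1))
  }
  E0 <- residual(state$W, Tm)
  e[1] <- sum(E0 * E0)
  corr[1, ] <- layer_corr(state$W)
  if (config$steps > 0L) for (t in seq_len(config$steps)) {
    state <- step_deep(state, Tm, config$epsilon, config$dt, bp = bp)
    E <- residual(state$W, Tm)
    e[t + 1L] <- sum(E * E)
    if (!is.finite(e[t + 1L]) || e[t + 1L] > 1e6 * max(e[1], 1e-12))
      stop("numerical blow-up at step ", t, ": dt too large")
    corr[t + 1L, ] <- layer_corr(state$W)
  }
  structure(list(e = e, corr = corr, W = state$W, config = config),
            class = "linear_sim_trace")
}

#' Epsilon sweep of the linear dynamics
#'
#' Integrates one trajectory per epsilon, all sharing the same seeded target
#' and feedback initialization, plus (optionally) the randomly initialized
#' gradient-flow comparator.
#'
#' @param config Base [linear_sim_config()] (its epsilon is ignored).
#' @param epsilons Epsilon values, e.g. \code{c(0, 0.25, 0.5, 1)}.
#' @param include_bp Add the bp comparator trace (named \code{"bp"}).
#' @return Named list of \code{linear_sim_trace} objects
#'   (\code{"eps_<value>"} and optionally \code{"bp"}).
#' @export
sweep_linear <- function(config, epsilons = c(0, 0.25, 0.5, 1),
                         include_bp = TRUE) {
  Tm <- make_target(config$dims, config$sd, config$seed)
  R0 <- make_R0(config$dims, config$sd, config$seed)
  out <- list()
  for (eps in epsilons) {
    cfg <- config; cfg$epsilon <- eps; cfg$init <- "zero"
    out[[paste0("eps_", format(eps))]] <- simulate_linear(cfg, Tm, R0)
  }
  if (include_bp) {
    cfg <- config; cfg$init <- "random"
    out[["bp"]] <- simulate_linear(cfg, Tm, R0)
  }
  out
}

#' Steps needed to reach a relative error threshold
#'
#' @param trace A \code{linear_sim_trace}.
#' @param rel_threshold Fraction of the initial error, default \code{1e-3}.
#' @return First step index (0-based) with \code{e <= rel_threshold * e[0]},
#'   or \code{Inf} if never reached.
#' @export
steps_to_threshold <- function(trace, rel_threshold = 1e-3) {
  hit <- which(trace$e <= rel_threshold * trace$e[1])
  if (!length(hit)) Inf else hit[1] - 1L
}

#' Export a sweep as a long data frame
#'
#' One row per (run, step): run label, step, e, log10(e), and the per-layer
#' correlations.
#'
#' @param traces Result of [sweep_linear()].
#' @return A data frame suitable for CSV export.
#' @export
sweep_to_frame <- function(traces) {
  do.call(rbind, lapply(names(traces), function(nm) {
    tr <- traces[[nm]]
    data.frame(run = nm, step = seq_along(tr$e) - 1L, e = tr$e,
               log_e = log10(pmax(tr$e, .Machine$double.xmin)),
               tr$corr, row.names = NULL)
  }))
}
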