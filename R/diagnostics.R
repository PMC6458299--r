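# Alignment and filter-similarity diagnostics.

#' W-R alignment correlation
#'
#' Pearson correlation between a layer's flattened feedforward weights and
#' the transpose of its feedback weights, the quantity whose growth during
#' training is the feedback-alignment phenomenon. For sparse runs the
#' correlation is restricted to coordinates present in both connectivity
#' masks (absent synapses carry no signal). Degenerate (constant) inputs
#' give 0 by convention. In \code{bp} mode feedback is the transpose of W by
#' construction, so the correlation is 1.
#'
#' @param pair A [weight_pair()], a conv or local network stage, or a whole
#'   \code{hebbnet_network} (returns one value per trainable layer).
#' @param method \code{"pearson"} (default) or \code{"cosine"} (normalized
#'   inner product; the two coincide for mean-zero weights).
#' @param mode Training mode of the owning network; \code{"bp"} short-cuts
#'   to 1.
#' @return Correlation(s) in \code{[-1, 1]}.
#' @export
alignment_correlation <- function(pair, method = c("pearson", "cosine"),
                                  mode = NULL) {
  method <- match.arg(method)
  if (inherits(pair, "hebbnet_network")) {
    idx <- trainable_stages(pair)
    return(vapply(idx, function(s)
      alignment_correlation(pair$stages[[s]], method, pair$mode), numeric(1)))
  }
  if (identical(mode, "bp")) return(1)
  corfun <- if (method == "cosine") {
    function(a, b) {
      na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
      if (na == 0 || nb == 0) 0 else sum(a * b) / (na * nb)
    }
  } else safe_cor
  if (inherits(pair, "weight_pair")) {
    keep <- (pair$mask_W == 1) & (t(pair$mask_R) == 1)
    return(corfun(pair$W[keep], t(pair$R)[keep]))
  }
  if (inherits(pair, "local_weights")) {
    keep <- pair$mask_W == 1 & pair$mask_R == 1
    return(corfun(pair$vals_W[keep], pair$vals_R[keep]))
  }
  if (is.list(pair) && !is.null(pair$kind)) {
    if (pair$kind %in% c("dense", "output"))
      return(alignment_correlation(pair$pair, method))
    if (pair$kind == "conv") {
      keep <- (pair$mask_W == 1) & (pair$mask_R == 1)
      return(corfun(pair$W_bank[keep], pair$R_bank[keep]))
    }
    if (pair$kind == "local")
      return(alignment_correlation(pair$lw, method))
  }
  stop("alignment_correlation: unsupported object")
}

#' Cross-location filter similarity of an untied layer
#'
#' Reconstructs the local filter (tap vector) of an untied locally connected
#' layer at each requested interior grid location and returns their pairwise
#' Pearson correlation matrix. A layer freshly replicated from a filter bank
#' scores exactly 1 everywhere; independently updated locations that remain
#' correlated after training indicate that the data's local statistics are
#' translation-consistent.
#'
#' @param lw A [local_weights()] object (or a local network stage).
#' @param locations List (or 2-column matrix) of \code{c(i, j)} interior grid
#'   locations; boundary locations with truncated windows are rejected.
#' @param channel Output channel to extract, or \code{NULL} for all channels
#'   concatenated.
#' @return Symmetric correlation matrix, one row/column per location.
#' @export
filter_similarity <- function(lw, locations, channel = NULL) {
  if (is.list(lw) && !is.null(lw$kind) && lw$kind == "local") lw <- lw$lw
  stopifnot(inherits(lw, "local_weights"))
  if (is.matrix(locations))
    locations <- lapply(seq_len(nrow(locations)), function(k) locations[k, ])
  filt <- lapply(locations, function(p)
    filter_at_location(lw, p[1], p[2], channel = channel))
  m <- length(filt)
  out <- diag(1, m)
  for (a in seq_len(m)) for (b in seq_len(m)) if (a < b)
    out[a, b] <- out[b, a] <- safe_cor(filt[[a]], filt[[b]])
  dimnames(out) <- rep(list(vapply(locations, paste, "", collapse = ",")), 2)
  out
}

#' Permutation test for mean cross-location filter similarity
#'
#' Tests whether the mean pairwise correlation between an untied layer's
#' location filters exceeds chance, by independently permuting each
#' location's tap vector and recomputing the statistic.
#'
#' @inheritParams filter_similarity
#' @param n_perm Number of permutations.
#' @param seed Seed for the permutation draws.
#' @return List with \code{statistic} (observed mean off-diagonal
#'   correlation), \code{p_value}, and \code{perm_stats}.
#' @export
filter_similarity_test <- function(lw, locations, channel = NULL,
                                   n_perm = 499, seed = 1L) {
  if (is.list(lw) && !is.null(lw$kind) && lw$kind == "local") lw <- lw$lw
  if (is.matrix(locations))
    locations <- lapply(seq_len(nrow(locations)), function(k) locations[k, ])
  filt <- lapply(locations, function(p)
    filter_at_location(lw, p[1], p[2], channel = channel))
  mean_offdiag <- function(fl) {
    m <- length(fl); tot <- 0; k <- 0
    for (a in seq_len(m)) for (b in seq_len(m)) if (a < b) {
      tot <- tot + safe_cor(fl[[a]], fl[[b]]); k <- k + 1
    }
    tot / k
  }
  obs <- mean_offdiag(filt)
  perm <- with_seed(derive_seed(seed, "other"), vapply(seq_len(n_perm),
    function(i) mean_offdiag(lapply(filt, sample)), numeric(1)))
  list(statistic = obs,
       p_value = (1 + sum(perm >= obs)) / (1 + n_perm),
       perm_stats = perm)
}
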