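---
title: "Training networks with asymmetric feedback and Hebbian updates: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Training networks with asymmetric feedback and Hebbian updates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Back-propagation computes each layer's error signal with the *transpose of
the feedforward weight matrix*. In a physical neural system the feedback
synapses carrying that signal are distinct from the feedforward synapses, so
exact transposition ("weight transport") is implausible. `hebbnet`
implements a family of trainers that keep a *separate* feedback matrix
`R_l` per layer and differ only in what happens to it:

* **bp** — feedback through `t(W_l)`: exact back-propagation (reference).
* **frfb** — `R_l` fixed at a random initialization (feedback alignment).
* **urfb** — `R_l` initialized at random but updated with the *same
  Hebbian increment* as its feedforward counterpart: both synapses connect
  the same pair of units, hence see the same pre-synaptic activity
  `x_{l-1,j}` and post-synaptic (top-down) activity `delta_{l,i}`, and both
  move by `eta * mean_batch(delta_{l,i} * x_{l-1,j})`.

If `R(0) = t(W(0))`, the urfb rule preserves `R = t(W)` exactly and the
system *is* back-propagation; with independent initialization it is not,
yet (the phenomenon the package reproduces at desk scale) it tracks bp
closely while frfb degrades as depth grows.

## Model components

**Activation.** All hidden trainable layers use the saturated linearity
`satlin(h) = min(max(h, -1), 1)`. Its derivative gate is 1 on `|h| <= 1`
(boundary inclusive) and 0 otherwise: a saturated unit
transmits no error. The output layer applies no nonlinearity.

**Loss.** The default loss is the one-vs-all margin (hinge) loss
`L = max(1 - x_c, 0) + mu * sum_{i != c} max(1 + x_i, 0)` with margin fixed
at 1 and off-class weight `mu` (default 1: `mu` balances the one-vs-all
terms and has no canonical value, so equal weighting is the neutral
choice). Its top-layer error signal is local — unit `i` needs only
its own input and the teaching signal: `+1` if `i` is the target class and
`x_i <= 1`, `-mu` if `i` is a wrong class and `x_i >= -1`, else 0.
Boundary values take the nonzero branch. The off-class gate threshold is
`-1` (the exact derivative of the loss above, independent of `mu`); a
variant reading that gates at `-mu` is reachable through the
`off_threshold` argument. A
softmax/cross-entropy comparator (`loss = "softmax"`) is provided; it is
*not* a local computation and exists only as a reference.

**Sequencing.** Learning is strictly phase-ordered: a full bottom-up pass;
then, top-down, each layer's error signal is computed from the layer above
*before* anything below moves, while the *feedforward* activities of the
layer below are still in place to serve as the pre-synaptic factors of the
update. `feedback_pass()` computes every `delta_l` with the pre-update
weights; `apply_updates()` then applies all increments. Calling
`feedback_pass()` on an evaluation-mode trace is an error.

**Layers.** Dense, tied convolution ("same" zero padding, implemented with
an im2col patch matrix so forward/feedback/update are plain matrix
products), untied locally connected (the convolution's sparse connectivity
pattern with independently stored and updated entries — `Matrix` sparse
matrices with a fixed pattern), max-pooling (window `w`, zero padding,
retained every `stride` pixels; error routed winner-take-all to the
recorded argmax, overlapping windows accumulating by sum), dropout (a
fraction `rate` of units zeroed; the mask is drawn once per batch and
shared by its examples (one random subset of units per training batch);
per-example masks are available; no rescaling of survivors, and evaluation
disables dropout entirely), and a parameter-free residual SUM stage.

## Parameters that matter

| parameter | default | meaning / rationale |
|---|---|---|
| `eta` | 0.1 | SGD step; the reference protocol's value, no momentum/adaptivity |
| `batch_size` | 500 | reference protocol's batch size |
| `mu` | 1 | hinge off-class weight; equal class weighting |
| `sparsity` | 0 | fraction of connections fixed at 0, drawn *independently* for W and R (asymmetric connectivity) |
| init `b_l` | `sqrt(6/(fan_in+fan_out))` | Glorot uniform range; conv layers use kernel-area fans |
| dropout rates | per architecture string | taken verbatim from the architecture listings |

Batch increments are *averaged* over the batch (not summed) so `eta = 0.1`
behaves comparably across batch sizes — the robust convention. `hebbian_increments(..., average = FALSE)`
restores summing.

## Numerical and tie-break choices

* Max-pool ties break to the first candidate in row-major window scan
  order; a window whose maximum is the zero padding (all-negative inputs at
  a border) records no winner and passes no error. Both behaviors are
  deterministic consequences of the zero-padding convention.
* argmax classification ties break to the lowest class index.
* Alignment correlation is Pearson over flattened `W_l` vs `t(R_l)`,
  restricted to coordinates present in both connectivity masks, 0 by
  convention for degenerate inputs; a cosine variant is available
  (`method = "cosine"`) — the two coincide for mean-zero weights. In bp
  mode the correlation is 1 by construction.
* "Maxpool 3" without a stride annotation means window 3, stride 2 (every
  second pixel retained, halving the grid); explicit strides are honored.
* Untied layers initialize each location's weights independently (Glorot
  with the convolution's fans). A replicated-from-bank initialization is
  available via `conv_to_local()`; tests that measure emergent filter
  similarity must *not* start replicated, or the similarity would be
  trivial.

## Linear-network dynamics

For a linear network `y = W_k ... W_1 x`, quadratic loss and whitened
input, gradient flow on the factors couples them through the residual
`E = T - W_k...W_1`. Replacing transposes with feedback matrices updated at
rate `epsilon` times the Hebbian increment and starting every `W_i` at 0
gives the closed system integrated by `simulate_linear()`:
`R_i(t) = R_i(0) + epsilon * t(W_i(t))` exactly, and `epsilon = 0 / 1`
recover the fixed / fully-updated feedback rules, with larger `epsilon`
converging faster. We integrate with explicit Euler steps, `dt = 0.005`,
chosen once so that the reference configuration (dims 40/100/100/10,
factor sd 0.2) reaches `e <= 1e-3 * e(0)` well within the 1000-step budget
for every `epsilon`, and frozen; a guard aborts if `e` grows by 1e6x
(too-large `dt`). The reference experiment reports an iteration budget without a step
size, so the `dt x steps` mapping is a package choice, not an empirical
claim. `R_i(0)` entries are drawn i.i.d. normal with the same sd as the
target factors (0.2); the bp comparator initializes its `W_i(0)` the same
way. A feedback matrix is materialized for *every* factor including the
first (whose feedback is never used to propagate an error) because the
per-layer correlation diagnostics track all layers.

One observed limit worth knowing: the final top-layer correlation in this
setting plateaus around 0.96–0.99 (rising with `epsilon`) rather than
passing 0.99 for every `epsilon`; the correlation freezes as soon as the
error reaches zero, and for `epsilon = 0` its limit is scale-invariant in
`R(0)`, so no parameter choice pushes it higher. The acceptance test that
demands `> 0.99` for all `epsilon` is therefore expected to stay red; it
is kept as written rather than weakened.

## What the synthetic data does and does not establish

`make_toy_dataset()` emulates exactly one property of natural images that
the experiments rely on: class-discriminative *local* structure repeated
(approximately identically) across spatial positions — each class's 5x5
oriented motif is stamped at a coarse grid of jittered anchors, plus
i.i.d. Gaussian pixel noise, clipped to [0, 1] and not standardized.
Defaults (16x16x1, 3 classes, 500 images/class, jitter 1, noise sd 0.1)
were fixed once so that a one-CPU run finishes in minutes and a
nearest-centroid baseline solves the task (<10% error) — the experiments
need a *learnable* task, not a hard one. The generator does not model
natural-image statistics, occlusion, scale or class overlap; consequently
a green desk-scale test establishes that the learning rules behave
relatively as described (urfb ~ bp; frfb slower and worse under depth),
not that absolute error rates transfer to real datasets. Because the toy
task is linearly separable, *converged* error rates saturate at 0 for all
modes given enough updates; the mode comparison is therefore run at the
reference protocol (batch 500, 30 epochs) where the budget of updates is
comparable to the scaled experiment and differences remain visible, and
the deeper-net comparison uses the heavier mid-network dropout (0.8) of
the deeper reference architectures.

## Reproducibility

One run seed fans out, via a fixed integer hash, to named streams (init /
mask / dropout / shuffle / data), so e.g. toggling dropout does not shift
initialization randomness and matched-seed runs across modes share
`W(0)`, `R(0)`, shuffles and dropout masks exactly. Checkpoints and run
manifests make a run bitwise reproducible; checkpoints are RDS files (no
HDF5 bindings are assumed in the target environment) and round-trip
double-precision weights bit-exactly.

## Known limitations

* Pure-R execution: desk-scale problems only; the reference CIFAR-scale
  architectures parse and run but 1,000-epoch replication is out of scope.
* Stride-1 "same"-padded convolutions only; no normalization layers (by
  design — the learning rule avoids them), no momentum or adaptive steps.
* The local-circuit neuron model for computing the thresholded top-layer
  signal in biological hardware is out of scope; the signal is computed
  arithmetically.
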