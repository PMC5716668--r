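---
title: "Estimating transmembrane currents on a known morphology: methods and design"
author: "skcsd package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating transmembrane currents on a known morphology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skcsd)
```

## The problem

An extracellular electrode records a weighted sum of all transmembrane
currents flowing in the surrounding tissue. When the recorded potential is
dominated by a single neuron whose three-dimensional morphology and position
relative to the electrode array are known — for example a patched, dye-filled
cell next to a multielectrode array — one can ask a much sharper question
than classical current source density (CSD) analysis does: *where on this
particular cell* do the current sinks and sources sit at each moment in
time?

This package implements the single-cell kernel CSD (skCSD) estimator for
that inverse problem. Given

1. a morphology (SWC file or generated test cell),
2. electrode positions (arbitrary 3-D layout), and
3. an electrodes-by-time matrix of potentials,

it returns the current density along the cell, per segment and per time
point, together with the validation machinery (ground-truth generators,
error metrics, cross-validation, parameter search) needed to decide how far
the result can be trusted for a particular setup.

## The model

### Morphology loop

The cable is treated as one-dimensional: dendrite thickness is ignored and
currents live on the centre line. To parametrize a branched tree with a
single coordinate, the tree is covered by a closed walk — the *morphology
loop* — that starts at the soma, traverses every edge exactly twice (once
per direction), and returns to the soma: a tree special case of the Chinese
postman problem. Arc length `s` along this walk ranges over `[0, l)` with
`l` exactly twice the summed branch length. Dendritic tips are turning
points visited once; ordinary points are covered twice; branch points more
often. The inverse map is unique: each `s` corresponds to exactly one
physical point.

The walk is realized as a depth-first traversal with unvisited neighbours
preferred and children taken in ascending segment id, which makes the loop
deterministic and reproducible. The curve through space is piecewise-linear
through the segment endpoints by default — exactly testable — with an
optional periodic smoothing-spline mode (`build_loop(tree, spline = TRUE)`)
for users who prefer a differentiable curve; the two coincide at every
traversal breakpoint.

### Basis, forward model, kernels

`M` Gaussian basis functions of width `R`,

> b_i(s) = exp(−d(s, s_i)² / R²),

are centred uniformly on the loop, with `d` the circular (modulo-`l`)
distance so coverage is seamless across the seam. Each basis source induces
an extracellular potential by the line integral of a point-source kernel in
an infinite homogeneous medium of conductivity σ:

> b_i(x) = 1/(4πσ) ∫ b_i(s) / |x − f(s)| ds,

evaluated by the midpoint rule. From these the electrode-space Gram matrix
`K[j,k] = Σ_i b_i(x_j) b_i(x_k)` and the cross-kernel
`K~(s, x_k) = Σ_i b_i(s) b_i(x_k)` are assembled. Estimation is kernel
ridge regression per time point:

> C(s) = K~ᵀ(s) (K + λI)⁻¹ V,

with `V` the measured potentials. The method is local in time — each column
of `V` is solved independently, with one Cholesky factorization of
`(K + λI)` shared across all time points. Finally the loop CSD is folded
back onto the cell: the currents of all arc-length samples mapped to a
segment are summed (both traversals contribute), which conserves the total
estimated current exactly. Outputs carry explicit units: per-segment
current in nA and line density in nA/µm of cable; both are reported because
visualization conventions differ.

## Parameters that matter

| parameter | meaning | default | notes |
|---|---|---|---|
| `M` | number of basis sources | 512 | at least twice the electrode count; more is harmless (cost is linear in `M`) |
| `R` | basis width, µm | grid `{8, 16, 32, 64, 128}` | sets the finest recoverable spatial scale |
| `λ` | ridge penalty | grid `{1e-5 … 1e-1}` | trades data fit against noise amplification |
| `σ` | conductivity, S/m | 0.3 | typical grey-matter value; configurable, recorded in every manifest |
| `Δs` | quadrature step, µm | `min(R/10, l/4096)` | resolves the Gaussian; halving `Δs` reduces quadrature error ~4× |

A deliberate unit convention underlies the `λ` grid: kernels are assembled
internally in SI units (volts per unit A/m source density), which puts
`‖K‖` at order 1–100 and makes the conventional decade grid span exactly
the under- to over-regularized regimes. The user-facing contract remains
µm / µV / nA/µm; `skcsd_estimate()` converts at its boundary. Had the
kernels been assembled on the µV scale, `‖K‖` would be ~10⁹ and every
`λ ≤ 0.1` would be numerically indistinguishable from zero.

## Choosing R and λ

Two selection routes are provided, mirroring how the method is used in
practice:

* **Leave-one-out cross-validation** (`loocv_error`, `grid_search`):
  electrode `k` is removed, the potential at its position is predicted by
  kernel interpolation from the other `N − 1` contacts with the same `λ`,
  and squared prediction errors are summed over electrodes and time.
  Because the basis does not depend on the electrode set, each fold reuses
  submatrices of the full `K`, making LOO cheap (`N` small solves). The
  error is reported raw, normalized by `N` (comparable across array
  sizes), and as a per-sample mean. Held-out prediction by kernel
  interpolation is the natural choice consistent with the estimator; the
  sum-over-time convention matches the L1 metric below.
* **Model-based selection with simulated ground truth** (`grid_search`
  with `truth`): simulate plausible current distributions on the same
  morphology and setup, and pick the `(R, λ)` minimizing the L1
  reconstruction error, optionally selecting on an initial time window and
  validating on the remainder (`train_idx`). On noisy recordings CV tends
  to over-smooth relative to the L1-optimal choice, which is why the
  model-based route is recommended whenever a morphology is available —
  it also shows which features of the truth survive reconstruction.

Ties in the grid are broken deterministically towards the smallest `λ`,
then the smallest `R`.

### Reconstruction error

Estimates are compared with ground truth by the normalized L1 distance
`Σ|C − C*| / Σ|C|` over segments and time. Because kernel interpolation can
only return a coarse-grained estimate, the (typically spiky) ground truth
is first convolved circularly along the loop with a mass-conserving
Gaussian kernel `exp(−d²/w²)` — the same functional convention as the basis
— with `w = 15` µm for the straight test cell and 30 µm for branched cells.

## The synthetic-data generator

All validation runs on data the package generates itself:

* **Morphologies**: a 516 µm / 53-segment ball-and-stick cable (a 500 µm /
  52-segment variant is available), and an 848 µm / 86-segment Y-shaped
  cell (32-segment stem, two 27-segment branches at ±30°) whose segments
  33 and 62 — the canonical synapse targets — lie on different branches
  close to the branch point. Arbitrary SWC files can be substituted.
* **Electrode layouts**: laminar probes (600 µm extent, 50 µm offset),
  rectangular grids, hexagonal lattices with exact nearest-neighbour
  pitch, and seeded uniform-random layouts.
* **Current patterns**: cosine modes `A cos(2πfx/L)` with `A = 0.15`
  nA/µm and `f` up to 12.5 cycles per cell length (the spatial-resolution
  probe), and synaptic-event dynamics — step-on/exponential-decay sinks
  (`τ = 2` ms) with the return current spread over the remaining segments
  in proportion to membrane area so that the total membrane current is
  zero at every instant, as charge conservation requires of a real cell.
  The default event amplitude is 1 nA (the order of magnitude of a 0.04 µS
  synapse at a ~25 mV driving force).
* **Forward model and noise**: potentials follow from the same
  point-source physics as the estimator's forward map but through an
  independent brute-force path (`oracle_potential`), with each segment's
  current spread uniformly along its two loop traversals. Gaussian white
  noise is calibrated so that SNR = sd(clean)/sd(noise), the levels
  studied being 16, 4 and 1. All generators are pure functions of their
  parameters and seed, and leave the caller's RNG state untouched.

What the generator deliberately does **not** emulate: cable-equation
membrane dynamics (no NEURON/LFPy biophysics — the return-current rule is
a stated surrogate, not a model of propagation), electrode surface
averaging, tissue inhomogeneity or slice boundary effects, and correlated
background from other cells. Passing tests therefore demonstrate the
correctness and conditioning of the *inverse machinery* under the stated
forward physics, not robustness to biological model mismatch; the
biophysical membrane parameters conventionally used for such simulations
(axial resistance 123 Ω·cm, membrane resistivity 30000 Ω·cm², capacitance
1 µF/cm², passive reversal −65 mV) are documented here for users who wish
to connect an external simulator.

## Numerical choices

* **Quadrature**: midpoint rule on a uniform grid that divides `l` exactly;
  `Δs = min(R/10, l/4096)` resolves the narrowest default basis. Empirical
  convergence is second order.
* **Singularity handling**: a 1 µm distance floor between electrodes and
  the curve — a line-source model is ill-posed below about one cable
  radius. Strict mode (default) raises an error naming the offending
  contacts; lenient mode clamps the distance and warns.
* **Solver**: Cholesky on `(K + λI)` with iterative refinement to a
  relative residual of 1e-8; if the conditioning floor (`ε·κ`) of a very
  small `λ` prevents that, the solver warns with the achieved residual
  rather than aborting a grid search. `λ = 0` on a numerically singular
  system is an error suggesting `λ > 0`.
* **Degenerate inputs**: zero-length segments, detached children, multiple
  roots and parent cycles are structural errors at parse time; all-zero
  ground truth is rejected by the L1 metric (undefined normalization);
  zero-variance recordings are rejected by the noise generator.
* **Determinism**: loop construction, grid tie-breaks and all file outputs
  are deterministic; every stochastic generator takes an explicit seed.

## Validation protocols and problem sizes

The shipped protocols (also used by the test suite and
`scripts/acceptance.R`) are scaled to run on a single CPU in seconds to a
couple of minutes:

* `protocol_cosine_resolution()` — 25 spatial frequencies × laminar probes
  of 8 and 128 contacts, best-of-grid L1 per pattern. The error rises
  monotonically with `f` for 8 electrodes (Spearman ρ ≈ 0.96) while 128
  electrodes reconstruct far higher modes — the discrete-sampling
  resolution limit of the method.
* `protocol_noise_curve()` — Y-shape two-synapse dynamics (140 time
  points), 4 × 8 grid, SNR ∈ {∞, 16, 4, 1}, five seeds each; mean L1
  degrades monotonically with noise.
* `protocol_cv_lambda()` — noiseless/SNR-4 twins; the CV-optimal `λ` is
  larger on the noisy twin in essentially all repetitions, i.e.
  regularization responds to noise as it should.

## Experimental preprocessing

For paired intra-/extracellular recordings, `sta_pipeline()` implements the
standard chain: spike detection on the intracellular trace by upward 0 mV
threshold crossing (1 ms refractory merge against chatter), exclusion of
broken channels, drift removal by subtracting a centred 100 ms moving
average, temporal smoothing with a centred 0.15 ms moving average, and
spike-triggered averaging of ±5 ms windows (edge-clipped windows dropped
with a count). Centred windows that shrink at the trace edges were chosen
for zero phase delay; whether the original analyses centred their windows
is not documented, but for spike-triggered averages, where timing is
meaningful, zero phase is the defensible choice. The result is a
`recording_set` whose time axis is the STA window, ready for
`skcsd_estimate()`.

## Known limitations

* Homogeneous, isotropic, purely resistive extracellular medium; no
  correction for slice/saline boundaries or electrode geometry.
* The morphology is trusted as given; errors in the reconstruction of the
  cell or its registration to the array propagate directly into the
  estimate.
* Estimates are linear in the data and unconstrained: no positivity or
  per-time zero-sum constraint is imposed, so unbalanced current estimates
  are possible (and diagnostic of model mismatch).
* Which reconstructed features are reliable for a *given* setup must be
  established by simulation on that setup (the model-based route above);
  a singular-vector analysis of the estimation operator would make this
  systematic but is not implemented here.
* Separating the target cell's contribution from background (spike-triggered
  averaging aside) is out of scope.

## A minimal end-to-end run

```{r example}
tree <- make_y_shape()
loop <- build_loop(tree)
electrodes <- electrode_layout("grid", nx = 4, ny = 8, pitch_x = 87,
                               pitch_y = 84, center = c(0, 295), z_plane = 50)
times <- seq(0.5, 70, by = 0.5)
truth <- synaptic_csd(tree, y_shape_events(tree), times)
rec <- add_noise(forward_simulate(truth, loop, electrodes, times = times),
                 snr = 16, seed = 1)
kset <- build_kernels(basis_config(M = 512, R = 8, l = loop$l),
                      loop, electrodes)
est <- skcsd_estimate(kset, rec, lambda = 0.01)
l1_error(est$segment_current, smooth_ground_truth(truth, loop, width = 30))
```
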