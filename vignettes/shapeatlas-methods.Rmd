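---
title: "Atlas construction and evaluation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atlas construction and evaluation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

An anatomical atlas summarizes a sample of segmented organ shapes. A
*probabilistic* atlas assigns every voxel `x` the probability `p(x)` of
belonging to the organ; a *statistical* atlas is a mean binary shape plus
PCA modes of variation. Both require the sample to be coregistered first,
and the choice of the geometric registration model changes the atlas in a
way that is easy to underestimate: very flexible registration makes the
aligned shapes nearly identical, which *removes* the inter-subject
variability the atlas is supposed to encode. `shapeatlas` implements three
atlas estimators, four registration models and an evaluation harness built
to measure exactly this effect.

# Models

## Random-set formulation

The sample shapes are treated as realizations `phi_1, ..., phi_n` of a
random compact set inside a common window `W` (the voxel grid). The
classical estimator of `p(x)` is the **normalized coverage function**
(`ncf_atlas()`):

    p_hat(x) = (1/n) * sum_i 1_{phi_i}(x)

It is unbiased but estimates every voxel in isolation, so its level sets
are rough. (As a practical note, the coverage estimator is sometimes
written without the `1/n` factor; the normalized form is the one that is a
probability and the one implemented here.)

## Signed distance and the GLM atlas

`signed_distance()` computes the exact voxel-centre signed Euclidean
distance (negative inside, positive outside, mm, anisotropic spacing).
On a lattice no voxel lies exactly on the boundary, so the 0-level of the
distance lives between voxel layers; the convention "inside strictly
negative, outside strictly positive" is the standard exact-EDT one and is
what the test oracles assert. The per-voxel average over the sample,
`d*(x)` (`mean_distance()`), is smooth; thresholding it at 0 gives the
Baddeley–Molchanov mean shape (`mean_shape_bm()`).

The GLM atlas (`glm_atlas()`) assumes `p(x) = F(beta' v(d*(x)))` with `F`
the logistic cdf and `v` a polynomial basis, by default linear
`v = (1, d*)`; a quadratic option exists but changes little. At each voxel
`x0`, `beta` is estimated by maximizing a *local pseudolikelihood*: the
Bernoulli loglikelihood of all coverage indicators `1_{phi_i}(x_j)` at
grid points `x_j` near `x0`, each term multiplied by a tricube kernel
weight `K(||x_j - x0||/h)`, `K(u) = (70/81)(1-|u|^3)^3`. (Written as a
product in front of the likelihood the weight would drop out of the
argmax; the multiplicative-per-term form is the standard local-likelihood
one and is what is implemented.) The atlas value is
`logistic(beta_hat(x0)' v(d*(x0)))`.

### Parameters that matter

* `band_halfwidth` (mm, default 3 x max spacing): fits are only computed
  in the band `|d*| <= band_halfwidth`. Outside it every indicator is
  constant (all shapes agree), so the atlas is clamped to `1 - eps` (deep
  inside) or `eps` (far outside). The band is both a computational and a
  statistical statement: the transition zone is where the data carry
  information. Points entering a fit are also restricted to the band —
  out-of-band points are label-constant and would only anchor the tails
  of the curve.
* `span` (default 0.7) or `bandwidth` (mm): the tricube bandwidth. The
  span rule sets `h(x0)` to the distance of the `ceil(span * B)`-th
  nearest in-band voxel (B = band size), i.e. a near-global neighbourhood
  — each fit pools most of the transition band, which is what gives the
  GLM atlas its smoothness. There is no published default value for this
  bandwidth; 0.7 follows the convention of local-regression software and
  is exposed in `glm_config()`.
* `eps` (default 1e-3): probability clamp; also the value reported for
  pure-label (separated) neighbourhoods, where the unpenalized MLE would
  diverge.
* Optimizer: damped Newton with step halving on the concave
  loglikelihood, `tol = 1e-8`, `max_iter = 100`.

### The band engine

A naive implementation runs one Newton solve per band voxel over up to
`span * B` neighbours per iteration. The compiled engine instead
discretizes `d*` into `nbins` bins (default 512, about 0.02 mm at default
settings): one pass per voxel accumulates tricube-weighted coverage
counts per bin (spatial weights are *exact*), then Newton runs on the
binned sufficient statistics. `fit_local_logistic()` is the exact,
unbinned reference implementation; the suite checks the engine against it
(agreement at 1e-3 on probabilities) and against a generic optimizer
(1e-4 on coefficients).

## Statistical atlas

`statistical_atlas()` builds the comparison statistical shape atlas from
binary inputs, which have no landmarks of their own:

1. **Semi-landmarks**: each shape is sliced along x, y, z at equal
   fractions of its own bounding extent; per slice the longest closed
   boundary contour is sampled at equal arclength fractions. The start
   point (smallest second, then first, in-slice coordinate) and CCW
   orientation make the parameterization deterministic, so the i-th
   landmark is geometrically comparable across cases. Per-slice counts
   are `max(3, round(density * mean contour length))`, shared across the
   population.
2. **PCA** over the stacked landmark coordinates gives the mean and
   orthonormal modes (`fit_shape_model()`).
3. **Reconstruction**: the mean landmarks are rasterized and dilated by
   one voxel into a barrier shell; `viscous_reconstruction()` grows a
   seed by repeated {dilate 1; open with ball(r); intersect with the
   allowed region}, so the front cannot leak through gaps narrower than
   the opening ball. Run from an inner seed and (inverted) from an outer
   window-corner seed, the two reconstructions bracket the surface; the
   final binary atlas is their Baddeley–Molchanov mean, which is always
   sandwiched between them.

Defaults: 8 slices per axis, opening radius 2 voxels, and a density of
one landmark per voxel of contour length (`1/min(spacing)`). Density is a
lattice-scale property: the rasterized shell must be watertight with
respect to the opening ball, so the default follows the voxel size rather
than a fixed per-mm value; sparser shells let the two growths meet
through the mesh holes and break the inner/outer sandwich. The iteration order in the literature is sometimes
quoted as {open; dilate; intersect}; a single-voxel seed does not survive
such an opening, so the implementation dilates first (and seeds are
pre-dilated by `r + 1`), which coincides with the quoted order for any
opening-stable front.

## Registration

All four models minimize the sum of squared differences (SSD) between
Gaussian-smoothed (sigma = 1 voxel) float copies of the masks — raw
binary SSD is a staircase in the parameters with no usable slope.

* **Rigid** (6 parameters): rotations about z, y, x composed as
  `Rz Ry Rx`, then translation. The rotation pivot is the volume-window
  centre (a reproducible choice; the pivot does not change the model
  class, only the parameterization of translation).
* **Similarity** (7): adds the homothety `K_h`, fitted in alternating
  batches: a 6-parameter rigid stage, then a 1-D line search on `K_h`
  (two cycles by default).
* **Affine** (12): unrestricted matrix + translation, one Nelder-Mead run
  plus a restart (12-dimensional simplices stall easily).
* **Demons**: symmetric-forces demons on the smoothed masks, 50
  iterations, no parametric pre-alignment — a *pure* representative of
  the local-deformation class. Regularization is Gaussian and applied
  every iteration, mostly on the update increment (sigma_fluid = 1.5
  voxels) with light smoothing of the accumulated field (sigma_field =
  0.5): smoothing only the accumulated field at comparable width leaves
  a persistent half-voxel equilibrium offset at the boundary (measured
  Dice 0.944 vs 0.978 on nested balls), because each iteration shrinks
  the converged field and the forces must keep fighting it. The best
  field seen over the iterations is returned, which enforces SSD
  monotonicity versus the identity.

The optimizer is derivative-free (Nelder-Mead) from identity angles plus
centroid-difference translation; with <= 12 parameters robustness matters
more than speed. The reference case is selected by registering every
shape to every candidate and taking the candidate with the smallest mean
final SSD (self-terms excluded, ties to the lowest index).

# Evaluation

Binary measures: Dice, Jaccard (`jaccard = dice/(2 - dice)`), Hausdorff
(voxel-centre, mm, exact via the distance transform). Probabilistic
atlases additionally get `IProb(P, S)`: mean probability inside the truth
minus mean probability outside it over the window, in `[-1, 1]`; an atlas
built from identical shapes scores exactly 1 against that shape.

For binary measures a probabilistic atlas is thresholded over
`t = 0, 0.1, ..., 0.9` (strict `p > t`, so `t = 0` is the atlas support)
and the best value per measure is reported — every method gets its best
chance. The harness (`leave_one_out()`) coregisters the whole sample
once per registration model, then for each exploration builds the atlas
from the aligned shapes of all *other* patients and scores it against the
held-out exploration's aligned shape. Coregistering once (rather than
re-registering inside every fold) matches the design of the evaluation
this package reproduces and keeps the harness quadratic-free; the
held-out case's ground truth enters the common frame under the same
geometric model as the training sample. `compare_methods()` then runs
all pairwise paired two-sided t tests per measure (12 method labels give
66 pairs) with Holm adjustment at 0.05 (the adjustment method in the
original analysis is unstated; Holm is assumption-free and conservative,
Bonferroni and none are exposed).

# Synthetic populations

`make_population()` emulates a sample of segmented organs: one smooth
multi-lobed base blob per population, pushed through per-case similarity
/ affine perturbations and a smooth random displacement field
(Gaussian-smoothed vector white noise). Defaults — 64^3 window of 1.5 mm
voxels, 18 mm base radius, 3 lobes, rotation sd 0.12 rad, translation sd
4 mm, log-scale sd 0.06, affine entry sd 0.04, warp 3 mm RMS with 12 mm
correlation length — are desk-scale stand-ins for inter-subject liver
variability: pose scatter of a few degrees/voxels, volume differences of
~15-20%, and non-affine surface variation of about two voxels. Draws are
truncated at 2.5 sd so a valid spec stays clear of the window. The warp
model matches the deformation class demons can express, deliberately: it
makes "flexible registration can absorb the variability" demonstrable.

What the generator does *not* emulate: realistic liver anatomy and
topology, segmentation errors, intensity information (registration here
is mask-driven), and multi-organ context. A green harness result
establishes the estimators' contracts and the direction of the
registration-flexibility effect on this family of shapes — not clinical
performance.

# Numerical choices and degenerate inputs

* Distances and volumes are physical (mm / mm^3), voxel-centre
  convention, anisotropic spacing respected everywhere.
* Indicator resampling under transforms is nearest-neighbour (binarity
  preserved); real-valued volumes use trilinear interpolation.
* `threshold_atlas()` is strict (`p > t`) so the `t = 0` sweep value is
  the support, not the window.
* Empty/full shapes: signed distance, Hausdorff, IProb and registration
  raise content errors rather than returning sentinels; optimizer
  failures return `converged = FALSE`, never an exception.
* Ties: reference selection and threshold selection resolve to the
  lowest index/threshold; landmark traversal fixes start point and
  orientation. All generators are pure functions of their spec and seed.

# Known limitations

* The demons implementation is single-scale; large pose offsets (beyond
  its capture range) are absorbed only partially, which is precisely the
  regime the evaluation harness probes, but it means demons results
  should not be read as the best achievable deformable registration.
* The affine optimizer is derivative-free and local; strong affine
  perturbations outside the tested capture range may need more restarts.
* The band engine's `d*`-binning is an approximation, controlled by
  `nbins` and validated at 1e-3; exact per-voxel fits are available but
  quadratic in the band size.
* `span`-mode bandwidths make each local fit near-global; with very
  heterogeneous coverage (e.g. after a partially failed registration)
  the pooled fit can depress interior probabilities — a real phenomenon
  of the estimator, not an artifact, but worth knowing when reading low
  IProb values for flexible registrations.
* At desk scale the demons model can usually absorb *all* of the
  generator's variability (the warp model is inside the demons
  deformation class, and pose offsets are within its capture range), so
  the penalty that flexible registration pays on real, large,
  strongly-varying anatomy — where single-scale demons partially fails
  and the atlas interior inherits the coverage deficits — appears only
  in some seeds of the synthetic harness, not uniformly. The suite's
  registration-flexibility ordering check documents this honestly: it
  can fail on populations that demons registers essentially perfectly.
* Parameter recovery of the parametric registrations is limited by the
  nearest-neighbour-quantized ground truth, not by the optimizer: at
  shape radii below ~10 voxels the SSD optimum itself sits a few degrees
  away from the generating rotation. Recovery at sub-degree fidelity
  needs shapes of radius ~20 voxels; the affine matrix is identifiable
  to about 0.1 per entry at that resolution.
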