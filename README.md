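# shapeatlas

Probabilistic and statistical atlas construction from samples of binary 3D
organ shapes, with a harness that measures how the choice of coregistration
model changes an atlas's ability to generalize to unseen cases.

## The problem

Segmentation of organs such as the liver leans on anatomical atlases as
prior knowledge. Given segmented binary shapes `phi_1, ..., phi_n` of the
same organ from different subjects, coregistered into a common window `W`,
a *probabilistic atlas* estimates the per-voxel probability
`p(x) = P(x ∈ Φ)` of belonging to the organ; a *statistical atlas* is a
mean shape plus PCA modes of variation. The quality that matters for
segmentation is how well the atlas fits a case that was *not* used to
build it — and that quality depends strongly on how flexible the
registration was: a deformable registration can make the aligned sample
nearly identical, which destroys the very variability the atlas should
encode.

## What the package implements

**Atlas estimators**

* `ncf_atlas()` — normalized coverage function,
  `p̂(x) = (1/n) Σᵢ 1_{φᵢ}(x)`: the classical voxel-wise estimator.
* `glm_atlas()` — a model-based estimator: at each voxel `x₀`, the
  coverage indicators of the sample are regressed on the mean signed
  distance `d*(x)` through a logistic link,
  `p̂(x₀) = logistic(β̂(x₀)ᵀ (1, d*(x₀)))`, where `β̂(x₀)` maximizes a
  tricube-kernel-weighted local pseudolikelihood
  (`K(u) = (70/81)(1−|u|³)³`). Smooth by construction because it pools
  information along the distance profile.
* `statistical_atlas()` — ordered semi-landmarks by slicing, PCA shape
  model, and a binary mean shape rebuilt by viscous morphological
  reconstruction from the mean landmarks.

**Registration** (`register()`, `register_demons()`,
`coregister_sample()`): rigid (6 parameters), similarity / global
rescaling (7, homothety `K_h`), affine (12), and demons (dense
displacement field), all minimizing the SSD between smoothed masks, with
automatic reference selection (`select_reference()`).

**Evaluation** (`dice()`, `jaccard()`, `hausdorff()`, `iprob()`,
`best_threshold_eval()`, `leave_one_out()`, `compare_methods()`): the
IProb measure of a probabilistic atlas `P` against a shape `S` is

    IProb(P, S) = mean_{x∈S} P(x) − mean_{x∉S} P(x)  ∈ [−1, 1],

1 exactly when `P` is the indicator of `S`. The leave-one-out harness
coregisters the sample once per model, builds each fold's atlas from all
*other* patients and scores it against the held-out case; methods are
compared by paired t tests with Holm adjustment.

**Synthetic data** (`population_spec()`, `make_population()`): organ-like
multi-lobed blobs with controlled pose, scale, affine and smooth local
deformation variability — every experiment in the test suite is fully
reproducible from a seed, no data download.

**I/O** (`read_volume()`, `write_volume()`): NIfTI-1 (`.nii`, `.nii.gz`),
MetaImage (`.mha`/`.mhd`), NRRD; voxel spacing respected everywhere
(distances in mm, volumes in mm³).

## Worked example

```r
library(shapeatlas)

# a population of 5 organ-like shapes with pose/scale/affine/warp variability
spec <- population_spec(n_cases = 5, seed = 1)
pop  <- make_population(spec)

# coregister under the similarity model and build the two probabilistic atlases
co  <- coregister_sample(pop, "similarity", reference = 1)
ncf <- ncf_atlas(co$aligned)
glm <- glm_atlas(co$aligned)

# how well does each atlas explain a shape it has seen?
round(c(ncf = iprob(ncf, co$aligned[[2]]), glm = iprob(glm, co$aligned[[2]])), 3)
#>   ncf   glm
#> 0.906 0.899

# the full leave-one-out harness, one method combination
rec <- leave_one_out(pop, seq_along(pop), "GLM", "similarity", reference = 1)
round(colMeans(rec[, c("dice", "jaccard", "hausdorff", "iprob")]), 3)
#>      dice   jaccard hausdorff     iprob
#>     0.919     0.850     4.352     0.894
```

`iprob ≈ 0.89` says that, inside a held-out shape, the GLM atlas assigns
on average high probability, while assigning almost none outside — the
atlas carries over to unseen cases despite the sample variability. The
`hausdorff` column is in mm (here 1.5 mm voxels).

## Command line

```sh
exec/shapeatlas synth    --out pop/ --n 6 --seed 1
exec/shapeatlas register --in pop/ --out aligned/ --model trs
exec/shapeatlas atlas    --in aligned/ --out atlas.nii.gz --method glm
exec/shapeatlas eval     --atlas atlas.nii.gz --truth pop/case_001.nii.gz --out rec.json
```

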