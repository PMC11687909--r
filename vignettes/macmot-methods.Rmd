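---
title: "macmot: methods, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{macmot: methods, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents what `macmot` computes, the conventions behind
every number it reports, why the open design questions were settled the
way they were, and what its synthetic data do and do not establish about
real microscopy. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself recompute.

## The pipeline

Input is pre-segmented label-mask time-lapse data (one integer label
image per frame, 5-minute frames by default) or a tracker's per-cell
coordinate table; `macmot` deliberately does not segment or track real
images — production segmentation/tracking tools do that better, and the
greedy nearest-centroid linker included here is plumbing for synthetic
stacks only. The stages are:

1. region extraction and sub-pixel contour extraction per frame;
2. track assembly and a minimum-duration filter (≥ 60 min, i.e. ≥ 13
   frames at 5-minute intervals), removing cells that leave the field;
3. per-cell features: morphology at the *first* frame (classification
   convention), motility over the whole track;
4. unsupervised morphology clustering and cluster naming;
5. quadratic discriminant analysis of group pairs in speed–persistence
   space, with Gaussian-process time-course smoothing for display;
6. SMOTE-balanced RBF-SVM subtype classification under shuffled,
   stratified 5-fold cross-validation.

## Conventions

* Coordinates are pixels; `x` is the column, `y` the row, origin at the
  top-left pixel centre, everything 1-based (R convention). Frames are
  1-based.
* Regions are 8-connected components of each nonzero label.
* Contours are extracted at the 0.5 iso-level of the binary mask
  (marching-squares interpolation via `grDevices::contourLines`),
  resampled to 200 equal arc-length points and smoothed with a circular
  Gaussian of σ = 1 sample spacing. The smoothing suppresses the
  digitization staircase that otherwise inflates perimeters of curved
  boundaries by ~6%. Measured biases of this convention on analytic
  shapes: a radius-30 digitized disk has compactness 0.989; a 20-px
  square measures ~2% short in perimeter and ~4% high in compactness
  (corners are rounded at the sample-spacing scale). Descriptors of
  objects smaller than ~10 px radius carry proportionally larger
  digitization error.
* Eccentricity uses pixel-set second moments for regions (the
  regionprops convention) and exact Green's-theorem polygon moments for
  contours; compactness and solidity use the smoothed contour.
  Compactness values pushed above 1 by discretization are clipped and
  flagged. Degenerate (collinear) regions return an eccentricity capped
  below 1 with a `degenerate` attribute.
* Speed is total path length over elapsed time, `(n−1) × Δt`, in px/min.
  Persistence is the directionality ratio — net displacement from the
  first point over total path length — which is guaranteed to lie in
  [0, 1]; a zero-length path has persistence 0 by convention, flagged.
  Both are defined "up to" every frame 2..n, giving a per-cell time
  series; the whole-track endpoint scalars are what clustering,
  discrimination and classification consume (an alternative would be
  time-averaged scalars; endpoint values are the package's documented
  choice and the series is available for anything else).
* Tracks shorter than 2 frames have undefined speed and are excluded.

## Shape modes

Each outline is resampled to 200 equal arc-length points starting at the
vertex farthest from the centroid, then aligned by generalized Procrustes
analysis: translation to a common centroid, per-shape rotation minimizing
squared distance to the evolving mean, with point correspondence
optimized over all cyclic shifts and traversal reflection at every
iteration (computed exactly via the FFT). Scale is *retained* by default
because cell size is biologically meaningful; `scale = "unit"` normalizes
it away. PCA of the aligned, flattened coordinates yields orthonormal
modes, variance fractions and per-shape scores;
`reconstruct_shape(model, mode, k_sd)` renders the mean displaced by a
chosen number of score standard deviations. All frames of all cells are
valid data points for this module, unlike classification morphology
(first frame only).

## Clustering and naming

k-means runs on z-scored (compactness, eccentricity, solidity) — the
three descriptors have incomparable units, and z-scoring makes the
result invariant to affine rescaling. `stats::kmeans` with 25 seeded
restarts supplies the optimizer. k is selected over 2–5 by mean
silhouette width; among near-ties (within 0.02) k values whose
silhouette plots contain negative widths or grossly uneven cluster sizes
are penalized, mirroring standard visual silhouette criteria. Cluster
naming is rule-based on the centroid signatures: circular = high
compactness and solidity, low eccentricity; elongated = high
eccentricity with high solidity; protruded = low compactness and
solidity; the remainder is "mixed" (transitional, overlapping or
ambiguous cells). Inconsistent rule outcomes name everything "mixed"
with a warning rather than guessing.

## Discrimination and time courses

QDA fits one Gaussian per group (maximum-likelihood covariance,
empirical priors) on the two motility scalars and predicts by maximum
posterior; near-singular covariances receive a flagged ridge of
`1e-6 × mean(diag)`. Accuracy is stratified 5-fold cross-validated
(stratification is this package's choice — fold class balance matters
with unequal groups). Combined groups (e.g. circular+elongated) are
merged before folding. The GP smoother uses a squared-exponential kernel
plus iid noise, hyperparameters by L-BFGS marginal-likelihood
maximization; since all cells share the 5-minute grid, the fit operates
on per-timepoint means with noise `σ²/nₜ` (the exact sufficient
statistic), and the 95% band is predictive for the per-timepoint group
mean. Optimizer failure falls back to fixed moment-based defaults,
flagged in the output.

## Classification

Feature sets: morphology = (eccentricity, compactness, cell size),
motility = (trajectory hull area, speed, persistence), combined = both.
Per fold, features are z-scored by training-fold statistics, the
training fold is SMOTE-balanced (each minority class upsampled to the
majority count by uniform interpolation toward one of its 5 nearest
same-class neighbours), and an RBF SVM (`e1071`, one-vs-one, C = 1,
γ = 1/p on unit-variance features — the `1/(p·var)` convention) is fit.
Balancing and scaling never see test rows. C and γ are deliberately not
tuned: the analysis compares feature *sets*, and tuning would confound
that comparison. With training class counts of 200/296/318 (a stratified
4/5 split of a 251/369/398 cohort), SMOTE yields 318 per class, 954
training points. The pooled confusion matrix is row-normalized so its
diagonal is the per-class accuracy.

## The synthetic generator

`macrophage_cohort()` and `render_cohort()` emulate the study conditions
the package is built for: three parent cultures (M0/M1/M2) imaged for
3 h at 5-minute intervals, 251/369/398 cells, with each parent a
*mixture* of shape archetypes because polarized cultures are impure.
Shapes are star-convex polygons (ellipse base, optional cosine lobes,
smooth Fourier boundary noise), rigid over time; trajectories are
correlated random walks (Gamma step lengths, wrapped-normal heading
increments). Default archetype parameters encode the observed coupling —
protruded cells fastest, elongated cells most persistent and
farthest-ranging, circular cells slow and local — and were chosen (once)
so those orderings hold robustly at a few hundred cells; magnitudes are
plausible for 20× phase-contrast imaging but are otherwise free choices,
since only orderings, not magnitudes, are established for the real
system.

Three further design elements matter for interpretation:

* **Transitional cells.** Each parent contains 30% "mixed"-archetype
  cells (dominant archetype 70% of the remainder, 15%/15% others).
  Real cohorts place roughly a third of cells in a fourth, unnameable
  morphology cluster; without this component the archetypes are so
  separable that a single modality reads them perfectly and the
  combined-features question becomes vacuous.
* **Per-cell variability.** Radius, aspect ratio, protrusion depth,
  step scale and heading concentration all carry log-normal per-cell
  jitter (`default_cell_variability()`), making each modality an
  informative but imperfect archetype readout, as in real data.
* **Direct parent effects.** Beyond mixture composition,
  `default_parent_effects()` applies small per-condition multipliers:
  M1 cells spread (area ×1.4) and step faster (×1.15), M2 cells turn
  less (concentration ×1.6), M0 cells step slower (×0.85). These mirror
  the described activation phenotypes (LPS-induced spreading,
  IL-4-induced persistent elongation) and give each modality partially
  *private* subtype information — the structural reason combining
  modalities helps, here as in real cultures. With all multipliers at 1
  the cohort is purely compositional and the combined model matches the
  better single modality instead of beating it.

What passing tests on this generator establish: the descriptor
implementations are correct against oracles and closed forms; the
pipeline's statistical machinery (silhouette selection, QDA calibration,
SMOTE arithmetic, CV bookkeeping) behaves as specified; and the
qualitative claims — morphology–motility coupling, a dominant low-rank
shape space, and the combined-features gain — are reproduced under
conditions *designed* to contain them. What they do not establish:
anything about segmentation quality, real shape statistics (real
boundaries are not star-convex, shapes deform over time), cell division,
death, adhesion or crowding, or the real effect sizes of any comparison.

## Numerical choices and degenerate inputs

* Problem sizes: unit tests use cohorts of tens to a few hundred cells
  and the acceptance checks a single 1018-cell cohort with 10 CV seeds;
  Monte-Carlo ordering checks use 200–300 tracks per archetype.
* Procrustes iteration stops at a relative mean change of 1e-8 (cap 100
  iterations, warning on non-convergence with the best iterate
  returned). Rank-deficient shape sets return fewer modes, flagged;
  zero-variance sets return none.
* k-means duplicate-point degeneracy returns a valid partition over the
  distinct rows instead of erroring.
* Greedy linking allows no frame gaps and starts new tracks for
  unmatched regions; stacks that relabel frames independently must use
  `method = "distance"` explicitly, since persistent-looking labels are
  indistinguishable from per-frame relabelling in general.
* Single-pixel regions contour as a unit square; empty regions error.
* The density guard in `render_cohort` rejects configurations whose
  total cell area exceeds ~60% of the frame, where overlap would make
  ground-truth masks meaningless.

## Known limitations

Morphology is measured at one frame and shapes are rigid in the
generator, so nothing here speaks to shape *dynamics*. The greedy linker
swaps identities when cells pass within the gate distance of each other;
it exists to serve sparse synthetic stacks. GP hyperparameters are fit
per group independently; no between-group sharing is attempted. The SVM
is intentionally untuned, so absolute accuracies are conservative; the
package's claims are comparative (combined vs single-modality), not
absolute.
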