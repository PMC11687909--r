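# macmot

Morphology and motility profiling of macrophage time-lapse imaging, and
prediction of polarization state (M0 / M1 / M2) from the two combined.

## The problem

Macrophages polarize into pro-inflammatory (M1, LPS-activated) and
anti-inflammatory (M2, IL-4-activated) states whose identification
normally requires staining, q-PCR panels or flow cytometry. Shape alone
partially identifies the state — naive cells are round, LPS-activated
cells spread with protrusions, IL-4-activated cells elongate — and so
does spontaneous migration: circular cells crawl slowly and stay put,
protruded cells move fast but wander locally, elongated cells migrate
persistently and travel far. `macmot` implements the full label-free
analysis that exploits this coupling: given segmented label-mask
time-lapse microscopy (or tracker output), it quantifies every cell's
shape and movement, groups morphologies without supervision, measures how
well movement predicts morphology, and classifies subtype from either or
both modalities. A synthetic generator with three motility-coupled shape
archetypes (plus a transitional "mixed" form) stands in for microscopy, so
the entire pipeline is testable and its statistical claims reproducible
from code alone.

## The quantities

Per cell, at its first frame (morphology) and over its whole track
(motility), with tracks shorter than one hour discarded:

| descriptor | definition |
|---|---|
| compactness | isoperimetric quotient `4πA / P²` (1 = disk) |
| eccentricity | `√(1 − b²/a²)` of the moment-equivalent ellipse |
| solidity | `A / A_hull` (low = protrusions/concavities) |
| cell size | region area, px² |
| speed | total path length / elapsed time (px/min) |
| persistence | net displacement / path length, in [0, 1] |
| trajectory hull area | convex-hull area of all visited positions |

On top of these: 200-point arc-length outline resampling with
generalized Procrustes alignment and PCA ("shape modes"); k-means on
z-scored (compactness, eccentricity, solidity) with silhouette-based
selection of k; quadratic discriminant analysis of group pairs in
(speed, persistence) with stratified 5-fold CV; Gaussian-process
smoothing of speed/persistence time courses; and an RBF-kernel SVM
subtype classifier whose training folds are SMOTE-balanced.

## Worked example

```r
library(macmot)

# a study-sized synthetic cohort: 1018 cells across three parent images
cohort <- macrophage_cohort(seed = 1)
table(cohort$parent_label)
#>  M0  M1  M2
#> 251 369 398

# unsupervised morphology grouping at k = 4, with rule-based naming
cl <- cluster_morphology(cohort, k = 4, seed = 0)
cl
#> morph_clusters: k = 4
#>  circular elongated     mixed protruded
#>       206       275       308       229

# how well does movement alone predict the morphology group?
run_pairwise_discrimination(cl$table, "cluster_name", seed = 0)
#>                              pair n_a n_b mean_accuracy
#> 1 protruded vs circular+elongated 229 481         0.973
#> 2           circular vs protruded 206 229         0.979
#> 3           circular vs elongated 206 275         0.894
#> ...

# subtype classification from morphology + motility combined
run_cv_experiment(cohort, "combined", seed = 0)
#> subtype_cv_report [combined]: overall accuracy 69.4%
#> row-normalized confusion (%):
#>       predicted
#> actual   M0   M1   M2
#>     M0 66.1 11.6 22.3
#>     M1  9.2 77.0 13.8
#>     M2 22.9 12.6 64.6
```

The cluster sizes show the three nameable shape groups plus a sizeable
"mixed" cluster of transitional/ambiguous cells; the QDA row shows that
protruded cells are told apart from everything else by motility alone
while circular-vs-elongated is the hardest pair; and the confusion matrix
gives per-class accuracies on its diagonal. Comparing feature sets
(`compare_feature_sets(cohort, seeds = 0:9)`) shows the combined model
beating both single-modality models.

A command-line wrapper for batch use lives at `inst/cli/macmot.R`
(subcommands `simulate`, `extract-features`, `cluster`, `discriminate`,
`classify`, `run-all`).

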