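---
title: "Methods: ensemble SDMs, prioritization, and protection-gap assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble SDMs, prioritization, and protection-gap assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`gapstack` estimates how much of each species' modeled distribution falls
in each protection category — full-protection units (SPA), sustainable-use
units (SUA), indigenous lands (IT), or none — and whether the cells inside
those categories are more important for conservation than chance. This
vignette is the package's account of the underlying methods: the models and
their assumptions, the parameters that matter, what the synthetic generator
does and does not emulate, and the numerical conventions.

## The spatial frame

All stages share one raster frame (`grid_raster`): a rectangular lattice of
square cells with an `NA` nodata mask. Cells are treated as equal-area. On
a real geographic grid (the default cell size, 0.05°, matches the usual
analysis resolution for such assessments) cell area shrinks with latitude;
we deliberately ignore that distortion, so percentages are cell-count
shares, not strictly area shares. Rasters serialize to plain-text ESRI
ASCII grids with fixed `%.10g` formatting, which is what makes whole-pipeline
byte determinism possible.

## Occurrence cleaning and spatial thinning

Records are dropped, in order, for missing coordinates, missing or
unparseable dates outside the 1900–2022 search window, falling outside the
study extent, and exact coordinate duplicates (first kept). Cleaning is
idempotent and every rejection is logged with its rule.

Thinning targets spatial autocorrelation: a Moran's correlogram is built on
the linear distances between points, with equal-width distance classes
(Sturges' rule on the number of pairs by default) and binary weights (a
pair contributes to exactly the class containing its distance). Per class,
significance comes from a permutation test in which the observed
arrangement counts as one permutation, so `p = (1 + #{|I*| ≥ |I|})/n_perm`
and p can never undercut its resolution `1/n_perm`. While the first class
shows significant *positive* autocorrelation at `alpha` (default 0.05), the
closest pair is located and its member with the higher local density
(neighbors within the first-class radius; ties to the lower index) is
removed; coincident duplicates are distance-zero pairs and therefore go
first. Thinning stops at non-significance or at 5 points — the minimum
occurrence count for a species to be modeled at all. Only positive
short-range autocorrelation triggers removal: significant *negative*
first-class autocorrelation (overdispersion) is not a clustering problem
and removing close pairs could not cure it.

Which variable should the correlogram be computed on is genuinely open; we
use the first principal component of the environmental stack evaluated at
the points, on the grounds that environmental redundancy among nearby
records is exactly what biases the suitability models.

## Predictor reduction

The environmental layers (standardized to zero mean, unit variance) are
reduced by PCA of their cell-wise covariance — equivalent to a correlation
PCA given the standardization. The minimal leading-axis set whose
cumulative explained variance reaches `variance_target` (default 0.95) is
retained and the component *scores*, written back per cell, become the
model predictors. Axis signs follow the convention that each axis's
largest-magnitude loading is positive, making outputs platform-deterministic.
Truncation loses at most `1 − retained` of the total variance, and the
tests verify the reconstruction error against that bound.

## Suitability learners

Four families share one contract: map predictor vectors to scores, monotone
min-max rescaled to [0, 1] over the grid.

* `max_entropy` — a log-linear density-ratio model: logistic regression of
  presences against background with linear and quadratic terms.
* `gaussian_bayes` — Gaussian class-conditional Bayes: multivariate normal
  fits to presence and background environments; the score is the
  log-density ratio (covariances ridge-regularized by 1e-6).
* `random_forest` — a 500-tree bagged-tree classifier of presences versus
  pseudo-absences.
* `support_vector` — a radial-kernel SVM (cost 1, gamma 1/d) of presences
  versus pseudo-absences, scored by oriented decision values. Decision
  values rather than calibrated probabilities are used because they are a
  deterministic, monotone score — all the contract requires — whereas the
  usual cross-validated calibration introduces RNG state outside the
  package's seed discipline.

Learners needing absences get 50 pseudo-absences sampled uniformly among
cells outside the presences' per-axis min–max environmental envelope —
locations deemed unsuitable by construction. Density-ratio learners are
contrasted with 10,000 background points drawn uniformly (with replacement
when the grid is smaller) over valid cells.

Evaluation uses a spatial partition for species with more than 30 records —
a chessboard coloring by (row + col) block parity, training on one color
and testing on the other, which separates train and test spatially — and a
seeded random 70/30 split otherwise. All learners are evaluated against the
held-out share of the pseudo-absence set so their metrics are comparable.
Metrics are ROC AUC (rank-based, monotone-invariant), TSS = sensitivity +
specificity − 1, and the Jaccard index TP/(TP+FP+FN), which ignores true
negatives because abundant trivially-correct absences inflate TSS for
low-prevalence species. The binarization threshold is chosen to maximize
Jaccard over the candidate set of unique held-out scores, ties resolved to
the lower threshold (the less exclusionary map). An undefined metric (an
empty class) is returned as `NA` with a warning, never silently as zero.

## Ensemble and basin constraint

The ensemble averages, cell-wise, the suitability maps of the models whose
Jaccard value strictly exceeds the mean Jaccard across the species' models;
if none does (all equal), all are included. Gating on Jaccard
*performance*, not on the threshold values themselves, is deliberate:
thresholds are score-scale quantities, and gating on them would reward
arbitrary rescalings. The ensemble threshold is the mean of the included
models' thresholds; re-optimizing Jaccard on the ensemble map is available
via `ensemble(fit, reoptimize = TRUE)`. Averaging happens before
binarization.

The binary range is then pruned by hydrographic connectivity: basins
partition the grid, a basin is "predicted" if it holds a presence cell, and
the retained set is everything reachable from basins that are predicted
*and* contain an occurrence, through chains of edge-adjacent (4-connected;
diagonal contact does not count) predicted basins. This constraint is
idempotent, only ever removes cells, and is verified in tests against an
independent graph-reachability oracle.

## Conservation prioritization

Cells are ranked by greedy core-area removal: at each step delete the cell
minimizing

> δ(cell) = max over species s of ( w_s · v(cell, s) / V_s ),

where `V_s` is species s's remaining total value; ties go to the lower flat
cell index. The `max` makes a cell holding a large share of *any* single
species' remaining range expensive to delete, encoding complementarity and
irreplaceability: a two-cell endemic keeps its cells until nearly the end
even among widespread species (a property the tests assert). The removal
order defines the rank fraction k/N — a bijection onto {1/N, …, 1}, higher
meaning more important. Removal is exact, one cell at a time, with the full
recomputation affordable at desk-scale grids; the implementation matches a
step-by-step brute-force oracle on hundreds of randomized small instances.
Input ranges may be binary (the pipeline default) or continuous. This
ranking is a defined, reproducible stand-in for published
prioritization software in the Zonation tradition, not a bit-compatible
reimplementation — such software has many variants and settings, and no
claim of equivalence is made.

## Protection classification and gap accounting

A cell belongs to SPA, SUA or IT only if at least `coverage_threshold`
(default 0.75) of its area falls in that category, otherwise it is
unprotected. Coverage fractions are computed exactly by subcell counting
when the category map is supplied on a finer lattice. Above a threshold of
0.5 double assignment is geometrically impossible (asserted); for
configurable thresholds ≤ 0.5 the precedence SPA > SUA > IT (most
restrictive first) resolves conflicts.

Per species, percentages of the (basin-constrained, binary) range per
category always sum to 100, and the hierarchical cumulative series — SPA,
SPA+SUA, SPA+SUA+IT — is non-decreasing with the final term equal to
100 − unprotected. A one-way fixed-effects ANOVA across the four category
percentage groups (species as replicates) asks whether some category
systematically holds more of the species' ranges; percentages enter
untransformed (no arcsine/logit), which keeps the statistic interpretable
but is worth remembering near 0/100%.

## The randomization test

For a target class with k cells, the observed mean rank fraction is
compared with `n_rand` (default 10,000) means of k-cell uniform draws
without replacement from *all* valid cells — protected and unprotected
alike, since nothing about the null restricts the pool — and

> p = #{draw mean ≥ observed} / n_rand.

The raw estimator is kept (p = 0 is possible and is displayed as
`< 1/n_rand`). Tests verify three properties: exactness (on a 6-cell grid
with a 2-cell target the sampled p converges to the exact fraction over all
15 subsets), calibration (p approximately uniform when targets are chosen
independently of importance), and power (the top importance decile on a
400-cell grid yields p ≤ 0.01 at 1,000 draws).

## The synthetic generator

The generator emulates the *structure* of real inputs with known ground
truth: environmental layers are Gaussian-smoothed white noise (kernel scale
= `autocorrelation_range` cells — the simplest controllable autocorrelation
mechanism), standardized exactly; true suitability is a product of
per-layer Gaussian niche kernels rescaled to a maximum of 1; occurrences
are drawn with probability proportional to true suitability, jittered
within their cell, and stamped with uniform 1900–2022 dates and source tags
so the cleaning rules have something to bite on; protection categories are
assigned by whole axis-aligned square blocks in seeded shuffled order until
each requested area fraction is met to within one block (clustering matters
because the randomization test's null behavior depends on spatial
structure; exact block shape does not); basins grow by seeded breadth-first
dilation from random cells, giving contiguous, exhaustive, mutually
exclusive patches with a known edge-adjacency relation.

Default study conditions: a 40×40 grid, 6 layers with autocorrelation range
6, 8 species with niche breadth 0.6 landscape-SD and niche centers uniform
in [−1.2, 1.2], 120 records per species, protection fractions SPA 0.10,
SUA 0.15, IT 0.25 (indigenous lands the largest protected class,
strict-protection units the smallest, about half the landscape unprotected
— realistic proportions for an Amazonian setting), 12 basins. The worked
examples and the acceptance script use these sizes; tests use smaller grids
chosen for the properties they probe.

What the generator does *not* emulate: sampling bias along rivers and
roads (occurrence sampling is purely suitability-proportional), real
climatological covariance structure between layers (layers are generated
independently), latitude-dependent cell area, and temporal dynamics.
Passing tests therefore demonstrate correctness of the machinery and
recoverability under known truth — not that any particular real-world
coverage estimate is right.

## Numerical conventions and edge cases

* Every operation that consumes randomness takes an explicit seed and
  derives independent sub-seeds, so one pipeline seed reproduces every
  stage byte-for-byte; RNG state is restored after each draw.
* Degenerate inputs are flagged, not fudged: constant values make Moran's I
  and ANOVA undefined (`NA` + flag), empty confusion classes make TSS or
  Jaccard `NA` with a warning, an all-zero species is rejected by the
  prioritizer.
* Ties: threshold selection takes the lowest optimal cutoff; cell removal
  takes the lowest flat index; majority resampling takes the smallest
  category code.
* A chessboard partition that degenerates (all points one color) falls back
  to the random split with a warning.
* Basin growth under a mask that disconnects the grid attaches unreachable
  pockets to the nearest seed, the one case where basin contiguity can be
  violated; it cannot arise without a disconnecting mask.

## Known limitations

Cell areas are treated as equal; protection overlays are raster-based
(supply polygons rasterized to a finer lattice — there is no
polygon-intersection engine); learners run at fixed, standard
hyperparameters with no tuning loops; no extrapolation diagnostics (MESS
maps) or future-climate projection; the prioritizer implements one
marginal-loss rule, not the full feature set of dedicated prioritization
software.
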