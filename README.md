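# gapstack

Ensemble species distribution models and protected-area gap analysis on
gridded landscapes.

## The problem

How much of a species' distribution actually falls inside protected areas —
and inside which kind? In regions like the Brazilian Amazon, protection
comes in legally distinct flavors: full-protection conservation units (SPA),
sustainable-use units (SUA), and indigenous lands (IT). Because verified
occurrence records cover only a sliver of most species' ranges (the
Wallacean shortfall), gap analyses of this kind work from *modeled*
distributions: ensemble species distribution models (SDMs) turned into
binary range maps, overlaid on a protection-category grid.

`gapstack` implements that full analysis as a tested, reusable pipeline:

1. **Occurrence preparation** — record cleaning (missing coordinates,
   missing or out-of-window dates, exact duplicates, out-of-extent points)
   and spatial thinning driven by a Moran's correlogram with permutation
   tests, removing occurrences until short-range environmental
   autocorrelation is non-significant.
2. **Predictor reduction** — PCA of the standardized environmental stack,
   retaining the leading axes explaining ≥ 95% of variance.
3. **Suitability modeling** — four learner families per species
   (`max_entropy`, `random_forest`, `support_vector`, `gaussian_bayes`),
   with 50 envelope-based pseudo-absences for the two-class learners and
   10,000 uniform background points for the density-ratio learners;
   chessboard spatial partitioning above 30 points, random 70/30 below.
4. **Evaluation** — ROC AUC; TSS = sensitivity + specificity − 1; and the
   Jaccard index TP/(TP+FP+FN), which deliberately neglects true negatives;
   the binarization threshold maximizes Jaccard on held-out points.
5. **Ensemble and spatial constraint** — cell-wise mean of the models whose
   Jaccard value exceeds the species' across-model mean; the binary range is
   then pruned to hydrographic basins connected (through chains of
   edge-adjacent predicted basins) to basins holding occurrence records.
6. **Prioritization** — a greedy core-area cell-removal ranking: repeatedly
   delete the cell minimizing `max_s (w_s · v_cell,s / V_s)` over remaining
   species totals `V_s`; removal order defines a conservation-importance
   rank fraction in (0, 1].
7. **Protection assessment** — 75%-coverage classification of analysis
   cells into SPA/SUA/IT/unprotected; per-species percentages and
   hierarchical cumulative percentages (SPA, SPA+SUA, SPA+SUA+IT) with
   one-way ANOVA; and a Monte Carlo randomization test (default 10,000
   draws) of mean importance per protection class, with
   `p = #{draw mean ≥ observed}/n`.

A synthetic-landscape generator (autocorrelated environmental layers,
species with known Gaussian niches, suitability-biased occurrence sampling,
block-clustered protection maps, contiguous basin partitions) provides
ground truth, so every stage is testable without external data. Rasters are
serialized as plain-text ESRI ASCII grids; category maps also export to
GeoJSON.

## Worked example

```r
library(gapstack)
st <- run_gap_study(seed = 1, n_rows = 24, n_cols = 24, n_layers = 4,
                    n_species = 3, n_occ = 80, n_background = 2000,
                    n_rand = 500, n_basins = 8)
print(st)
```

```
<gap_study> seed 1: 24 x 24 grid, 4 layers (3 PCA axes), 3 species modeled
  records: 240 raw -> 240 cleaned -> 67 thinned
  ensemble TSS: mean 0.872 (range 0.750-0.933)
<gap_report> 3 species
  mean % of range: SPA 14.6  SUA 20.3  IT 11.3  unprotected 53.8
  mean cumulative: SPA 14.6  +SUA 34.9  +IT 46.2
  ANOVA (category %): F(3, 8) = 16.92, p = 0.000798
<mc_rand> SPA (64 cells): observed mean 0.6731 vs randomized 0.5036, p < 0.002 (500 draws)
<mc_rand> SUA (96 cells): observed mean 0.4473 vs randomized 0.5005, p 0.978 (500 draws)
<mc_rand> IT (144 cells): observed mean 0.3611 vs randomized 0.5003, p 1 (500 draws)
<mc_rand> SPA+SUA+IT (304 cells): observed mean 0.4540 vs randomized 0.5013, p 1 (500 draws)
```

Reading this output: of the 240 raw synthetic records, all survived the
formal cleaning rules (the generator emits complete records) and 67
survived correlogram thinning. The three species' ensembles discriminate
held-out presences from pseudo-absences at TSS 0.75–0.93. On this landscape
about 54% of the mean modeled range is unprotected; adding SUA to SPA
raises mean coverage from 14.6% to 34.9%, and indigenous lands bring it to
46.2%. The randomization test finds SPA cells substantially more important
for conservation than chance sets of equal size (p < 0.002), while SUA/IT
cells are not (their observed means sit at or below the ~0.5 null).

Every stage is also available piecewise — `clean_records()`,
`autocorr_filter()`, `pca_reduce()`, `fit_sdm()`, `ensemble()`,
`spatial_constraint()`, `rank_cells()`, `classify_cells()`,
`gap_report()`, `mc_randomization()` — and as a command-line chain:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "gapstack.R", package = "gapstack"))')
Rscript $CLI synth --dir work --seed 7 --n-rows 24 --n-cols 24 --n-species 3
Rscript $CLI prep --dir work --seed 7
Rscript $CLI pca --dir work
Rscript $CLI fit --dir work --seed 7
Rscript $CLI ensemble --dir work
Rscript $CLI prioritize --dir work
Rscript $CLI assess --dir work --seed 7 --n-rand 1000
```

The chain is byte-deterministic: re-running with the same seed reproduces
every output file exactly.

## Documentation

The methods vignette (`vignettes/gap-analysis-methods.Rmd`) describes the
models, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, numerical conventions, and known
limitations.
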