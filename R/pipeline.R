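#' Run the full synthetic gap-analysis study
#'
#' One-call pipeline over a synthetic landscape: generates autocorrelated
#' environmental layers, species with Gaussian niches and suitability-biased
#' occurrence samples, cleans and spatially thins the records, reduces the
#' layers by PCA (95% variance), fits the four suitability learners per
#' species, builds the Jaccard-gated ensemble, constrains each binary range
#' by basin connectivity, ranks cells by greedy core-area importance,
#' classifies the grid into protection categories by the 75% coverage rule
#' (the protection map is generated on a 2x finer lattice so the rule is
#' exercised), assembles the per-species and cumulative protection
#' percentages with ANOVA, and runs the Monte Carlo randomization test of
#' mean importance for each protection class and for all classes combined.
#'
#' @param seed integer master seed; every stage derives its own sub-seed.
#' @param n_rows,n_cols,n_layers,autocorrelation_range landscape settings
#'   (see [landscape_spec()]).
#' @param n_species number of synthetic species.
#' @param n_occ raw occurrence records drawn per species.
#' @param niche_breadth niche width (standardized layer units) for all
#'   species.
#' @param fractions,block_size protection-map settings
#'   (see [make_protection_map()]).
#' @param n_basins basin count (see [make_basins()]).
#' @param n_pseudo,n_background,learners model settings (see [fit_sdm()]).
#' @param variance_target PCA variance retention target.
#' @param coverage_threshold protection classification rule (default 0.75).
#' @param n_rand randomizations for the Monte Carlo test.
#' @param thin apply the Moran's-correlogram autocorrelation filter.
#' @param alpha significance level for the filter.
#' @return object of class `gap_study` collecting every stage's result.
#' @export
run_gap_study <- function(seed = 1,
                          n_rows = 40, n_cols = 40, n_layers = 6,
                          autocorrelation_range = 6,
                          n_species = 8, n_occ = 120, niche_breadth = 0.6,
                          fractions = c(SPA = 0.10, SUA = 0.15, IT = 0.25),
                          block_size = 4, n_basins = 12,
                          n_pseudo = 50, n_background = 10000,
                          learners = sdm_learners(),
                          variance_target = 0.95,
                          coverage_threshold = 0.75,
                          n_rand = 10000, thin = TRUE, alpha = 0.05) {
  spec <- landscape_spec(n_rows, n_cols, n_layers = n_layers,
                         autocorrelation_range = autocorrelation_range,
                         seed = derive_seed(seed, 1))
  stack <- make_env_stack(spec)
  grid <- stack[[1]]
  pca <- pca_reduce(stack, variance_target)
  basins <- make_basins(grid, n_basins, seed = derive_seed(seed, 2))
  fine <- build_grid(c(grid$xmin,
                       grid$xmin + ncol(grid$values) * grid$cellsize,
                       grid$ymin,
                       grid$ymin + nrow(grid$values) * grid$cellsize),
                     cell_size = grid$cellsize / 2)
  pfine <- make_protection_map(fine, fractions, block_size = 2 * block_size,
                               seed = derive_seed(seed, 3))
  pmap <- classify_cells(grid, pfine, coverage_threshold)

  species <- sprintf("species_%02d", seq_len(n_species))
  truths <- lapply(seq_len(n_species), function(i) {
    ctr <- with_seed(derive_seed(seed, 400 + i),
                     stats::runif(n_layers, -1.2, 1.2))
    species_truth(ctr, rep(niche_breadth, n_layers))
  })
  names(truths) <- species

  fits <- list(); ensembles <- list(); constrained <- list()
  occ_clean <- list(); cleaning <- list()
  for (i in seq_len(n_species)) {
    suit_true <- make_true_suitability(stack, truths[[i]])
    raw <- sample_occurrences(suit_true, n_occ,
                              seed = derive_seed(seed, 500 + i),
                              species = species[i])
    cl <- clean_records(raw, grid)
    occ <- cl$occurrences
    if (thin && nrow(occ) >= 5) {
      ax1 <- suitability_at(pca$axes[[1]],
                            as.matrix(occ[, c("lon", "lat")]))
      th <- autocorr_filter(occ, ax1, alpha = alpha,
                            seed = derive_seed(seed, 600 + i))
      occ <- th$occurrences
    }
    cleaning[[species[i]]] <- data.frame(
      species = species[i], n_raw = nrow(raw), n_clean = nrow(cl$occurrences),
      n_thinned = nrow(occ), stringsAsFactors = FALSE)
    if (nrow(occ) < 5) next  # below the minimum usable occurrence count
    occ_clean[[species[i]]] <- occ
    fit <- fit_sdm(occ, pca, learners = learners, n_pseudo = n_pseudo,
                   n_background = n_background,
                   seed = derive_seed(seed, 700 + i))
    ens <- ensemble(fit)
    con <- spatial_constraint(ens$binary, basins, occ)
    fits[[species[i]]] <- fit
    ensembles[[species[i]]] <- ens
    constrained[[species[i]]] <- con
  }
  if (!length(constrained)) stopf("no species survived cleaning")

  ranges <- lapply(constrained, function(x) x$binary)
  # species whose constrained range is empty cannot enter the stack
  ok <- vapply(ranges, function(r) any(r$values > 0, na.rm = TRUE), TRUE)
  ranges <- ranges[ok]
  imp <- rank_cells(raster_stack(ranges, names = names(ranges)))
  report <- gap_report(ranges, pmap)
  targets <- list(SPA = "SPA", SUA = "SUA", IT = "IT",
                  protected = c("SPA", "SUA", "IT"))
  rand <- lapply(seq_along(targets), function(j)
    mc_randomization(imp, pmap, targets[[j]], n_rand = n_rand,
                     seed = derive_seed(seed, 800 + j)))
  names(rand) <- names(targets)

  structure(list(seed = seed, spec = spec, stack = stack, pca = pca,
                 basins = basins, protection_fine = pfine,
                 protection = pmap, truths = truths,
                 cleaning = do.call(rbind, cleaning),
                 occurrences = occ_clean, fits = fits,
                 ensembles = ensembles, constrained = constrained,
                 importance = imp, report = report,
                 randomization = rand),
            class = "gap_study")
}

#' @export
print.gap_study <- function(x, ...) {
  cat(sprintf("<gap_study> seed %d: %d x %d grid, %d layers (%d PCA axes), %d species modeled\n",
              x$seed, x$spec$n_rows, x$spec$n_cols, x$spec$n_layers,
              x$pca$n_retained, length(x$fits)))
  cat(sprintf("  records: %d raw -> %d cleaned -> %d thinned\n",
              sum(x$cleaning$n_raw), sum(x$cleaning$n_clean),
              sum(x$cleaning$n_thinned)))
  ens_tss <- vapply(x$ensembles, function(e) e$metrics$tss, 0.0)
  cat(sprintf("  ensemble TSS: mean %.3f (range %.3f-%.3f)\n",
              mean(ens_tss), min(ens_tss), max(ens_tss)))
  print(x$report)
  for (r in x$randomization) print(r)
  invisible(x)
}
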