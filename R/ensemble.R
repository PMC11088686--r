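#' Jaccard-gated ensemble of suitability models
#'
#' Averages the suitability maps of the models whose Jaccard performance
#' exceeds the mean Jaccard across the species' models, reducing the
#' uncertainty contributed by individual algorithms. The ensemble cutoff is
#' the mean of the included models' thresholds (re-optimizing the Jaccard
#' index on the ensemble map is available via `reoptimize`), and the binary
#' range map is `suitability >= threshold`. When no model is strictly above
#' the mean (all Jaccard values equal), every model is included.
#'
#' @param models an `sdm_fit` object, or a list of per-learner model entries
#'   (each with `suitability`, `threshold`, `metrics$jaccard`).
#' @param reoptimize if `TRUE`, re-select the ensemble threshold by
#'   maximizing the Jaccard index on the fit's held-out points (only
#'   available when `models` is an `sdm_fit`).
#' @return object of class `sdm_ensemble`: `included_learners`,
#'   `suitability` (mean map), `threshold`, `binary` (0/1 `grid_raster`),
#'   and `metrics` when evaluation points are available.
#' @export
ensemble <- function(models, reoptimize = FALSE) {
  fit <- NULL
  if (inherits(models, "sdm_fit")) { fit <- models; models <- fit$models }
  if (!length(models)) stopf("need at least one model")
  if (is.null(names(models)))
    names(models) <- vapply(models, function(m) m$learner_id, "")
  jac <- vapply(models, function(m) m$metrics$jaccard, 0.0)
  keep <- jac > mean(jac)
  if (!any(keep)) keep <- rep(TRUE, length(models))  # all equal: include all
  inc <- models[keep]
  suit <- inc[[1]]$suitability
  acc <- suit$values
  if (length(inc) > 1)
    for (m in inc[-1]) acc <- acc + m$suitability$values
  suit$values <- acc / length(inc)
  threshold <- mean(vapply(inc, function(m) m$threshold, 0.0))
  metrics <- NULL
  if (!is.null(fit)) {
    if (reoptimize) {
      sel <- select_threshold(suit, fit$test_presences, fit$test_absences)
      threshold <- sel$threshold
    }
    ev <- evaluate_at_threshold(suit, threshold, fit$test_presences,
                                fit$test_absences)
    metrics <- list(auc = ev$auc, tss = ev$tss, jaccard = ev$jaccard,
                    sensitivity = ev$sensitivity,
                    specificity = ev$specificity)
  }
  binary <- suit
  binary$values <- (suit$values >= threshold) * 1
  structure(list(included_learners = names(models)[keep],
                 suitability = suit, threshold = threshold, binary = binary,
                 metrics = metrics),
            class = "sdm_ensemble")
}

#' @export
print.sdm_ensemble <- function(x, ...) {
  cat(sprintf("<sdm_ensemble> learners: %s; threshold %.3f\n",
              paste(x$included_learners, collapse = ", "), x$threshold))
  if (!is.null(x$metrics))
    cat(sprintf("  AUC %.3f  TSS %.3f  Jaccard %.3f\n",
                x$metrics$auc, x$metrics$tss, x$metrics$jaccard))
  cat(sprintf("  predicted cells: %d\n",
              sum(x$binary$values > 0, na.rm = TRUE)))
  invisible(x)
}

#' Constrain a binary range by basin connectivity to occurrences
#'
#' Reduces overprediction by pruning the binary range to hydrographic
#' basins that either hold occurrence records or are connected to such
#' basins through chains of adjacent predicted basins. A basin is
#' "predicted" when at least one presence cell falls in it; seed basins are
#' predicted basins containing at least one occurrence; the retained set is
#' everything reachable from a seed through edge-adjacent predicted basins.
#' Presence cells outside retained basins are zeroed.
#'
#' @param binary 0/1 presence `grid_raster` (e.g. `ensemble(...)$binary`).
#' @param basins a `basin_map` (as from [make_basins()]), or a list with
#'   `basins` (labelled `grid_raster`) and `adjacency` (data.frame
#'   `from`/`to`).
#' @param occ occurrence data.frame (`lon`, `lat`); every point must fall in
#'   a basin.
#' @return object of class `constrained_range`: `binary` (pruned raster) and
#'   `retained_basins` (sorted basin ids).
#' @export
spatial_constraint <- function(binary, basins, occ) {
  bmap <- basins$basins
  adj <- basins$adjacency
  if (!nrow(occ)) stopf("no occurrences supplied")
  occ_cells <- cells_from_xy(bmap, occ$lon, occ$lat)
  occ_basin <- bmap$values[occ_cells]
  if (anyNA(occ_basin)) stopf("an occurrence falls outside every basin")
  pres_cells <- which(!is.na(binary$values) & binary$values > 0)
  predicted <- sort(unique(bmap$values[pres_cells]))
  seeds <- intersect(predicted, unique(occ_basin))
  # BFS over the basin adjacency graph restricted to predicted basins
  retained <- seeds
  frontier <- seeds
  while (length(frontier)) {
    nb <- adj$to[adj$from %in% frontier]
    nxt <- setdiff(intersect(nb, predicted), retained)
    retained <- c(retained, nxt)
    frontier <- nxt
  }
  retained <- sort(retained)
  out <- binary
  drop <- pres_cells[!(bmap$values[pres_cells] %in% retained)]
  out$values[drop] <- 0
  structure(list(binary = out, retained_basins = retained),
            class = "constrained_range")
}

#' @export
print.constrained_range <- function(x, ...) {
  cat(sprintf("<constrained_range> %d presence cells in %d basins (%s)\n",
              sum(x$binary$values > 0, na.rm = TRUE),
              length(x$retained_basins),
              paste(x$retained_basins, collapse = ", ")))
  invisible(x)
}
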