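#' Rank cells by conservation importance (greedy core-area removal)
#'
#' Iterative cell removal in the core-area spirit: at every step the cell
#' with the smallest marginal loss
#' `delta(cell) = max over species of (weight * cell value / species'
#' remaining total value)` is deleted; ties go to the lower flat cell index.
#' The removal order defines the importance ranking: a cell removed at step
#' `k` of `N` gets rank fraction `k / N`, so values form a bijection onto
#' `{1/N, ..., 1}` and higher means more important (removed later). The
#' `max` aggregation protects range-restricted species: a cell holding a
#' large share of any one species' remaining range is expensive to remove,
#' which encodes complementarity and irreplaceability.
#'
#' Inputs may be binary presence rasters (the default pipeline path) or
#' continuous suitability surfaces.
#'
#' @param ranges [raster_stack()] (or list of `grid_raster`) of per-species
#'   non-negative value layers; every species needs at least one positive
#'   cell.
#' @param weights positive per-species weights (default all 1).
#' @return object of class `cell_importance`: `rank_fraction` (a
#'   `grid_raster`), `removal_order` (flat cell indices, first removed
#'   first), `n_cells`.
#' @export
rank_cells <- function(ranges, weights = NULL) {
  layers <- if (inherits(ranges, "raster_stack")) unclass(ranges)
    else if (is_grid_raster(ranges)) list(ranges) else ranges
  if (!length(layers)) stopf("need at least one species")
  ns <- length(layers)
  if (is.null(weights)) weights <- rep(1, ns)
  if (length(weights) != ns || any(weights <= 0))
    stopf("weights must be positive, one per species")
  cells <- which(Reduce(`&`, lapply(layers, function(l) !is.na(l$values))))
  V <- vapply(layers, function(l) l$values[cells], numeric(length(cells)))
  if (length(cells) == 1L) V <- matrix(V, nrow = 1L)
  if (any(V < 0)) stopf("range values must be non-negative")
  totals <- colSums(V)
  if (any(totals == 0)) stopf("species with zero total value")
  N <- length(cells)
  remaining <- rep(TRUE, N)
  order_out <- integer(N)
  for (k in seq_len(N)) {
    idx <- which(remaining)
    live <- totals > 0
    M <- V[idx, live, drop = FALSE] *
      rep(weights[live] / totals[live], each = length(idx))
    delta <- M[, 1]
    if (ncol(M) > 1)
      for (j in 2:ncol(M)) delta <- pmax(delta, M[, j])
    pick <- idx[which.min(delta)]  # which.min: lowest flat index wins ties
    order_out[k] <- pick
    totals <- totals - V[pick, ]
    remaining[pick] <- FALSE
  }
  rf <- layers[[1]]
  rf$values[] <- NA_real_
  rf$values[cells[order_out]] <- seq_len(N) / N
  structure(list(rank_fraction = rf,
                 removal_order = cells[order_out], n_cells = N),
            class = "cell_importance")
}

#' @export
print.cell_importance <- function(x, ...) {
  cat(sprintf("<cell_importance> %d cells ranked; top cell (flat index %d)\n",
              x$n_cells, x$removal_order[x$n_cells]))
  invisible(x)
}

#' Mean conservation importance over a cell set
#'
#' @param importance a `cell_importance` (or its `rank_fraction` raster).
#' @param cells non-empty vector of flat cell indices, all ranked.
#' @return arithmetic mean of the rank fractions over the set.
#' @export
mean_importance <- function(importance, cells) {
  rf <- if (inherits(importance, "cell_importance"))
    importance$rank_fraction else importance
  if (!length(cells)) stopf("empty cell set")
  v <- rf$values[cells]
  if (anyNA(v)) stopf("cell set includes unranked (nodata) cells")
  mean(v)
}
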