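# Shared fixtures and independent oracles, all built in code.

# small raster from a matrix given row-wise (top row first)
rmat <- function(..., nrow, xmin = 0, ymin = 0, cellsize = 1) {
  grid_raster(matrix(c(...), nrow = nrow, byrow = TRUE),
              xmin = xmin, ymin = ymin, cellsize = cellsize)
}

# gradient landscape: axis value increases with x (column), constant in y
gradient_stack <- function(n = 20) {
  v <- matrix(rep(seq(0, 1, length.out = n), each = n), n, n)
  raster_stack(list(grid_raster(v)), names = "axis1")
}

# lag-1 Moran's I over a raster with rook (edge) neighbours: an independent
# measure of spatial autocorrelation used to compare smoothing ranges
lag1_moran <- function(r) {
  v <- r$values
  z <- v - mean(v)
  num <- 0; s0 <- 0
  nr <- nrow(v); nc <- ncol(v)
  num <- sum(z[-nr, ] * z[-1, ]) + sum(z[, -nc] * z[, -1])
  s0 <- (nr - 1) * nc + nr * (nc - 1)
  (length(v) / (2 * s0)) * (2 * num) / sum(z^2)
}

# brute-force greedy core-area removal: recomputes every cell's marginal
# loss from scratch at each step (independent of rank_cells' incremental
# bookkeeping)
bf_removal_order <- function(V, weights) {
  N <- nrow(V)
  remaining <- seq_len(N)
  out <- integer(0)
  while (length(remaining)) {
    tot <- colSums(V[remaining, , drop = FALSE])
    best <- NA_integer_; best_d <- Inf
    for (i in remaining) {
      contrib <- ifelse(tot > 0, (weights / tot) * V[i, ], 0)
      d <- max(contrib)
      if (d < best_d) { best_d <- d; best <- i }
    }
    out <- c(out, best)
    remaining <- setdiff(remaining, best)
  }
  out
}

# exhaustive confusion counts / metric evaluation over labelled test points
bf_metrics <- function(scores_p, scores_a, threshold) {
  tp <- sum(scores_p >= threshold); fn <- sum(scores_p < threshold)
  fp <- sum(scores_a >= threshold); tn <- sum(scores_a < threshold)
  list(counts = c(TP = tp, FP = fp, FN = fn, TN = tn),
       tss = if (tp + fn > 0 && tn + fp > 0)
         tp / (tp + fn) + tn / (tn + fp) - 1 else NA_real_,
       jaccard = if (tp + fp + fn > 0) tp / (tp + fp + fn) else NA_real_)
}

# a tiny fitted-model stub for ensemble-rule tests
stub_model <- function(suit, threshold, jaccard, id = "m") {
  list(learner_id = id, suitability = suit, threshold = threshold,
       metrics = list(jaccard = jaccard))
}

# cached small end-to-end study shared by several acceptance checks
study_cache <- new.env(parent = emptyenv())
small_study <- function() {
  if (is.null(study_cache$st))
    study_cache$st <- run_gap_study(
      seed = 11, n_rows = 24, n_cols = 24, n_layers = 4, n_species = 4,
      n_occ = 80, n_background = 2000, n_rand = 1000, n_basins = 8)
  study_cache$st
}
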