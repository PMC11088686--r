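#' Reduce an environmental stack to orthogonal principal-component axes
#'
#' Performs a PCA of the cell-wise covariance of the (pre-standardized)
#' layers over the valid cells and retains the minimal set of leading axes
#' whose cumulative explained variance reaches `variance_target` (default
#' 95%). The retained component scores, written back per cell, become the
#' model predictors, removing multicollinearity among the raw layers.
#'
#' The sign of each axis is fixed so its largest-magnitude loading is
#' positive, making the output deterministic across platforms.
#'
#' @param stack environmental [raster_stack()] (>= 2 layers, shared mask).
#' @param variance_target fraction of variance to retain (default 0.95).
#' @return object of class `pca_stack`: list with `axes` (a [raster_stack()]
#'   of retained score layers), `loadings` (layers x retained axes),
#'   `explained` (fraction per axis, all axes), `n_retained`, `center`.
#' @export
pca_reduce <- function(stack, variance_target = 0.95) {
  if (length(stack) < 2) stopf("need at least 2 layers")
  if (variance_target <= 0 || variance_target > 1)
    stopf("variance_target must lie in (0, 1]")
  cells <- stack_valid_cells(stack)
  X <- stack_values(stack, cells)
  if (length(cells) < ncol(X))
    stopf("fewer valid cells (%d) than layers (%d)", length(cells), ncol(X))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(expl) >= variance_target - 1e-12)[1]
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-|loading| entry of each axis made positive
  for (j in seq_len(k)) {
    m <- which.max(abs(rot[, j]))
    if (rot[m, j] < 0) rot[, j] <- -rot[, j]
  }
  scores <- sweep(X, 2L, pc$center) %*% rot
  axes <- lapply(seq_len(k), function(j) {
    r <- stack[[1]]
    r$values[] <- NA_real_
    r$values[cells] <- scores[, j]
    r
  })
  structure(list(
    axes = raster_stack(axes, names = sprintf("pc%02d", seq_len(k))),
    loadings = rot,
    explained = expl,
    n_retained = k,
    center = pc$center), class = "pca_stack")
}

#' @export
print.pca_stack <- function(x, ...) {
  cum <- cumsum(x$explained)
  cat(sprintf("<pca_stack> %d of %d axes retained (cumulative %.1f%%)\n",
              x$n_retained, length(x$explained), 100 * cum[x$n_retained]))
  cat("  explained:", paste(sprintf("%.3f", x$explained), collapse = " "),
      "\n")
  invisible(x)
}

#' Project new layer values onto retained axes
#'
#' @param object a `pca_stack`.
#' @param newdata matrix of raw layer values (columns in the original layer
#'   order).
#' @param ... unused.
#' @return matrix of component scores (columns = retained axes).
#' @export
predict.pca_stack <- function(object, newdata, ...) {
  sweep(as.matrix(newdata), 2L, object$center) %*% object$loadings
}

# Back-projection onto the original layer space, used to bound the
# information lost by truncation.
pca_reconstruct <- function(pca, scores) {
  sweep(scores %*% t(pca$loadings), 2L, pca$center, `+`)
}
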