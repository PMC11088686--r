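#' Envelope-based pseudo-absences
#'
#' Builds the per-axis environmental envelope (min-max box) of the presence
#' points and samples `n` cells uniformly among cells falling outside the
#' envelope on at least one axis — locations deemed unsuitable, where
#' two-class learners can be given "absence" data. If fewer than `n` such
#' cells exist, all of them are returned with a warning.
#'
#' @param presence_env matrix of axis values at the presence points.
#' @param env_stack a `pca_stack` or [raster_stack()] of predictor axes.
#' @param n number of pseudo-absences (default 50).
#' @param seed integer seed.
#' @return list of class `contrast_points`: `kind = "pseudo_absence"`,
#'   `cells` (flat indices), `points` (cell centers), `env` (axis values).
#' @export
envelope_pseudo_absences <- function(presence_env, env_stack, n = 50,
                                     seed = 1) {
  stack <- axes_stack(env_stack)
  presence_env <- as.matrix(presence_env)
  if (nrow(presence_env) < 5) stopf("need at least 5 presences")
  if (any(!is.finite(presence_env))) stopf("presence axis values must be finite")
  cells <- stack_valid_cells(stack)
  X <- stack_values(stack, cells)
  lo <- apply(presence_env, 2L, min)
  hi <- apply(presence_env, 2L, max)
  outside <- rep(FALSE, nrow(X))
  for (j in seq_len(ncol(X)))
    outside <- outside | X[, j] < lo[j] | X[, j] > hi[j]
  cand <- cells[outside]
  if (length(cand) < n) {
    warning(sprintf(
      "only %d cells outside the presence envelope (requested %d)",
      length(cand), n))
    chosen <- cand
  } else {
    chosen <- with_seed(derive_seed(seed, 53), sample(cand, n))
  }
  contrast_points("pseudo_absence", stack, chosen)
}

#' Uniform background points
#'
#' Samples `n` cells uniformly over the valid study area (with replacement
#' when `n` exceeds the number of valid cells), characterizing the available
#' environment for density-ratio learners.
#'
#' @param grid a `grid_raster` (or [raster_stack()] / `pca_stack`).
#' @param n number of points (default 10000).
#' @param seed integer seed.
#' @param env_stack optional predictor stack used to attach axis values.
#' @return list of class `contrast_points` with `kind = "background"`.
#' @export
sample_background <- function(grid, n = 10000, seed = 1, env_stack = NULL) {
  stack <- if (!is.null(env_stack)) axes_stack(env_stack)
    else if (is_grid_raster(grid)) NULL else axes_stack(grid)
  base <- if (is_grid_raster(grid)) grid else axes_stack(grid)[[1]]
  cells <- if (is.null(stack)) valid_cells(base) else stack_valid_cells(stack)
  if (!length(cells)) stopf("grid has no valid cells")
  chosen <- with_seed(derive_seed(seed, 59),
                      sample(cells, n, replace = n > length(cells)))
  if (is.null(stack)) {
    structure(list(kind = "background", cells = chosen,
                   points = cell_centers(base, chosen), env = NULL),
              class = "contrast_points")
  } else contrast_points("background", stack, chosen)
}

contrast_points <- function(kind, stack, cells) {
  structure(list(kind = kind, cells = cells,
                 points = cell_centers(stack[[1]], cells),
                 env = stack_values(stack, cells)),
            class = "contrast_points")
}

axes_stack <- function(x) {
  if (inherits(x, "pca_stack")) x$axes
  else if (inherits(x, "raster_stack")) x
  else stopf("expected a pca_stack or raster_stack")
}

#' Partition occurrence points for model evaluation
#'
#' Species with more than 30 points are partitioned by the chessboard
#' method: grid cells are colored alternately by (row + col) parity on an
#' aggregated block grid, points on one color train the model and points on
#' the other evaluate it. Species with 30 or fewer points get a seeded
#' random 70/30 split (at least one test point). If every point lands on one
#' chessboard color the partition degenerates and the random split is used
#' instead, with a warning.
#'
#' @param occ occurrence data.frame (`lon`, `lat`).
#' @param grid a `grid_raster` defining the cell lattice.
#' @param seed integer seed.
#' @param block_size chessboard block side in cells (default 1).
#' @return list of class `sdm_partition`: `scheme`, `train`, `test` (row
#'   indices into `occ`).
#' @export
partition_points <- function(occ, grid, seed = 1, block_size = 1) {
  n <- nrow(occ)
  if (n < 5) stopf("need at least 5 points")
  if (n > 30) {
    cells <- cells_from_xy(grid, occ$lon, occ$lat)
    nr <- nrow(grid$values)
    row <- (cells - 1L) %% nr + 1L
    col <- (cells - 1L) %/% nr + 1L
    parity <- ((row - 1L) %/% block_size + (col - 1L) %/% block_size) %% 2L
    train <- which(parity == 0L)
    test <- which(parity == 1L)
    if (length(train) && length(test)) {
      return(structure(list(scheme = "chessboard", train = train,
                            test = test), class = "sdm_partition"))
    }
    warning("chessboard partition degenerate; falling back to random split")
  }
  n_train <- round(0.7 * n)
  if (n_train >= n) n_train <- n - 1L
  if (n_train < 1L) n_train <- 1L
  train <- with_seed(derive_seed(seed, 61), sort(sample(n, n_train)))
  structure(list(scheme = "random_split", train = train,
                 test = setdiff(seq_len(n), train)),
            class = "sdm_partition")
}

#' Learner identifiers
#'
#' The four suitability learner families: a regularized log-linear
#' density-ratio model (`max_entropy`), a bagged-tree classifier
#' (`random_forest`), a kernel margin classifier (`support_vector`), and a
#' Gaussian class-conditional Bayes classifier (`gaussian_bayes`).
#' `max_entropy` and `gaussian_bayes` contrast presences against background
#' points; `random_forest` and `support_vector` require absence data and are
#' contrasted against envelope pseudo-absences.
#' @export
sdm_learners <- function() c("max_entropy", "random_forest",
                             "support_vector", "gaussian_bayes")

quad_features <- function(X) {
  X <- as.matrix(X)
  out <- cbind(X, X^2)
  colnames(out) <- c(colnames(X), paste0(colnames(X), "_sq"))
  out
}

log_dmvnorm <- function(X, mu, sigma) {
  p <- length(mu)
  sigma <- sigma + diag(1e-6, p)
  ch <- chol(sigma)
  z <- forwardsolve(t(ch), t(X) - mu)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * p * log(2 * pi)
}

rescale01 <- function(s) {
  rng <- range(s)
  if (rng[2] - rng[1] < 1e-12) return(rep(0.5, length(s)))
  (s - rng[1]) / (rng[2] - rng[1])
}

#' Fit one suitability learner
#'
#' Trains the chosen learner on presence versus contrast environments and
#' scores every grid cell, returning scores monotone-rescaled to \[0, 1\]
#' over the grid. All learners share this contract; internals differ per
#' family (see [sdm_learners()]).
#'
#' @param learner_id one of [sdm_learners()].
#' @param presence_env matrix of axis values at training presences.
#' @param contrast_env matrix of axis values at contrast points
#'   (background or pseudo-absences, per the learner's requirement).
#' @param env_stack `pca_stack` or [raster_stack()] used to score the grid.
#' @param settings named list of learner options (`ntree` for the forest,
#'   `cost`/`gamma` for the SVM).
#' @param seed integer seed (bagging).
#' @return suitability `grid_raster` in \[0, 1\].
#' @export
fit_learner <- function(learner_id, presence_env, contrast_env, env_stack,
                        settings = list(), seed = 1) {
  learner_id <- match.arg(learner_id, sdm_learners())
  stack <- axes_stack(env_stack)
  Xp <- as.matrix(presence_env); Xa <- as.matrix(contrast_env)
  if (!nrow(Xp) || !nrow(Xa)) stopf("empty training set")
  Xall <- rbind(Xp, Xa)
  if (nrow(unique(Xall)) < 2)
    stopf("degenerate training data: a single unique environment vector")
  cells <- stack_valid_cells(stack)
  G <- stack_values(stack, cells)
  colnames(Xp) <- colnames(Xa) <- colnames(G)

  score <- switch(learner_id,
    max_entropy = {
      y <- c(rep(1, nrow(Xp)), rep(0, nrow(Xa)))
      F <- quad_features(rbind(Xp, Xa))
      df <- data.frame(F, .y = y)
      fit <- suppressWarnings(
        stats::glm(.y ~ ., data = df, family = stats::binomial()))
      co <- stats::coef(fit)
      co[is.na(co)] <- 0  # aliased (collinear) features contribute nothing
      as.numeric(cbind(1, quad_features(G)) %*% co)
    },
    gaussian_bayes = {
      mu_p <- colMeans(Xp); mu_a <- colMeans(Xa)
      sg_p <- stats::cov(Xp); sg_a <- stats::cov(Xa)
      log_dmvnorm(G, mu_p, sg_p) - log_dmvnorm(G, mu_a, sg_a)
    },
    random_forest = {
      y <- factor(c(rep("pres", nrow(Xp)), rep("abs", nrow(Xa))),
                  levels = c("abs", "pres"))
      ntree <- settings$ntree %||% 500
      fit <- with_seed(derive_seed(seed, 67),
        randomForest::randomForest(x = rbind(Xp, Xa), y = y, ntree = ntree))
      stats::predict(fit, G, type = "prob")[, "pres"]
    },
    support_vector = {
      y <- factor(c(rep("pres", nrow(Xp)), rep("abs", nrow(Xa))),
                  levels = c("abs", "pres"))
      fit <- e1071::svm(x = rbind(Xp, Xa), y = y, kernel = "radial",
                        cost = settings$cost %||% 1,
                        gamma = settings$gamma %||% (1 / ncol(Xp)),
                        probability = FALSE)
      dec <- attr(stats::predict(fit, G, decision.values = TRUE),
                  "decision.values")[, 1]
      dtr <- attr(stats::predict(fit, rbind(Xp, Xa), decision.values = TRUE),
                  "decision.values")[, 1]
      # orient decision values so presences score high
      if (mean(dtr[seq_len(nrow(Xp))]) < mean(dtr[-seq_len(nrow(Xp))]))
        dec <- -dec
      dec
    })
  out <- stack[[1]]
  out$values[] <- NA_real_
  out$values[cells] <- rescale01(score)
  out
}

#' Suitability values at points
#'
#' @param suitability a `grid_raster`.
#' @param points two-column matrix/data.frame of coordinates, or a vector of
#'   flat cell indices.
#' @return numeric scores.
#' @export
suitability_at <- function(suitability, points) {
  cells <- if (is.matrix(points) || is.data.frame(points)) {
    pts <- as.matrix(points[, 1:2, drop = FALSE])
    cells_from_xy(suitability, pts[, 1], pts[, 2])
  } else as.integer(points)
  if (anyNA(cells)) stopf("some points fall outside the grid")
  suitability$values[cells]
}

#' Confusion-matrix counts at a threshold
#'
#' Presence is predicted where suitability >= threshold; counts are taken
#' over the test presences and test absences.
#'
#' @param suitability `grid_raster` of scores in \[0, 1\].
#' @param threshold cutoff in \[0, 1\].
#' @param test_presences,test_absences coordinates (or cell indices) of the
#'   evaluation points; both non-empty.
#' @return named integer vector `c(TP, FP, FN, TN)`.
#' @export
confusion_counts <- function(suitability, threshold, test_presences,
                             test_absences) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
    stopf("threshold must lie in [0, 1]")
  sp <- suitability_at(suitability, test_presences)
  sa <- suitability_at(suitability, test_absences)
  if (!length(sp) || !length(sa)) stopf("test sets must be non-empty")
  c(TP = sum(sp >= threshold), FP = sum(sa >= threshold),
    FN = sum(sp < threshold), TN = sum(sa < threshold))
}

#' True Skill Statistic
#'
#' `TSS = sensitivity + specificity - 1 = TP/(TP+FN) + TN/(TN+FP) - 1`,
#' ranging over \[-1, 1\]. An empty class (no test presences, or no test
#' absences) makes the statistic undefined; `NA` is returned with a warning
#' rather than a silent 0.
#'
#' @param counts named vector with `TP`, `FP`, `FN`, `TN` (as from
#'   [confusion_counts()]).
#' @return numeric TSS, or `NA` if undefined.
#' @export
tss <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  fn <- counts[["FN"]]; tn <- counts[["TN"]]
  if (tp + fn == 0 || tn + fp == 0) {
    warning("TSS undefined: empty presence or absence class")
    return(NA_real_)
  }
  tp / (tp + fn) + tn / (tn + fp) - 1
}

#' Jaccard index of a confusion matrix
#'
#' `TP / (TP + FP + FN)`: a discrimination metric built only from true
#' positives, false positives and false negatives, deliberately neglecting
#' true negatives (which inflate scores for low-prevalence species).
#'
#' @inheritParams tss
#' @return numeric in \[0, 1\], or `NA` (with a warning) if `TP+FP+FN = 0`.
#' @export
jaccard_index <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]; fn <- counts[["FN"]]
  if (tp + fp + fn == 0) {
    warning("Jaccard undefined: no positives observed or predicted")
    return(NA_real_)
  }
  tp / (tp + fp + fn)
}

auc_scores <- function(pos, neg) {
  r <- rank(c(pos, neg))
  np <- length(pos); nn <- length(neg)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the ROC curve
#'
#' Rank-based AUC: the probability that a random test presence outscores a
#' random test absence (ties counted half). Invariant under strictly
#' monotone transforms of the scores.
#'
#' @inheritParams confusion_counts
#' @return numeric in \[0, 1\].
#' @export
auc <- function(suitability, test_presences, test_absences) {
  sp <- suitability_at(suitability, test_presences)
  sa <- suitability_at(suitability, test_absences)
  if (!length(sp) || !length(sa)) stopf("test sets must be non-empty")
  auc_scores(sp, sa)
}

#' Select the Jaccard-optimal threshold
#'
#' Scans the sorted unique suitability values at the test points and returns
#' the cutoff maximizing the Jaccard index — the threshold minimizing
#' omission and commission errors relative to true positives. Ties are
#' broken toward the lower threshold.
#'
#' @inheritParams confusion_counts
#' @return list with `threshold` and `jaccard` (the value attained).
#' @export
select_threshold <- function(suitability, test_presences, test_absences) {
  sp <- suitability_at(suitability, test_presences)
  sa <- suitability_at(suitability, test_absences)
  if (!length(sp) || !length(sa)) stopf("test sets must be non-empty")
  cand <- sort(unique(c(sp, sa)))
  jac <- vapply(cand, function(th) {
    tp <- sum(sp >= th); fp <- sum(sa >= th); fn <- sum(sp < th)
    if (tp + fp + fn == 0) -Inf else tp / (tp + fp + fn)
  }, 0.0)
  best <- which.max(jac)  # which.max takes the first (lowest) on ties
  list(threshold = cand[best], jaccard = jac[best])
}

evaluate_at_threshold <- function(suitability, threshold, test_presences,
                                  test_absences) {
  cts <- confusion_counts(suitability, threshold, test_presences,
                          test_absences)
  sens <- cts[["TP"]] / (cts[["TP"]] + cts[["FN"]])
  spec <- cts[["TN"]] / (cts[["TN"]] + cts[["FP"]])
  list(counts = cts, sensitivity = sens, specificity = spec,
       tss = sens + spec - 1,
       jaccard = cts[["TP"]] / (cts[["TP"]] + cts[["FP"]] + cts[["FN"]]),
       auc = auc(suitability, test_presences, test_absences))
}

#' Fit the four-learner suitability model for one species
#'
#' The per-species workhorse: partitions the occurrences (chessboard above
#' 30 points, random 70/30 otherwise), builds envelope pseudo-absences and
#' uniform background points, fits every requested learner on its required
#' contrast (background for `max_entropy`/`gaussian_bayes`, pseudo-absences
#' for `random_forest`/`support_vector`), selects each learner's
#' Jaccard-optimal threshold on the held-out points, and records AUC, TSS,
#' Jaccard, sensitivity and specificity.
#'
#' Evaluation contrasts all learners against the held-out share of the
#' pseudo-absence set, so metrics are comparable across learners.
#'
#' @param occ cleaned occurrence data.frame for one species.
#' @param env `pca_stack` (or [raster_stack()]) of predictor axes.
#' @param learners subset of [sdm_learners()].
#' @param n_pseudo pseudo-absence count (default 50).
#' @param n_background background-point count (default 10000).
#' @param seed integer seed.
#' @param settings per-learner settings list.
#' @return object of class `sdm_fit`.
#' @export
fit_sdm <- function(occ, env, learners = sdm_learners(), n_pseudo = 50,
                    n_background = 10000, seed = 1, settings = list()) {
  if (nrow(occ) < 5) stopf("fewer than 5 occurrences; species unusable")
  stack <- axes_stack(env)
  grid <- stack[[1]]
  species <- if ("species" %in% names(occ) && nrow(occ))
    as.character(occ$species[1]) else "species"
  part <- partition_points(occ, grid, seed = derive_seed(seed, 2))
  pres_cells <- cells_from_xy(grid, occ$lon, occ$lat)
  if (anyNA(pres_cells)) stopf("occurrences fall outside the grid")
  pres_env <- stack_values(stack, pres_cells)
  pa <- envelope_pseudo_absences(pres_env, stack, n = n_pseudo,
                                 seed = derive_seed(seed, 3))
  bg <- sample_background(grid, n = n_background,
                          seed = derive_seed(seed, 5), env_stack = stack)
  n_pa <- nrow(pa$env)
  pa_train <- with_seed(derive_seed(seed, 7),
                        sort(sample(n_pa, max(1L, round(0.7 * n_pa)))))
  pa_test <- setdiff(seq_len(n_pa), pa_train)
  if (!length(pa_test)) { pa_test <- pa_train[length(pa_train)]
                          pa_train <- pa_train[-length(pa_train)] }
  test_p <- pres_cells[part$test]
  test_a <- pa$cells[pa_test]
  models <- lapply(learners, function(lid) {
    contrast <- if (lid %in% c("max_entropy", "gaussian_bayes")) bg$env
      else pa$env[pa_train, , drop = FALSE]
    suit <- fit_learner(lid, pres_env[part$train, , drop = FALSE], contrast,
                        stack, settings = settings[[lid]] %||% list(),
                        seed = derive_seed(seed, 11))
    sel <- select_threshold(suit, test_p, test_a)
    ev <- evaluate_at_threshold(suit, sel$threshold, test_p, test_a)
    list(learner_id = lid, suitability = suit, threshold = sel$threshold,
         metrics = list(auc = ev$auc, tss = ev$tss, jaccard = ev$jaccard,
                        sensitivity = ev$sensitivity,
                        specificity = ev$specificity))
  })
  names(models) <- learners
  structure(list(species = species, models = models, partition = part,
                 pseudo_absences = pa, background = bg,
                 test_presences = test_p, test_absences = test_a,
                 occurrences = occ, seed = seed),
            class = "sdm_fit")
}

#' @export
print.sdm_fit <- function(x, ...) {
  cat(sprintf("<sdm_fit> %s: %d occurrences (%s partition, %d train / %d test)\n",
              x$species, nrow(x$occurrences), x$partition$scheme,
              length(x$partition$train), length(x$partition$test)))
  print(summary(x))
  invisible(x)
}

#' @export
summary.sdm_fit <- function(object, ...) {
  do.call(rbind, lapply(object$models, function(m)
    data.frame(learner = m$learner_id, threshold = m$threshold,
               auc = m$metrics$auc, tss = m$metrics$tss,
               jaccard = m$metrics$jaccard, row.names = NULL)))
}
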