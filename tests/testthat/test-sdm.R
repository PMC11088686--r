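test_that("pseudo-absences respect the environmental envelope", {
  stack <- gradient_stack(20)  # axis values 0..1 by column

  # presences spanning the full axis range leave no candidate cells
  full <- matrix(c(0, 1), ncol = 1)
  expect_warning(pa0 <- envelope_pseudo_absences(rbind(full, full, full),
                                                 stack, n = 10),
                 "outside")
  expect_length(pa0$cells, 0L)

  # presences confined to [0.4, 0.6] force all pseudo-absences outside it
  inside <- matrix(seq(0.4, 0.6, length.out = 6), ncol = 1)
  pa <- envelope_pseudo_absences(inside, stack, n = 50, seed = 2)
  expect_length(pa$cells, 50L)
  expect_true(all(pa$env[, 1] < 0.4 | pa$env[, 1] > 0.6))
})

test_that("background sampling is uniform over valid cells", {
  g4 <- grid_raster(matrix(0, 2, 2))
  bg <- sample_background(g4, n = 10, seed = 1)
  expect_length(bg$cells, 10L)
  expect_true(all(bg$cells %in% 1:4))

  g100 <- grid_raster(matrix(0, 10, 10))
  bg2 <- sample_background(g100, n = 10000, seed = 3)
  tab <- tabulate(bg2$cells, 100)
  expect_gt(chisq.test(tab)$p.value, 0.01)

  expect_identical(sample_background(g100, 500, seed = 9)$cells,
                   sample_background(g100, 500, seed = 9)$cells)
})

test_that("partitioning switches schemes at 30 points with a 70/30 split below", {
  g <- build_grid(c(0, 1, 0, 1), 0.05)
  set.seed(6)
  occ31 <- data.frame(lon = runif(31), lat = runif(31))
  p31 <- partition_points(occ31, g, seed = 1)
  expect_equal(p31$scheme, "chessboard")
  expect_setequal(c(p31$train, p31$test), 1:31)
  expect_length(intersect(p31$train, p31$test), 0L)

  occ10 <- data.frame(lon = runif(10), lat = runif(10))
  p10 <- partition_points(occ10, g, seed = 1)
  expect_equal(p10$scheme, "random_split")
  expect_length(p10$train, 7L)
  expect_length(p10$test, 3L)

  # chessboard on uniformly spread points is roughly balanced
  set.seed(3)
  occ200 <- data.frame(lon = runif(200), lat = runif(200))
  p200 <- partition_points(occ200, g, seed = 1)
  expect_lt(abs(length(p200$train) - length(p200$test)),
            0.2 * max(length(p200$train), length(p200$test)))
})

test_that("every learner is monotone in a single informative axis", {
  stack <- gradient_stack(20)
  ax <- stack_values(stack)[, 1]
  set.seed(4)
  pres <- matrix(sort(ax[ax > 0.7])[sample(sum(ax > 0.7), 30, TRUE)],
                 ncol = 1)
  abs_ <- matrix(ax[ax < 0.3][sample(sum(ax < 0.3), 30, TRUE)], ncol = 1)
  for (lid in sdm_learners()) {
    suit <- fit_learner(lid, pres, abs_, stack, seed = 1)
    rho <- cor(ax, suit$values[stack_valid_cells(stack)],
               method = "spearman")
    expect_gt(rho, 0.9)
    expect_true(all(suit$values >= 0 & suit$values <= 1))
  }
})

test_that("uninformative training data yields flatter suitability than informative", {
  stack <- make_env_stack(landscape_spec(15, 15, n_layers = 2, seed = 3))
  X <- stack_values(stack)
  set.seed(5)
  idx <- sample(nrow(X), 40)
  same_p <- X[idx[1:20], , drop = FALSE]
  same_a <- X[idx[21:40], , drop = FALSE]
  ord <- order(X[, 1])
  info_p <- X[ord[(nrow(X) - 19):nrow(X)], , drop = FALSE]
  info_a <- X[ord[1:20], , drop = FALSE]
  for (lid in c("max_entropy", "gaussian_bayes")) {
    flat <- fit_learner(lid, same_p, same_a, stack, seed = 2)
    sharp <- fit_learner(lid, info_p, info_a, stack, seed = 2)
    expect_lt(var(as.vector(flat$values)), var(as.vector(sharp$values)))
  }
  expect_error(fit_learner("max_entropy", same_p[c(1, 1), ],
                           same_p[c(1, 1), ], stack), "degenerate")
  expect_error(fit_learner("nonsense", same_p, same_a, stack))
})

test_that("confusion counts match direct enumeration and boundary cases", {
  suit <- gradient_stack(4)[[1]]  # 16 cells, values by column
  cells <- 1:16
  scores <- suit$values[cells]
  pres <- cells[scores >= 0.6]
  abs_ <- cells[scores < 0.6]
  cts <- confusion_counts(suit, 0.6, pres, abs_)
  expect_equal(unname(cts), c(length(pres), 0L, 0L, length(abs_)),
               ignore_attr = TRUE)

  cts0 <- confusion_counts(suit, 0, pres, abs_)
  expect_equal(cts0[["FN"]], 0L)
  expect_equal(cts0[["TN"]], 0L)

  expect_error(confusion_counts(suit, 1.5, pres, abs_), "threshold")

  # hand-built 6-point case
  s6 <- grid_raster(matrix(c(0.9, 0.8, 0.4, 0.3, 0.2, 0.7), 1))
  cts6 <- confusion_counts(s6, 0.5, c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(cts6), c(2L, 1L, 1L, 2L), ignore_attr = TRUE)
})

test_that("tss and jaccard agree with exhaustive enumeration on 6 points", {
  scores <- c(0.9, 0.8, 0.55, 0.45, 0.3, 0.1)
  suit <- grid_raster(matrix(scores, 1))
  for (mask in 1:62) {  # all labelings with both classes present
    lab <- as.logical(bitwAnd(mask, 2^(0:5)))
    pres <- which(lab); absn <- which(!lab)
    for (th in c(0, 0.2, 0.5, 0.7, 1)) {
      cts <- confusion_counts(suit, th, pres, absn)
      bf <- bf_metrics(scores[pres], scores[absn], th)
      expect_identical(unname(cts), unname(bf$counts))
      if (!is.na(bf$tss)) expect_equal(tss(cts), bf$tss)
      if (!is.na(bf$jaccard)) expect_equal(jaccard_index(cts), bf$jaccard)
    }
  }
  expect_equal(tss(c(TP = 8, FN = 2, TN = 7, FP = 3)), 0.5)  # 0.8 + 0.7 - 1
  expect_equal(jaccard_index(c(TP = 10, FP = 5, FN = 5, TN = 0)), 0.5)
  expect_warning(tss(c(TP = 0, FN = 0, TN = 3, FP = 1)), "undefined")
  expect_warning(jaccard_index(c(TP = 0, FP = 0, FN = 0, TN = 5)),
                 "undefined")
})

test_that("auc is rank-based, calibrated at chance, and monotone-invariant", {
  set.seed(10)
  scores <- runif(200)
  suit <- grid_raster(matrix(scores, 10))
  pres <- 1:100; absn <- 101:200
  a <- auc(suit, pres, absn)
  expect_gt(a, 0.4); expect_lt(a, 0.6)

  # strictly monotone transform leaves auc unchanged
  suit2 <- suit; suit2$values <- suit$values^3
  expect_equal(auc(suit2, pres, absn), a)

  # separable case
  sep <- grid_raster(matrix(c(0.9, 0.8, 0.1, 0.2), 1))
  expect_equal(auc(sep, 1:2, 3:4), 1)
})

test_that("threshold selection maximizes Jaccard with ties to the low side", {
  sep <- grid_raster(matrix(c(0.9, 0.8, 0.2, 0.1), 1))
  sel <- select_threshold(sep, 1:2, 3:4)
  expect_equal(sel$jaccard, 1)
  expect_equal(sel$threshold, 0.8)  # lowest candidate attaining 1

  # 6-point case versus brute-force scan over all candidates
  scores <- c(0.85, 0.7, 0.65, 0.5, 0.45, 0.2)
  suit <- grid_raster(matrix(scores, 1))
  pres <- c(1, 2, 4); absn <- c(3, 5, 6)
  sel2 <- select_threshold(suit, pres, absn)
  cand <- sort(unique(scores))
  jac <- sapply(cand, function(th)
    bf_metrics(scores[pres], scores[absn], th)$jaccard)
  expect_equal(sel2$jaccard, max(jac))
  expect_equal(sel2$threshold, cand[which.max(jac)])

  # all test points share one score
  one <- grid_raster(matrix(rep(0.4, 4), 1))
  expect_equal(select_threshold(one, 1:2, 3:4)$threshold, 0.4)
})

test_that("fit_sdm assembles per-learner models with sane metrics", {
  stack <- make_env_stack(landscape_spec(20, 20, n_layers = 2,
                                         autocorrelation_range = 4,
                                         seed = 21))
  suit <- make_true_suitability(stack, species_truth(c(0.5, -0.5),
                                                     c(0.5, 0.5)))
  occ <- sample_occurrences(suit, 60, seed = 2)
  occ <- clean_records(occ, stack[[1]])$occurrences
  pca <- pca_reduce(stack, 0.95)
  fit <- fit_sdm(occ, pca, n_background = 1000, seed = 3)
  expect_s3_class(fit, "sdm_fit")
  expect_named(fit$models, sdm_learners())
  for (m in fit$models) {
    expect_true(all(m$suitability$values >= 0 & m$suitability$values <= 1,
                    na.rm = TRUE))
    expect_gte(m$threshold, 0); expect_lte(m$threshold, 1)
    expect_gte(m$metrics$tss, -1); expect_lte(m$metrics$tss, 1)
    expect_gte(m$metrics$jaccard, 0); expect_lte(m$metrics$jaccard, 1)
  }
  s <- summary(fit)
  expect_equal(nrow(s), 4L)
})

test_that("rank-based auc agrees with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(13)
  scores <- c(rnorm(60, 1), rnorm(80))
  suit <- grid_raster(matrix(scores, 10))
  a <- auc(suit, 1:60, 61:140)
  ref <- suppressMessages(as.numeric(pROC::auc(
    c(rep(1, 60), rep(0, 80)), scores, direction = "<")))
  expect_equal(a, ref, tolerance = 1e-12)
})
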