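test_that("75% coverage classification from a fine categorical raster", {
  g <- build_grid(c(0, 2, 0, 2), cell_size = 1)  # 2 x 2 analysis cells
  # fine raster at 4x resolution: 16 subcells per analysis cell
  fine <- build_grid(c(0, 2, 0, 2), cell_size = 0.25)
  fv <- matrix(0, 8, 8)
  fv[1:4, 1:4] <- 1          # top-left cell: 100% SPA
  fv[1:4, 5:8][1:13] <- 2    # top-right: 13/16 = 81% SUA
  fv[5:8, 1:4][1:8] <- 1     # bottom-left: 50% SPA ...
  fv[5:8, 1:4][9:16] <- 2    # ... and 50% SUA -> unprotected at 0.75
  # bottom-right all zero: fully outside -> unprotected
  fr <- grid_raster(fv, cellsize = 0.25,
                    levels = c("unprotected", "SPA", "SUA", "IT"))
  pmap <- classify_cells(g, fr, coverage_threshold = 0.75)
  expect_equal(pmap$values[1, 1], 1)  # SPA
  expect_equal(pmap$values[1, 2], 2)  # SUA (81% >= 75%)
  expect_equal(pmap$values[2, 1], 0)  # split 50/50: unprotected
  expect_equal(pmap$values[2, 2], 0)

  # at a permissive threshold the split cell resolves by precedence SPA > SUA
  pmap2 <- classify_cells(g, fr, coverage_threshold = 0.5)
  expect_equal(pmap2$values[2, 1], 1)
})

test_that("coverage-fraction rasters classify identically to the rule", {
  g <- build_grid(c(0, 3, 0, 1), cell_size = 1)
  frs <- list(SPA = grid_raster(matrix(c(0.8, 0.5, 0), 1)),
              SUA = grid_raster(matrix(c(0, 0.5, 0.2), 1)),
              IT = grid_raster(matrix(c(0.2, 0, 0.75), 1)))
  pmap <- classify_cells(g, frs)
  expect_equal(as.vector(pmap$values), c(1, 0, 3))
})

test_that("species percentages partition to 100 with the hierarchical cumulative", {
  pm <- grid_raster(matrix(c(1, 1, 2, 2, 3, 3, 3, 0), 1),
                    levels = c("unprotected", "SPA", "SUA", "IT"))
  rng <- grid_raster(matrix(1, 1, 8))
  row <- species_percentages(rng, pm, "sp")
  expect_equal(c(row$pct_SPA, row$pct_SUA, row$pct_IT, row$pct_unprotected),
               c(25, 25, 37.5, 12.5))
  expect_equal(c(row$cum_SPA, row$cum_SPA_SUA, row$cum_SPA_SUA_IT),
               c(25, 50, 87.5))
  expect_equal(row$pct_SPA + row$pct_SUA + row$pct_IT + row$pct_unprotected,
               100, tolerance = 1e-9)
  expect_equal(row$cum_SPA_SUA_IT, 100 - row$pct_unprotected)

  # all presence inside IT
  it_only <- grid_raster(matrix(c(0, 0, 0, 0, 1, 1, 1, 0), 1))
  row2 <- species_percentages(it_only, pm)
  expect_equal(c(row2$pct_SPA, row2$pct_SUA, row2$pct_IT,
                 row2$pct_unprotected), c(0, 0, 100, 0))
  expect_equal(c(row2$cum_SPA, row2$cum_SPA_SUA, row2$cum_SPA_SUA_IT),
               c(0, 0, 100))

  # whole-grid range reproduces the category shares
  g <- build_grid(c(0, 1, 0, 1), 0.05)
  pm2 <- make_protection_map(g, seed = 5)
  whole <- g; whole$values[] <- 1
  row3 <- species_percentages(whole, pm2)
  shares <- 100 * table(factor(pm2$values, levels = 0:3)) / 400
  expect_equal(c(row3$pct_unprotected, row3$pct_SPA, row3$pct_SUA,
                 row3$pct_IT), as.vector(shares))

  expect_error(species_percentages(grid_raster(matrix(0, 1, 8)), pm),
               "presence")
})

test_that("one-way ANOVA matches the classical formula and is calibrated", {
  same <- list(c(1, 2, 3), c(2, 1, 3), c(3, 2, 1))
  res <- one_way_anova(same)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)

  groups <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  res2 <- one_way_anova(groups)
  # direct evaluation of F = (SSB/df_b) / (SSW/df_w)
  y <- unlist(groups); gm <- mean(y)
  ssb <- sum(3 * (sapply(groups, mean) - gm)^2)
  ssw <- sum(unlist(lapply(groups, function(g) (g - mean(g))^2)))
  f_direct <- (ssb / 2) / (ssw / 6)
  expect_equal(res2$F, f_direct, tolerance = 1e-10)
  expect_equal(res2$df_between, 2)
  expect_equal(res2$df_within, 6)
  expect_equal(res2$p, pf(f_direct, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)

  # label shuffling gives approximately uniform p-values
  set.seed(30)
  pooled <- rnorm(30)
  ps <- replicate(100, {
    lab <- sample(rep(1:3, each = 10))
    one_way_anova(split(pooled, lab))$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)

  # degenerate all-equal data flagged rather than fabricated
  deg <- one_way_anova(list(c(1, 1), c(1, 1)))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$F))

  expect_error(one_way_anova(list(1:3)), "2 groups")
  expect_error(one_way_anova(list(1:3, 5)), "at least 2 values")
})

test_that("randomization test: degenerate cases and exact enumeration", {
  pm6 <- grid_raster(matrix(c(1, 1, 0, 0, 0, 0), 1),
                     levels = c("unprotected", "SPA", "SUA", "IT"))
  # constant importance: every draw ties the observed mean -> p = 1
  const <- grid_raster(matrix(0.5, 1, 6))
  r1 <- mc_randomization(const, pm6, "SPA", n_rand = 200, seed = 1)
  expect_equal(r1$p, 1)

  # target = all valid cells: every draw is the full set -> p = 1
  allp <- grid_raster(matrix(c(1, 1, 1, 1, 1, 1), 1),
                      levels = c("unprotected", "SPA", "SUA", "IT"))
  imp6 <- grid_raster(matrix((1:6) / 6, 1))
  r2 <- mc_randomization(imp6, allp, "SPA", n_rand = 100, seed = 2)
  expect_equal(r2$p, 1)

  # 2-cell target on 6 cells: exact p over all C(6,2) = 15 subsets
  obs <- mean(imp6$values[1:2])
  combs <- combn(6, 2)
  exact <- mean(apply(combs, 2, function(ix) mean(imp6$values[ix])) >= obs)
  r3 <- mc_randomization(imp6, pm6, "SPA", n_rand = 10000, seed = 3)
  expect_equal(r3$observed_mean, obs)
  expect_lt(abs(r3$p - exact), 0.02)

  expect_error(mc_randomization(imp6, pm6, "IT", n_rand = 10), "empty")
})

test_that("randomization p-values are calibrated under the null and powered", {
  g <- build_grid(c(0, 1, 0, 1), 0.05)  # 400 cells
  r <- g; set.seed(31); r$values[] <- runif(400)
  imp <- rank_cells(list(r))

  # null: targets drawn uniformly at random -> p approximately uniform
  ps <- sapply(1:200, function(i) {
    pm <- g
    pm$values[] <- 0
    set.seed(1000 + i)
    pm$values[sample(400, 40)] <- 1
    attr(pm, "levels") <- c("unprotected", "SPA", "SUA", "IT")
    mc_randomization(imp, pm, "SPA", n_rand = 200, seed = i)$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)

  # power: the top importance decile as target is detected at p <= 0.01
  top <- imp$removal_order[361:400]
  pm <- g; pm$values[] <- 0; pm$values[top] <- 1
  attr(pm, "levels") <- c("unprotected", "SPA", "SUA", "IT")
  res <- mc_randomization(imp, pm, "SPA", n_rand = 1000, seed = 7)
  expect_lte(res$p, 0.01)
})
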