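#' Classify analysis-grid cells into protection categories
#'
#' Applies the fractional-coverage rule: a cell is assigned to SPA, SUA or
#' IT only when at least `coverage_threshold` (default 75%) of its area
#' falls in that category; cells reaching the threshold for no category are
#' "unprotected". With a threshold above 0.5 double assignment is
#' geometrically impossible (asserted); for configurable thresholds at or
#' below 0.5 the precedence SPA > SUA > IT (more restrictive first) is
#' applied.
#'
#' @param grid the analysis `grid_raster` (e.g. from [build_grid()]).
#' @param categories either a categorical `grid_raster` of codes with levels
#'   `c("unprotected", "SPA", "SUA", "IT")` — on the analysis geometry, or on
#'   a finer grid whose dimensions are integer multiples (coverage fractions
#'   are then computed by exact cell counting) — or a named list
#'   `list(SPA =, SUA =, IT =)` of coverage-fraction rasters on the analysis
#'   geometry.
#' @param coverage_threshold fraction in (0, 1\] (default 0.75).
#' @return categorical `grid_raster` (codes 0:3, levels unprotected/SPA/
#'   SUA/IT) on the analysis geometry.
#' @export
classify_cells <- function(grid, categories, coverage_threshold = 0.75) {
  if (coverage_threshold <= 0 || coverage_threshold > 1)
    stopf("coverage_threshold must lie in (0, 1]")
  cats <- c("SPA", "SUA", "IT")
  nr <- nrow(grid$values); ncl <- ncol(grid$values)
  frac <- array(0, c(nr, ncl, 3))
  if (is_grid_raster(categories)) {
    lv <- attr(categories, "levels")
    if (is.null(lv)) stopf("categorical raster needs a `levels` attribute")
    fact <- categories$cellsize / grid$cellsize
    fine_per_coarse <- round(1 / fact)
    if (abs(fine_per_coarse * categories$cellsize - grid$cellsize) > 1e-9)
      stopf("category raster cell size must evenly divide the grid cell size")
    f <- fine_per_coarse
    if (nrow(categories$values) != nr * f ||
        ncol(categories$values) != ncl * f)
      stopf("category raster extent does not match the analysis grid")
    for (ci in seq_along(cats)) {
      code <- match(cats[ci], lv) - 1L
      hit <- (categories$values == code) * 1
      hit[is.na(hit)] <- 0
      if (f == 1L) frac[, , ci] <- hit
      else frac[, , ci] <- aggregate_raster(
        grid_raster(hit, cellsize = categories$cellsize), f, "mean")$values
    }
  } else if (is.list(categories)) {
    for (ci in seq_along(cats)) {
      r <- categories[[cats[ci]]]
      if (is.null(r)) next
      if (!same_geometry(r, grid)) stopf("fraction rasters must share the grid")
      v <- r$values; v[is.na(v)] <- 0
      frac[, , ci] <- v
    }
  } else stopf("unsupported `categories` input")
  out <- matrix(NA_real_, nr, ncl)
  valid <- !is.na(grid$values)
  out[valid] <- 0
  hits <- frac >= coverage_threshold
  if (coverage_threshold > 0.5) {
    nhit <- hits[, , 1] + hits[, , 2] + hits[, , 3]
    stopifnot("double category assignment is impossible above 0.5" =
                all(nhit[valid] <= 1))
  }
  for (ci in 3:1)  # reverse order implements SPA > SUA > IT precedence
    out[valid & hits[, , ci]] <- ci
  grid_raster(out, xmin = grid$xmin, ymin = grid$ymin,
              cellsize = grid$cellsize,
              levels = c("unprotected", "SPA", "SUA", "IT"))
}

category_cells <- function(pmap, category) {
  lv <- attr(pmap, "levels")
  codes <- match(category, lv) - 1L
  if (anyNA(codes)) stopf("unknown category: %s",
                          paste(category[is.na(codes)], collapse = ", "))
  which(pmap$values %in% codes)
}

#' Per-species protection percentages
#'
#' Computes the share of a species' distribution falling in each protection
#' category, plus the hierarchical cumulative shares (SPA alone, SPA + SUA,
#' SPA + SUA + IT) that express what protection level is reached as
#' progressively less restrictive categories are added.
#'
#' @param binary_range 0/1 presence `grid_raster` on the analysis geometry
#'   (a finer binary range is transferred by majority rule).
#' @param pmap categorical protection map from [classify_cells()] (or
#'   [make_protection_map()]).
#' @param species species label for the output row.
#' @return one-row data.frame: `species`, `n_cells`, `pct_SPA`, `pct_SUA`,
#'   `pct_IT`, `pct_unprotected`, `cum_SPA`, `cum_SPA_SUA`,
#'   `cum_SPA_SUA_IT`.
#' @export
species_percentages <- function(binary_range, pmap, species = "species") {
  if (!same_geometry(binary_range, pmap)) {
    f <- round(pmap$cellsize / binary_range$cellsize)
    if (f < 1 || abs(f * binary_range$cellsize - pmap$cellsize) > 1e-9)
      stopf("binary range geometry incompatible with protection map")
    binary_range <- aggregate_raster(binary_range, f, "majority")
  }
  pres <- which(!is.na(binary_range$values) & binary_range$values > 0 &
                  !is.na(pmap$values))
  if (!length(pres)) stopf("species has no presence cells on the grid")
  lv <- attr(pmap, "levels")
  cat_of <- lv[pmap$values[pres] + 1L]
  pct <- function(x) 100 * sum(cat_of == x) / length(pres)
  p_spa <- pct("SPA"); p_sua <- pct("SUA"); p_it <- pct("IT")
  p_un <- pct("unprotected")
  data.frame(species = species, n_cells = length(pres),
             pct_SPA = p_spa, pct_SUA = p_sua, pct_IT = p_it,
             pct_unprotected = p_un,
             cum_SPA = p_spa, cum_SPA_SUA = p_spa + p_sua,
             cum_SPA_SUA_IT = p_spa + p_sua + p_it,
             stringsAsFactors = FALSE)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA:
#' `F = (SSB / df_between) / (SSW / df_within)` with the p-value from the
#' upper tail of the F distribution. The case of zero variance both within
#' and between groups is undefined and flagged (`NA` statistics with
#' `degenerate = TRUE`).
#'
#' @param groups list of numeric vectors (>= 2 groups, each with >= 2
#'   values).
#' @return list `F`, `df_between`, `df_within`, `p`, `degenerate`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) stopf("need at least 2 groups")
  if (any(lengths(groups) < 2)) stopf("each group needs at least 2 values")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(y) <= length(groups)) stopf("too few observations")
  if (stats::var(y) == 0)
    return(list(F = NA_real_, df_between = length(groups) - 1L,
                df_within = length(y) - length(groups), p = NA_real_,
                degenerate = TRUE))
  ow <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(F = unname(ow$statistic), df_between = unname(ow$parameter[1]),
       df_within = unname(ow$parameter[2]), p = unname(ow$p.value),
       degenerate = FALSE)
}

#' Protection gap report across species
#'
#' Assembles the per-species percentage table and runs the one-way ANOVA
#' asking whether some protection category holds a systematically higher
#' share of the species' ranges (species are the replicates; the four
#' groups are the SPA, SUA, IT and unprotected percentage columns).
#'
#' @param ranges named list of 0/1 presence rasters (one per species).
#' @param pmap protection map (see [species_percentages()]).
#' @return object of class `gap_report`: `percentages` (data.frame),
#'   `anova`, `anova_cumulative`.
#' @export
gap_report <- function(ranges, pmap) {
  if (!length(ranges)) stopf("no species ranges supplied")
  nm <- names(ranges) %||% sprintf("species_%d", seq_along(ranges))
  tab <- do.call(rbind, Map(function(r, s) species_percentages(r, pmap, s),
                            ranges, nm))
  rownames(tab) <- NULL
  an <- one_way_anova(list(SPA = tab$pct_SPA, SUA = tab$pct_SUA,
                           IT = tab$pct_IT,
                           unprotected = tab$pct_unprotected))
  an_cum <- one_way_anova(list(SPA = tab$cum_SPA,
                               SPA_SUA = tab$cum_SPA_SUA,
                               SPA_SUA_IT = tab$cum_SPA_SUA_IT))
  structure(list(percentages = tab, anova = an, anova_cumulative = an_cum),
            class = "gap_report")
}

#' @export
print.gap_report <- function(x, digits = 1, ...) {
  tab <- x$percentages
  cat(sprintf("<gap_report> %d species\n", nrow(tab)))
  cat(sprintf("  mean %% of range: SPA %.1f  SUA %.1f  IT %.1f  unprotected %.1f\n",
              mean(tab$pct_SPA), mean(tab$pct_SUA), mean(tab$pct_IT),
              mean(tab$pct_unprotected)))
  cat(sprintf("  mean cumulative: SPA %.1f  +SUA %.1f  +IT %.1f\n",
              mean(tab$cum_SPA), mean(tab$cum_SPA_SUA),
              mean(tab$cum_SPA_SUA_IT)))
  if (!x$anova$degenerate)
    cat(sprintf("  ANOVA (category %%): F(%d, %d) = %.2f, p = %.3g\n",
                x$anova$df_between, x$anova$df_within, x$anova$F, x$anova$p))
  invisible(x)
}

#' Monte Carlo randomization test of mean importance in a protection class
#'
#' Tests whether the cells of a protection class are more important for
#' conservation than a random set of the same size: the observed mean rank
#' fraction over the class is compared with `n_rand` means of equally sized
#' uniform draws (without replacement) from all valid cells, and
#' `p = #\{draw mean >= observed\} / n_rand`. A raw p of 0 is kept (its
#' resolution is `1/n_rand`); the print method displays it as
#' `< 1/n_rand`.
#'
#' @param importance a `cell_importance` (or rank-fraction `grid_raster`).
#' @param pmap protection map on the same geometry.
#' @param target one category (`"SPA"`, `"SUA"`, `"IT"`, `"unprotected"`) or
#'   a union, e.g. `c("SPA", "SUA", "IT")` for "all protected".
#' @param n_rand number of randomizations (default 10000).
#' @param seed integer seed.
#' @return object of class `mc_rand`: `category`, `observed_mean`,
#'   `randomized_mean`, `n_randomizations`, `n_cells`, `p`.
#' @export
mc_randomization <- function(importance, pmap, target, n_rand = 10000,
                             seed = 1) {
  if (n_rand < 1) stopf("n_rand must be >= 1")
  rf <- if (inherits(importance, "cell_importance"))
    importance$rank_fraction else importance
  if (!same_geometry(rf, pmap)) stopf("importance and map geometries differ")
  pool <- which(!is.na(rf$values) & !is.na(pmap$values))
  tcells <- intersect(category_cells(pmap, target), pool)
  if (!length(tcells)) stopf("target class is empty")
  k <- length(tcells)
  if (k > length(pool)) stopf("target larger than the valid-cell pool")
  vals <- rf$values[pool]
  obs <- mean(rf$values[tcells])
  draws <- with_seed(derive_seed(seed, 71),
    vapply(seq_len(n_rand),
           function(i) mean(vals[sample.int(length(pool), k)]), 0.0))
  structure(list(category = paste(target, collapse = "+"),
                 observed_mean = obs, randomized_mean = mean(draws),
                 n_randomizations = n_rand, n_cells = k,
                 p = sum(draws >= obs) / n_rand),
            class = "mc_rand")
}

#' @export
print.mc_rand <- function(x, ...) {
  pshow <- if (x$p == 0) sprintf("< %g", 1 / x$n_randomizations)
    else sprintf("%g", x$p)
  cat(sprintf(
    "<mc_rand> %s (%d cells): observed mean %.4f vs randomized %.4f, p %s (%d draws)\n",
    x$category, x$n_cells, x$observed_mean, x$randomized_mean, pshow,
    x$n_randomizations))
  invisible(x)
}
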