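#' Clean raw occurrence records
#'
#' Applies the standard record-exclusion rules for distribution modeling:
#' records with missing coordinates are dropped, records without a parseable
#' collection date in the 1900-2022 search window are dropped, exact
#' coordinate duplicates are collapsed to the first record, and points
#' falling outside the study extent are dropped. Every rejection is logged
#' with the rule that fired.
#'
#' @param records data.frame with columns `species`, `lon`, `lat`, `date`,
#'   `source` (the occurrence CSV layout). May be empty.
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` or a `grid_raster` whose
#'   bounding box is used.
#' @return list with `occurrences` (the cleaned data.frame) and `log`
#'   (data.frame `record`, `species`, `rule`), one log row per rejection.
#' @examples
#' recs <- data.frame(species = "sp", lon = c(0.5, NA, 0.5), lat = 0.5,
#'                    date = c(NA, "1980-01-01", "1980-01-01"),
#'                    source = "x")
#' clean_records(recs, c(0, 1, 0, 1))  # keeps only the third record
#' @export
clean_records <- function(records, extent) {
  if (is_grid_raster(extent)) {
    v <- extent
    extent <- c(v$xmin, v$xmin + ncol(v$values) * v$cellsize,
                v$ymin, v$ymin + nrow(v$values) * v$cellsize)
  }
  log0 <- data.frame(record = integer(0), species = character(0),
                     rule = character(0), stringsAsFactors = FALSE)
  if (!nrow(records)) return(list(occurrences = records, log = log0))
  rule <- rep(NA_character_, nrow(records))

  no_coord <- is.na(records$lon) | is.na(records$lat)
  rule[no_coord] <- "missing_coordinates"

  yr <- suppressWarnings(as.integer(sub("^\\s*(\\d{4}).*$", "\\1",
                                        as.character(records$date))))
  bad_date <- is.na(records$date) | is.na(yr) | yr < 1900 | yr > 2022
  rule[is.na(rule) & bad_date] <- "missing_or_invalid_date"

  outside <- !no_coord &
    (records$lon < extent[1] | records$lon > extent[2] |
       records$lat < extent[3] | records$lat > extent[4])
  rule[is.na(rule) & outside] <- "outside_extent"

  ok <- which(is.na(rule))  # duplicates judged among surviving records only
  key <- paste(records$species, records$lon, records$lat, sep = "\r")
  rule[ok[duplicated(key[ok])]] <- "duplicate_coordinates"

  keep <- is.na(rule)
  rejected <- which(!keep)
  list(
    occurrences = {
      out <- records[keep, , drop = FALSE]
      rownames(out) <- NULL
      out
    },
    log = data.frame(record = rejected,
                     species = as.character(records$species[rejected]),
                     rule = rule[rejected], stringsAsFactors = FALSE))
}

# Moran's I for one binary weight matrix (W symmetric 0/1, zero diagonal).
moran_i_binary <- function(values, W) {
  z <- values - mean(values)
  s2 <- sum(z^2)
  if (s2 == 0) return(NA_real_)
  n <- length(values)
  s0 <- sum(W)
  if (s0 == 0) return(NA_real_)
  (n / s0) * as.numeric(t(z) %*% W %*% z) / s2
}

# Permutation test of Moran's I for one weight matrix, vectorized: all
# permuted quadratic forms come from a single W %*% Z product. z'z and S0
# are permutation-invariant, so only the numerator varies.
perm_moran <- function(values, W, n_perm, seed) {
  i_obs <- moran_i_binary(values, W)
  if (is.na(i_obs)) return(list(I = NA_real_, p = 1))
  n <- length(values)
  z <- values - mean(values)
  s2 <- sum(z^2); s0 <- sum(W)
  Zp <- with_seed(seed, vapply(seq_len(n_perm - 1L),
                               function(i) z[sample(n)], numeric(n)))
  i_perm <- (n / s0) * colSums(Zp * (W %*% Zp)) / s2
  list(I = i_obs, p = (1 + sum(abs(i_perm) >= abs(i_obs))) / n_perm)
}

#' Moran's correlogram with permutation tests
#'
#' Bins the pairwise linear distances between points into `n_classes`
#' equal-width classes and computes Moran's I per class with binary weights
#' (a pair contributes weight 1 in its class). Significance per class comes
#' from a permutation test of the values over the points: the observed
#' arrangement counts as one permutation, so
#' `p = (1 + #\{|I_perm| >= |I_obs|\}) / n_perm` and p is never below
#' `1 / n_perm`.
#'
#' Constant values make Moran's I undefined (zero variance); such classes are
#' reported with `I = NA`, `p = 1` and `degenerate = TRUE` rather than being
#' treated as significant.
#'
#' @param points two-column matrix or data.frame of coordinates (>= 5 points).
#' @param values finite numeric vector, one value per point.
#' @param n_classes number of distance classes; default Sturges' rule on the
#'   number of pairs.
#' @param n_perm number of permutations (observed arrangement included).
#' @param seed integer seed for the permutations.
#' @return data.frame with one row per class: `class`, `d_lower`, `d_upper`,
#'   `n_pairs`, `I`, `p`, `degenerate`.
#' @export
morans_correlogram <- function(points, values, n_classes = NULL,
                               n_perm = 999, seed = 1) {
  pts <- as.matrix(points[, 1:2, drop = FALSE])
  n <- nrow(pts)
  if (n < 5) stopf("at least 5 points are required (got %d)", n)
  if (any(!is.finite(values)) || length(values) != n)
    stopf("`values` must be finite, one per point")
  D <- as.matrix(stats::dist(pts))
  npairs <- n * (n - 1) / 2
  if (is.null(n_classes)) n_classes <- max(2L, ceiling(log2(npairs)) + 1L)
  dmax <- max(D)
  if (dmax == 0) dmax <- 1  # all points coincident: one class holds all pairs
  breaks <- seq(0, dmax, length.out = n_classes + 1)
  zvar <- stats::var(values) > 0
  out <- lapply(seq_len(n_classes), function(k) {
    lo <- breaks[k]; hi <- breaks[k + 1]
    W <- (if (k == 1) D >= lo else D > lo) & D <= hi
    diag(W) <- FALSE
    W <- W * 1
    np <- sum(W) / 2
    if (!zvar || np == 0) {
      return(data.frame(class = k, d_lower = lo, d_upper = hi, n_pairs = np,
                        I = NA_real_, p = 1, degenerate = !zvar))
    }
    pm <- perm_moran(values, W, n_perm, derive_seed(seed, 41 + k))
    data.frame(class = k, d_lower = lo, d_upper = hi, n_pairs = np,
               I = pm$I, p = pm$p, degenerate = FALSE)
  })
  do.call(rbind, out)
}

#' Thin occurrences until first-class spatial autocorrelation is gone
#'
#' Iteratively removes points until the first distance class of the Moran's
#' correlogram on the supplied environmental values is non-significant at
#' `alpha`, or until only 5 points remain (the minimum usable occurrence
#' count). At each step the closest pair is found and its member with the
#' higher local density (more neighbors within the first-class distance;
#' ties: the lower record index) is dropped — exact coordinate duplicates are
#' distance-0 pairs and therefore go first.
#'
#' @param occ cleaned occurrence data.frame (columns `lon`, `lat`, ...).
#' @param env_values numeric vector of an environmental variable at the
#'   points (by convention the first PCA axis of the predictor stack, since
#'   environmental autocorrelation is what biases the models).
#' @param alpha significance level (default 0.05).
#' @param n_classes,n_perm passed to [morans_correlogram()].
#' @param seed integer seed.
#' @return list with `occurrences` (a subset of the input rows), `removed`
#'   (original row indices dropped) and `iterations`.
#' @export
autocorr_filter <- function(occ, env_values, alpha = 0.05, n_classes = NULL,
                            n_perm = 999, seed = 1) {
  if (nrow(occ) < 5) stopf("fewer than 5 occurrences; species unusable")
  if (length(env_values) != nrow(occ))
    stopf("env_values must match the occurrence rows")
  keep <- seq_len(nrow(occ))
  vals <- env_values
  it <- 0L
  repeat {
    pts <- as.matrix(occ[keep, c("lon", "lat")])
    n <- length(keep)
    D <- as.matrix(stats::dist(pts))
    npairs <- n * (n - 1) / 2
    ncl <- n_classes %||% max(2L, ceiling(log2(npairs)) + 1L)
    d_upper <- max(D, 1e-300) / ncl  # upper bound of the first class
    W <- (D <= d_upper) * 1
    diag(W) <- 0
    first <- if (stats::var(vals[keep]) == 0 || sum(W) == 0)
      list(I = NA_real_, p = 1)
      else perm_moran(vals[keep], W, n_perm, derive_seed(seed, 100 + it))
    significant <- !is.na(first$I) && first$p < alpha && first$I > 0
    if (!significant || n <= 5) break
    diag(D) <- Inf
    mn <- which(D == min(D), arr.ind = TRUE)[1, ]
    i <- mn[1]; j <- mn[2]
    dens <- rowSums(D <= d_upper)
    drop_local <- if (dens[i] > dens[j]) i
      else if (dens[j] > dens[i]) j
      else min(i, j)
    keep <- keep[-drop_local]
    it <- it + 1L
  }
  out <- occ[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(occurrences = out, removed = setdiff(seq_len(nrow(occ)), keep),
       iterations = it)
}
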