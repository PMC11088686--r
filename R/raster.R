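#' Lightweight single-band raster
#'
#' A `grid_raster` is a rectangular cell lattice with an origin, a square cell
#' size and an `NA` nodata mask. It is the common spatial frame for
#' environmental layers, suitability surfaces, conservation-importance maps,
#' and categorical protection/basin maps. Values are stored as a numeric
#' matrix whose first row is the *top* (northernmost) row of the grid, the
#' usual raster convention.
#'
#' Categorical rasters are `grid_raster` objects holding integer codes plus a
#' `levels` attribute mapping code `i` to `levels[i + 1]` (code 0 is the first
#' level).
#'
#' @param values numeric matrix; `NA` marks nodata cells.
#' @param xmin,ymin coordinates of the lower-left corner of the grid.
#' @param cellsize side length of a (square) cell, in map units
#'   (degrees for a geographic grid, abstract length otherwise).
#' @param levels optional character vector of category labels for integer
#'   codes `0:(length(levels) - 1)`.
#' @return an object of class `grid_raster`.
#' @export
grid_raster <- function(values, xmin = 0, ymin = 0, cellsize = 1,
                        levels = NULL) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0)
    stop("`cellsize` must be a single positive number")
  storage.mode(values) <- "double"
  r <- structure(
    list(values = values, xmin = xmin, ymin = ymin, cellsize = cellsize),
    class = "grid_raster")
  if (!is.null(levels)) attr(r, "levels") <- as.character(levels)
  r
}

#' @export
print.grid_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<grid_raster> %d x %d cells, cellsize %g, origin (%g, %g)\n",
              nrow(v), ncol(v), x$cellsize, x$xmin, x$ymin))
  cat(sprintf("  valid cells: %d / %d", sum(!is.na(v)), length(v)))
  lv <- attr(x, "levels")
  if (!is.null(lv)) {
    cat("  categories:", paste(lv, collapse = ", "))
  } else {
    rng <- suppressWarnings(range(v, na.rm = TRUE))
    if (all(is.finite(rng))) cat(sprintf("  range [%g, %g]", rng[1], rng[2]))
  }
  cat("\n")
  invisible(x)
}

#' @rdname grid_raster
#' @param x object to test.
#' @export
is_grid_raster <- function(x) inherits(x, "grid_raster")

#' Build an empty analysis grid over an extent
#'
#' Creates the regular lattice used as the analysis frame, e.g. the 0.05
#' degree grid overlaid on a study region. The number of rows/columns is the
#' smallest count of whole cells covering the extent (an extent smaller than
#' one cell yields a single cell). An optional mask marks cells outside the
#' study polygon as nodata so they are excluded from all denominators.
#'
#' @param extent numeric `c(xmin, xmax, ymin, ymax)`.
#' @param cell_size positive cell side length (default 0.05).
#' @param mask optional logical matrix (`TRUE` = keep) with the implied
#'   dimensions, or a function `f(x, y)` returning `TRUE` inside the study
#'   area, evaluated at cell centers.
#' @return a `grid_raster` with value 0 on valid cells and `NA` elsewhere.
#' @examples
#' g <- build_grid(c(0, 1, 0, 1), cell_size = 0.05)  # 20 x 20 = 400 cells
#' @export
build_grid <- function(extent, cell_size = 0.05, mask = NULL) {
  if (length(extent) != 4L || !is.numeric(extent))
    stop("`extent` must be numeric c(xmin, xmax, ymin, ymax)")
  if (extent[2] <= extent[1] || extent[4] <= extent[3])
    stop("degenerate extent")
  if (!is.numeric(cell_size) || cell_size <= 0)
    stop("`cell_size` must be positive")
  nc <- max(1L, ceiling((extent[2] - extent[1]) / cell_size - 1e-9))
  nr <- max(1L, ceiling((extent[4] - extent[3]) / cell_size - 1e-9))
  vals <- matrix(0, nr, nc)
  r <- grid_raster(vals, xmin = extent[1], ymin = extent[3],
                   cellsize = cell_size)
  if (!is.null(mask)) {
    if (is.function(mask)) {
      ctr <- cell_centers(r, seq_len(nr * nc))
      keep <- matrix(mask(ctr[, 1], ctr[, 2]), nr, nc)
    } else keep <- mask
    if (!identical(dim(keep), dim(vals)))
      stop("mask dimensions do not match grid")
    r$values[!keep] <- NA_real_
  }
  r
}

n_cells <- function(r) length(r$values)

#' @rdname grid_raster
#' @param r a `grid_raster`.
#' @export
valid_cells <- function(r) which(!is.na(r$values))

#' Coordinates of cell centers
#'
#' @param r a `grid_raster`.
#' @param cells flat cell indices (column-major, as returned by [valid_cells()]).
#' @return two-column matrix of x, y center coordinates.
#' @export
cell_centers <- function(r, cells) {
  nr <- nrow(r$values)
  row <- (cells - 1L) %% nr + 1L
  col <- (cells - 1L) %/% nr + 1L
  cbind(x = r$xmin + (col - 0.5) * r$cellsize,
        y = r$ymin + (nr - row + 0.5) * r$cellsize)
}

#' Map point coordinates to flat cell indices
#'
#' Points outside the grid map to `NA`.
#'
#' @param r a `grid_raster`.
#' @param x,y point coordinates.
#' @return integer vector of flat (column-major) cell indices.
#' @export
cells_from_xy <- function(r, x, y) {
  nr <- nrow(r$values); ncl <- ncol(r$values)
  col <- floor((x - r$xmin) / r$cellsize) + 1L
  rowfromtop <- nr - floor((y - r$ymin) / r$cellsize)
  ok <- col >= 1L & col <= ncl & rowfromtop >= 1L & rowfromtop <= nr
  idx <- ifelse(ok, (col - 1L) * nr + rowfromtop, NA_integer_)
  as.integer(idx)
}

same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$xmin, a$ymin, a$cellsize),
                     c(b$xmin, b$ymin, b$cellsize)))
}

#' Stack of co-registered rasters
#'
#' @param layers list of `grid_raster` objects sharing one geometry.
#' @param names optional layer names.
#' @return object of class `raster_stack` (a named list of layers).
#' @export
raster_stack <- function(layers, names = NULL) {
  if (!length(layers)) stop("empty stack")
  if (!all(vapply(layers, is_grid_raster, TRUE)))
    stop("all layers must be grid_raster objects")
  for (l in layers[-1])
    if (!same_geometry(layers[[1]], l)) stop("layers differ in geometry")
  if (is.null(names)) names <- sprintf("layer%02d", seq_along(layers))
  structure(stats::setNames(layers, names), class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  cat(sprintf("<raster_stack> %d layers: %s\n", length(x),
              paste(names(x), collapse = ", ")))
  print(x[[1]])
  invisible(x)
}

#' Extract stack values as a cells-by-layers matrix
#'
#' @param stack a `raster_stack`.
#' @param cells flat cell indices; default all cells valid in every layer.
#' @return numeric matrix with one column per layer.
#' @export
stack_values <- function(stack, cells = NULL) {
  if (is.null(cells)) cells <- stack_valid_cells(stack)
  m <- vapply(stack, function(l) l$values[cells], numeric(length(cells)))
  if (length(cells) == 1L) m <- matrix(m, nrow = 1L)
  colnames(m) <- names(stack)
  m
}

stack_valid_cells <- function(stack) {
  ok <- !is.na(stack[[1]]$values)
  for (l in stack[-1]) ok <- ok & !is.na(l$values)
  which(ok)
}

#' Write / read a raster as an ESRI ASCII grid
#'
#' Plain-text, GDAL-readable serialization used for all raster outputs. The
#' writer is deterministic (fixed `%.10g` formatting), so identical rasters
#' produce byte-identical files.
#'
#' @param r a `grid_raster`.
#' @param path file path (conventionally `.asc`).
#' @param nodata value written for `NA` cells.
#' @export
write_asc <- function(r, path, nodata = -9999) {
  v <- r$values
  hdr <- c(sprintf("ncols %d", ncol(v)),
           sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", r$xmin),
           sprintf("yllcorner %.10g", r$ymin),
           sprintf("cellsize %.10g", r$cellsize),
           sprintf("NODATA_value %.10g", nodata))
  v[is.na(v)] <- nodata
  rows <- apply(v, 1L, function(z) paste(sprintf("%.10g", z), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path) {
  ln <- readLines(path)
  hdr <- ln[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  body <- strsplit(trimws(ln[-(1:6)]), "\\s+")
  v <- do.call(rbind, lapply(body, as.numeric))
  v[v == h[["nodata_value"]]] <- NA_real_
  grid_raster(v, xmin = h[["xllcorner"]], ymin = h[["yllcorner"]],
              cellsize = h[["cellsize"]])
}

#' Export a categorical raster as GeoJSON rectangles
#'
#' Writes one Polygon feature per cell (grouped per category in the
#' `category` property); intended for small desk-scale grids where a
#' rectangle-per-cell representation is acceptable to downstream GIS tools.
#'
#' @param r categorical `grid_raster` (integer codes with a `levels`
#'   attribute).
#' @param path output `.geojson` path.
#' @export
write_category_geojson <- function(r, path) {
  lv <- attr(r, "levels")
  if (is.null(lv)) stop("raster has no `levels` attribute")
  nr <- nrow(r$values)
  cells <- valid_cells(r)
  feats <- lapply(cells, function(i) {
    row <- (i - 1L) %% nr + 1L
    col <- (i - 1L) %/% nr + 1L
    x0 <- r$xmin + (col - 1L) * r$cellsize
    y0 <- r$ymin + (nr - row) * r$cellsize
    x1 <- x0 + r$cellsize; y1 <- y0 + r$cellsize
    ring <- list(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0))
    list(type = "Feature",
         properties = list(category = lv[r$values[i] + 1L], cell = i),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  obj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Aggregate a fine raster to a coarser grid
#'
#' Aggregates blocks of `fact` x `fact` cells into one coarse cell, either by
#' the mean (continuous layers) or by majority vote (categorical layers, ties
#' to the smaller code). Used to transfer species ranges and protection maps
#' onto the analysis grid.
#'
#' @param r a `grid_raster` whose dimensions are multiples of `fact`.
#' @param fact positive integer aggregation factor.
#' @param fun `"mean"` or `"majority"`.
#' @return the aggregated `grid_raster`.
#' @export
aggregate_raster <- function(r, fact, fun = c("mean", "majority")) {
  fun <- match.arg(fun)
  fact <- as.integer(fact)
  v <- r$values
  if (nrow(v) %% fact != 0L || ncol(v) %% fact != 0L)
    stop("raster dimensions must be multiples of `fact`")
  nr2 <- nrow(v) %/% fact; nc2 <- ncol(v) %/% fact
  out <- matrix(NA_real_, nr2, nc2)
  for (i in seq_len(nr2)) for (j in seq_len(nc2)) {
    blk <- v[((i - 1L) * fact + 1L):(i * fact),
             ((j - 1L) * fact + 1L):(j * fact)]
    blk <- blk[!is.na(blk)]
    if (!length(blk)) next
    out[i, j] <- if (fun == "mean") mean(blk) else {
      tab <- table(blk)
      as.numeric(names(tab)[which.max(tab)])  # which.max: first (smallest) wins ties
    }
  }
  grid_raster(out, xmin = r$xmin, ymin = r$ymin,
              cellsize = r$cellsize * fact, levels = attr(r, "levels"))
}
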