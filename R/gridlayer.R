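#' Georeferenced grid layer
#'
#' `grid_layer` is the package's common currency for environmental fields,
#' habitat-suitability surfaces and presence/absence ranges: a north-up,
#' row-major rectangular lattice of square cells in geographic (longitude /
#' latitude) coordinates.  The centre of cell (r, c) (1-based) lies at
#' `(origin_lon + (c - 0.5) * cell_size, origin_lat - (r - 0.5) * cell_size)`,
#' where the origin is the grid's upper-left corner.  Missing cells are held
#' as `NA` internally; `nodata` is the sentinel used on disk.
#'
#' @param values numeric matrix (rows x cols); cells equal to `nodata` are
#'   converted to `NA`.
#' @param origin_lon,origin_lat upper-left corner, decimal degrees.
#' @param cell_size cell edge, decimal degrees (> 0).
#' @param nodata sentinel written for missing cells on export.
#' @return an object of class `grid_layer`.
#' @seealso [binary_range()], [read_ascii_grid()], [write_ascii_grid()]
#' @export
grid_layer <- function(values, origin_lon, origin_lat, cell_size,
                       nodata = -9999) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_input("`values` must be a numeric matrix")
  stopifnot(length(origin_lon) == 1L, length(origin_lat) == 1L,
            length(cell_size) == 1L)
  if (!is.finite(cell_size) || cell_size <= 0)
    stop_input("`cell_size` must be a positive number of degrees")
  values[!is.na(values) & values == nodata] <- NA_real_
  structure(
    list(values = values,
         origin_lon = as.numeric(origin_lon),
         origin_lat = as.numeric(origin_lat),
         cell_size = as.numeric(cell_size),
         nodata = as.numeric(nodata)),
    class = "grid_layer")
}

#' @export
print.grid_layer <- function(x, ...) {
  v <- x$values
  cat(sprintf("<%s> %d x %d cells, %.6g deg, origin (%.6g, %.6g)\n",
              class(x)[1L], nrow(v), ncol(v), x$cell_size,
              x$origin_lon, x$origin_lat))
  cat(sprintf("  valid cells: %d; value range: [%s, %s]\n",
              sum(!is.na(v)),
              format(suppressWarnings(min(v, na.rm = TRUE))),
              format(suppressWarnings(max(v, na.rm = TRUE)))))
  invisible(x)
}

is_grid_layer <- function(x) inherits(x, "grid_layer")

#' Do two layers share the same lattice?
#'
#' Layers are aligned iff shape, origin and cell size match exactly (within
#' 1e-9 degrees for the floating-point fields).  All cellwise operations in
#' the package require alignment and never resample silently.
#'
#' @param a,b `grid_layer` objects.
#' @return `TRUE` or `FALSE`.
#' @export
grids_aligned <- function(a, b) {
  stopifnot(is_grid_layer(a), is_grid_layer(b))
  identical(dim(a$values), dim(b$values)) &&
    abs(a$origin_lon - b$origin_lon) < 1e-9 &&
    abs(a$origin_lat - b$origin_lat) < 1e-9 &&
    abs(a$cell_size - b$cell_size) < 1e-9
}

check_aligned <- function(...) {
  layers <- list(...)
  for (i in seq_along(layers)[-1L])
    if (!grids_aligned(layers[[1L]], layers[[i]]))
      stop_input("grid layers are not aligned (shape, origin and cell size ",
                 "must match exactly)")
  invisible(TRUE)
}

# Cell-centre coordinate helpers (1-based row/col indices).
cell_lons <- function(layer) layer$origin_lon +
  (seq_len(ncol(layer$values)) - 0.5) * layer$cell_size
cell_lats <- function(layer) layer$origin_lat -
  (seq_len(nrow(layer$values)) - 0.5) * layer$cell_size

# Matrices of per-cell centre coordinates, same shape as `values`.
cell_lon_matrix <- function(layer)
  matrix(cell_lons(layer), nrow(layer$values), ncol(layer$values),
         byrow = TRUE)
cell_lat_matrix <- function(layer)
  matrix(cell_lats(layer), nrow(layer$values), ncol(layer$values))

# Row/col index of the cell containing a point; NA when outside the grid.
# Boundary convention: a point on a cell's upper/left edge belongs to it.
point_cell <- function(layer, lon, lat) {
  col <- floor((lon - layer$origin_lon) / layer$cell_size) + 1
  row <- floor((layer$origin_lat - lat) / layer$cell_size) + 1
  bad <- is.na(lon) | is.na(lat) |
    col < 1 | col > ncol(layer$values) | row < 1 | row > nrow(layer$values)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Per-cell area in square kilometres
#'
#' Cell area follows the cosine-latitude rule on a sphere of radius 6371 km:
#' `(cell_size * pi/180 * 6371)^2 * cos(centre latitude)`.  Rows whose centre
#' latitude exceeds 89.5 degrees in absolute value are rejected to avoid the
#' polar degeneracy.
#'
#' @param layer a `grid_layer`.
#' @return matrix of areas (km^2), same shape as `layer$values`.
#' @export
cell_area_km2 <- function(layer) {
  stopifnot(is_grid_layer(layer))
  lats <- cell_lats(layer)
  if (any(abs(lats) > 89.5))
    stop_input("grid rows with |centre latitude| > 89.5 degrees are not ",
               "supported")
  edge <- layer$cell_size * pi / 180 * 6371
  matrix(edge^2 * cos(lats * pi / 180),
         nrow(layer$values), ncol(layer$values))
}

#' Presence/absence range
#'
#' A `binary_range` is a `grid_layer` whose valid cells are exactly 0 or 1,
#' augmented with its 1-cell count and cosine-latitude-weighted area.
#'
#' @param layer a `grid_layer` with values in \{0, 1, NA\}.
#' @return an object of classes `binary_range`, `grid_layer` with elements
#'   `cell_count` and `area_km2`.
#' @export
binary_range <- function(layer) {
  stopifnot(is_grid_layer(layer))
  v <- layer$values
  ok <- is.na(v) | v == 0 | v == 1
  if (!all(ok))
    stop_input("binary range values must be 0, 1 or missing")
  layer$cell_count <- sum(v == 1, na.rm = TRUE)
  layer$area_km2 <- if (layer$cell_count == 0) 0 else
    sum(cell_area_km2(layer)[!is.na(v) & v == 1])
  class(layer) <- unique(c("binary_range", class(layer)))
  layer
}

is_binary_range <- function(x) inherits(x, "binary_range")

#' Depth-weighted soil aggregation
#'
#' Collapses per-depth soil layers to a single surface for the first metre of
#' soil: a per-cell weighted mean with weights proportional to the thickness
#' of each depth interval.  The default intervals are 0-5, 5-15, 15-30,
#' 30-60 and 60-100 cm (thicknesses 5, 10, 15, 30, 40).  A missing value at
#' any depth propagates to the output.
#'
#' @param layers list of aligned `grid_layer`s, one per depth interval.
#' @param depth_intervals_cm two-column matrix of (top, bottom) depths;
#'   intervals must be contiguous from 0.
#' @return a `grid_layer` of weighted means.
#' @export
depth_weighted_soil <- function(layers,
                                depth_intervals_cm = cbind(
                                  top = c(0, 5, 15, 30, 60),
                                  bottom = c(5, 15, 30, 60, 100))) {
  stopifnot(is.list(layers), length(layers) >= 1L)
  depth_intervals_cm <- as.matrix(depth_intervals_cm)
  if (nrow(depth_intervals_cm) != length(layers))
    stop_input("one depth interval per layer is required")
  if (depth_intervals_cm[1L, 1L] != 0 ||
      any(depth_intervals_cm[-1L, 1L] !=
          depth_intervals_cm[-nrow(depth_intervals_cm), 2L]))
    stop_input("depth intervals must be contiguous from 0")
  do.call(check_aligned, layers)
  thick <- depth_intervals_cm[, 2L] - depth_intervals_cm[, 1L]
  w <- thick / sum(thick)
  out <- layers[[1L]]$values * w[1L]
  for (i in seq_along(layers)[-1L]) out <- out + layers[[i]]$values * w[i]
  res <- layers[[1L]]
  res$values <- out
  res
}

#' Mask out excluded land-cover cells
#'
#' Cells flagged 1 in the exclusion mask (e.g. urban areas, water bodies,
#' bare areas, permanent snow/ice) become missing in the layer and so drop
#' out of every downstream area, count and sum.
#'
#' @param layer a `grid_layer` (or `binary_range`, whose counts are
#'   recomputed).
#' @param mask a `binary_range` aligned with `layer`; 1 = exclude.
#' @return a layer of the same class as `layer`.
#' @export
apply_exclusion_mask <- function(layer, mask) {
  stopifnot(is_grid_layer(layer), is_binary_range(mask))
  check_aligned(layer, mask)
  drop <- !is.na(mask$values) & mask$values == 1
  layer$values[drop] <- NA_real_
  if (is_binary_range(layer)) {
    class(layer) <- setdiff(class(layer), "binary_range")
    layer$cell_count <- NULL
    layer$area_km2 <- NULL
    layer <- binary_range(layer)
  }
  layer
}

#' Taxon richness map
#'
#' Cellwise count of presences over a set of aligned ranges.
#'
#' @param ranges non-empty list of aligned `binary_range`s.
#' @return a `grid_layer` of integer counts (missing cells count as absence).
#' @export
richness_map <- function(ranges) {
  if (!is.list(ranges) || length(ranges) == 0L)
    stop_input("`ranges` must be a non-empty list of binary ranges")
  stopifnot(all(vapply(ranges, is_binary_range, logical(1L))))
  do.call(check_aligned, ranges)
  acc <- matrix(0, nrow(ranges[[1L]]$values), ncol(ranges[[1L]]$values))
  for (r in ranges) {
    pres <- !is.na(r$values) & r$values == 1
    acc <- acc + pres
  }
  out <- ranges[[1L]]
  class(out) <- "grid_layer"
  out$cell_count <- NULL
  out$area_km2 <- NULL
  out$values <- acc
  out
}

#' Read an ESRI ASCII grid
#'
#' Parses the plain-text ESRI ASCII raster dialect (ncols/nrows/xllcorner/
#' yllcorner/cellsize/NODATA_value header, rows north to south).  The nodata
#' sentinel is honoured exactly.
#'
#' @param path file path.
#' @return a `grid_layer`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, n = 6L)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(parts) == 2L && is.na(suppressWarnings(as.numeric(parts[1L])))) {
      hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
      n_hdr <- n_hdr + 1L
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop_input("not an ESRI ASCII grid: missing header fields in ", path)
  nodata <- hdr[["nodata_value"]] %||% -9999
  vals <- scan(path, what = double(), skip = n_hdr, quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop_input("ASCII grid body has ", length(vals), " values; expected ",
               nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  grid_layer(m,
             origin_lon = hdr$xllcorner,
             origin_lat = hdr$yllcorner + nr * hdr$cellsize,
             cell_size = hdr$cellsize,
             nodata = nodata)
}

#' Write an ESRI ASCII grid
#'
#' @param layer a `grid_layer`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(layer, path) {
  stopifnot(is_grid_layer(layer))
  v <- layer$values
  v[is.na(v)] <- layer$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10f", layer$origin_lon),
    sprintf("yllcorner %.10f", layer$origin_lat - nrow(v) * layer$cell_size),
    sprintf("cellsize %.10f", layer$cell_size),
    sprintf("NODATA_value %s", format(layer$nodata))), con)
  writeLines(apply(v, 1L, function(row)
    paste(sprintf("%.17g", row), collapse = " ")), con)
  invisible(path)
}
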