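#' Regular lon/lat grid specification
#'
#' Describes a cell-center-registered regular grid in geographic coordinates
#' (WGS84, decimal degrees).  Cells are half-open intervals
#' `[origin + k*d, origin + (k+1)*d)` on each axis, so every point of the
#' domain belongs to exactly one cell; the center of cell `(i, j)` is
#' `origin + (k + 0.5)*d`.
#'
#' @param lon_origin,lat_origin Lower-left corner of cell (0, 0), degrees.
#' @param dlon,dlat Positive cell sizes, degrees.
#' @param ncols,nrows Positive integer grid dimensions.
#' @return An object of class `grid_spec`.
#' @examples
#' gs <- grid_spec(0, 50, 0.5, 0.5, 20, 10)
#' head(cell_centers(gs))
#' @export
grid_spec <- function(lon_origin, lat_origin, dlon, dlat, ncols, nrows) {
  stopifnot(is.numeric(lon_origin), is.numeric(lat_origin))
  if (!(dlon > 0 && dlat > 0))
    stop_trawlcover("grid cell sizes must be positive", "grid_error")
  ncols <- as.integer(ncols); nrows <- as.integer(nrows)
  if (ncols < 1L || nrows < 1L)
    stop_trawlcover("grid dimensions must be positive integers", "grid_error")
  if (lon_origin + ncols * dlon > 360 + 1e-9 ||
      lat_origin < -90 - 1e-9 || lat_origin + nrows * dlat > 90 + 1e-9)
    stop_trawlcover("grid does not fit within the globe", "grid_error")
  structure(
    list(lon_origin = lon_origin, lat_origin = lat_origin,
         dlon = dlon, dlat = dlat, ncols = ncols, nrows = nrows),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %g x %g deg, origin (%g, %g)\n",
              x$nrows, x$ncols, x$dlon, x$dlat, x$lon_origin, x$lat_origin))
  invisible(x)
}

#' @export
format.grid_spec <- function(x, ...) {
  sprintf("%dx%d@%gx%g+(%g,%g)", x$nrows, x$ncols, x$dlon, x$dlat,
          x$lon_origin, x$lat_origin)
}

grid_spec_equal <- function(a, b, tol = 1e-9) {
  a$ncols == b$ncols && a$nrows == b$nrows &&
    abs(a$lon_origin - b$lon_origin) < tol &&
    abs(a$lat_origin - b$lat_origin) < tol &&
    abs(a$dlon - b$dlon) < tol && abs(a$dlat - b$dlat) < tol
}

#' Cell centers of a grid
#'
#' @param spec A [grid_spec].
#' @return A data.frame with `lon`, `lat`, `col`, `row` (1-based, row 1 is the
#'   southernmost row), one line per cell in column-major (row-fastest) order
#'   matching the layout of `values(layer)`.
#' @export
cell_centers <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  lon <- spec$lon_origin + (seq_len(spec$ncols) - 0.5) * spec$dlon
  lat <- spec$lat_origin + (seq_len(spec$nrows) - 0.5) * spec$dlat
  data.frame(lon = rep(lon, each = spec$nrows),
             lat = rep(lat, times = spec$ncols),
             col = rep(seq_len(spec$ncols), each = spec$nrows),
             row = rep(seq_len(spec$nrows), times = spec$ncols))
}

#' Locate points on a grid
#'
#' Half-open cell membership: a point exactly on a shared edge belongs to the
#' cell whose half-open interval contains it.
#'
#' @param spec A [grid_spec].
#' @param lon,lat Point coordinates, degrees.
#' @return A data.frame with 1-based `col` and `row`; `NA` for points outside
#'   the grid.
#' @export
cell_index <- function(spec, lon, lat) {
  stopifnot(inherits(spec, "grid_spec"))
  col <- floor((lon - spec$lon_origin) / spec$dlon) + 1
  row <- floor((lat - spec$lat_origin) / spec$dlat) + 1
  bad <- col < 1 | col > spec$ncols | row < 1 | row > spec$nrows
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(col = as.integer(col), row = as.integer(row))
}

#' Georeferenced raster layer
#'
#' A single-band raster on a [grid_spec].  Values are stored as an
#' `nrows x ncols` matrix with row 1 the southernmost row; `NA` marks missing
#' cells, which are excluded from all denominators downstream.
#'
#' @param spec A [grid_spec].
#' @param values Numeric or logical matrix of dimension `nrows x ncols`, or a
#'   single value to fill.
#' @param units Unit string (`"m"`, `"mg/m3"`, `"events"`, `"tons/year"`,
#'   `"probability"`, `"kg/km2"`, ...).
#' @return An object of class `grid_layer`.
#' @export
grid_layer <- function(spec, values, units = "") {
  stopifnot(inherits(spec, "grid_spec"))
  if (length(values) == 1L)
    values <- matrix(values, spec$nrows, spec$ncols)
  if (!is.matrix(values) || nrow(values) != spec$nrows ||
      ncol(values) != spec$ncols)
    stop_trawlcover(
      sprintf("values must be a %d x %d matrix", spec$nrows, spec$ncols),
      "grid_error")
  if (identical(units, "probability")) {
    v <- values[!is.na(values)]
    if (length(v) && (min(v) < 0 || max(v) > 1))
      stop_trawlcover("probability layer outside [0, 1]", "validation_error")
  }
  structure(list(spec = spec, values = values, units = units),
            class = "grid_layer")
}

#' @rdname grid_layer
#' @param layer A `grid_layer`.
#' @export
layer_values <- function(layer) {
  stopifnot(inherits(layer, "grid_layer"))
  layer$values
}

#' @rdname grid_layer
#' @export
layer_spec <- function(layer) {
  stopifnot(inherits(layer, "grid_layer"))
  layer$spec
}

#' @export
print.grid_layer <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("grid_layer [%s] %s; %d/%d cells non-missing",
              x$units, format(x$spec), length(v), length(x$values)))
  if (length(v) && is.numeric(v))
    cat(sprintf("; range %.4g..%.4g", min(v), max(v)))
  cat("\n")
  invisible(x)
}

#' @export
plot.grid_layer <- function(x, main = x$units, ...) {
  s <- x$spec
  lon <- s$lon_origin + (seq_len(s$ncols) - 0.5) * s$dlon
  lat <- s$lat_origin + (seq_len(s$nrows) - 0.5) * s$dlat
  graphics::image(lon, lat, t(x$values * 1), main = main,
                  xlab = "lon", ylab = "lat", ...)
  invisible(x)
}

#' Spherical cell areas of a grid
#'
#' Exact area of each lon/lat quadrangle cell on the authalic sphere,
#' `R^2 * dlambda * (sin(phi2) - sin(phi1))`.
#'
#' @param spec A [grid_spec].
#' @return Matrix of cell areas in km², same layout as layer values.
#' @export
cell_areas_km2 <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  r <- .authalic_radius_km
  lat1 <- spec$lat_origin + (seq_len(spec$nrows) - 1) * spec$dlat
  lat2 <- lat1 + spec$dlat
  band <- r^2 * (spec$dlon * pi / 180) *
    (sin(lat2 * pi / 180) - sin(lat1 * pi / 180))
  matrix(band, spec$nrows, spec$ncols)
}

.authalic_radius_km <- 6371.0072
.mean_radius_km <- 6371.0088

stop_trawlcover <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "trawlcover_error")))
}

#' Normalize longitudes
#'
#' @param lon Longitudes in degrees.
#' @param range `"180"` for \eqn{[-180, 180)} (the package default) or
#'   `"360"` for \eqn{[0, 360)}, the recentered mode used for point sets and
#'   grids straddling the antimeridian (e.g. Bering Sea surveys).
#' @return Normalized longitudes.
#' @export
normalize_lon <- function(lon, range = c("180", "360")) {
  range <- match.arg(range)
  out <- lon %% 360
  if (range == "180") out <- ((out + 180) %% 360) - 180
  out
}
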