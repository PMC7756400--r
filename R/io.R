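#' Read and validate a haul table
#'
#' A haul is one bottom-trawl tow, the atomic geo-referenced sample of a
#' survey.  The table must carry `survey_id`, `lon`, `lat`, `year`;
#' `depth_m` and `distance_to_coast_nm` are optional.
#'
#' @param path CSV file (UTF-8, header row).
#' @param year_window Allowed study window for `year`, inclusive.
#' @return A validated data.frame of hauls, row order preserved, with the
#'   number of records reported as attribute `n_records`.
#' @export
read_hauls <- function(path, year_window = c(2001, 2019)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_hauls(df, year_window)
}

#' @rdname read_hauls
#' @param hauls A data.frame of hauls.
#' @export
validate_hauls <- function(hauls, year_window = c(2001, 2019)) {
  mandatory <- c("survey_id", "lon", "lat", "year")
  missing_col <- setdiff(mandatory, names(hauls))
  if (length(missing_col))
    stop_trawlcover(
      sprintf("missing mandatory column(s): %s",
              paste(missing_col, collapse = ", ")),
      "schema_error")
  check_range <- function(field, lo, hi, hi_open = FALSE) {
    v <- hauls[[field]]
    bad <- which(!is.na(v) & (v < lo | if (hi_open) v >= hi else v > hi))
    if (length(bad))
      stop_trawlcover(
        sprintf("%s out of range [%g, %g%s] at row %d (value %g)",
                field, lo, hi, if (hi_open) ")" else "", bad[1], v[bad[1]]),
        "validation_error", row = bad[1])
  }
  check_range("lon", -180, 180, hi_open = TRUE)
  check_range("lat", -90, 90)
  check_range("year", year_window[1], year_window[2])
  if ("depth_m" %in% names(hauls)) check_range("depth_m", 0, Inf)
  if ("distance_to_coast_nm" %in% names(hauls))
    check_range("distance_to_coast_nm", 0, Inf)
  structure(hauls, n_records = nrow(hauls))
}

#' @rdname read_hauls
#' @export
write_hauls <- function(hauls, path) {
  utils::write.csv(hauls, path, row.names = FALSE)
  invisible(path)
}

# ---- region polygons (GeoJSON) ----------------------------------------------

#' Region polygon
#'
#' A management region: an EEZ, a stock boundary, or an FAO statistical area.
#' Geometry is a list of parts; each part is a list of closed rings (2-column
#' lon/lat matrices), the first ring the outer boundary and the rest holes.
#'
#' @param region_id Identifier string.
#' @param kind One of `"eez"`, `"stock"`, `"fao_area"`.
#' @param geometry List of parts as described, or a single ring matrix.
#' @return An object of class `region_polygon`.
#' @export
region_polygon <- function(region_id, kind = c("eez", "stock", "fao_area"),
                           geometry) {
  kind <- match.arg(kind)
  if (is.matrix(geometry)) geometry <- list(list(geometry))
  if (is.matrix(geometry[[1]])) geometry <- list(geometry)
  geometry <- lapply(geometry, function(part) lapply(part, close_ring))
  for (part in geometry)
    for (ring in part)
      if (nrow(ring) < 4)
        stop_trawlcover("polygon ring needs at least 3 distinct vertices",
                        "geometry_error")
  area <- sum(vapply(geometry, function(part)
    abs(ring_area_planar(part[[1]])) -
      sum(vapply(part[-1], function(h) abs(ring_area_planar(h)), 0)), 0))
  if (area <= 0)
    stop_trawlcover("region polygon has zero area", "geometry_error")
  structure(list(region_id = region_id, kind = kind, geometry = geometry),
            class = "region_polygon")
}

close_ring <- function(ring) {
  ring <- as.matrix(ring)
  if (ncol(ring) != 2)
    stop_trawlcover("ring must be a 2-column lon/lat matrix", "geometry_error")
  if (any(!is.finite(ring)))
    stop_trawlcover("non-finite ring coordinate", "geometry_error")
  if (!isTRUE(all.equal(ring[1, ], ring[nrow(ring), ], tolerance = 0,
                        check.attributes = FALSE)))
    ring <- rbind(ring, ring[1, , drop = FALSE])
  unname(ring)
}

#' @export
print.region_polygon <- function(x, ...) {
  cat(sprintf("region_polygon %s [%s]: %d part(s)\n",
              x$region_id, x$kind, length(x$geometry)))
  invisible(x)
}

#' Read region polygons from GeoJSON
#'
#' Accepts an RFC 7946 FeatureCollection of Polygon / MultiPolygon features
#' with `region_id` and `kind` properties, lon-lat axis order, WGS84.
#'
#' @param path GeoJSON file.
#' @return List of [region_polygon] objects.
#' @export
read_regions <- function(path) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection"))
    stop_trawlcover("expected a GeoJSON FeatureCollection", "schema_error")
  lapply(gj$features, function(f) {
    props <- f$properties
    if (is.null(props$region_id))
      stop_trawlcover("feature missing region_id property", "schema_error")
    geom <- f$geometry
    ring_mat <- function(ring) {
      m <- do.call(rbind, lapply(ring, function(xy)
        c(as.numeric(xy[[1]]), as.numeric(xy[[2]]))))
      if (nrow(m) < 4 ||
          !isTRUE(all.equal(m[1, ], m[nrow(m), ], check.attributes = FALSE)))
        stop_trawlcover("unclosed or degenerate GeoJSON ring",
                        "geometry_error")
      m
    }
    parts <- switch(geom$type,
      Polygon = list(lapply(geom$coordinates, ring_mat)),
      MultiPolygon = lapply(geom$coordinates, function(p)
        lapply(p, ring_mat)),
      stop_trawlcover(sprintf("unsupported geometry type %s", geom$type),
                      "schema_error"))
    region_polygon(props$region_id,
                   kind = if (is.null(props$kind)) "eez" else props$kind,
                   geometry = parts)
  })
}

#' @rdname read_regions
#' @param regions List of [region_polygon] objects.
#' @export
write_regions <- function(regions, path) {
  features <- lapply(regions, function(r) {
    coords <- lapply(r$geometry, function(part)
      lapply(part, function(ring)
        lapply(seq_len(nrow(ring)), function(i) as.list(unname(ring[i, ])))))
    geom <- if (length(coords) == 1L)
      list(type = "Polygon", coordinates = coords[[1]])
    else
      list(type = "MultiPolygon", coordinates = coords)
    list(type = "Feature",
         properties = list(region_id = r$region_id, kind = r$kind),
         geometry = geom)
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- rasters (ESRI ASCII grid) ----------------------------------------------

#' Read or write a georeferenced raster
#'
#' Plain-text ESRI ASCII grid, geographic coordinates only (the `DX`/`DY`
#' header extension carries non-square cells).  The grid transform is
#' reconstructed into a [grid_spec]; `NODATA` cells become `NA`.  Projected
#' rasters are rejected: the pipeline works exclusively in lon/lat WGS84.
#'
#' @param path `.asc` file.
#' @param units Unit string to attach on read (the format has no unit field).
#' @return A [grid_layer].
#' @export
read_grid <- function(path, units = "") {
  lines <- readLines(path, n = 8)
  hdr <- list(); n_hdr <- 0
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 2 && grepl("^[A-Za-z]", tok[1])) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
      n_hdr <- n_hdr + 1
    } else break
  }
  need <- c("ncols", "nrows")
  if (!all(need %in% names(hdr)))
    stop_trawlcover("not an ASCII grid: missing ncols/nrows header",
                    "schema_error")
  if (!is.null(hdr$crs) || !is.null(hdr$projection))
    stop_trawlcover("projected rasters are not supported", "crs_error")
  dx <- hdr$dx %||% hdr$cellsize
  dy <- hdr$dy %||% hdr$cellsize
  if (is.null(dx) || is.null(dy))
    stop_trawlcover("missing cellsize/dx/dy header", "schema_error")
  xll <- hdr$xllcorner %||% (hdr$xllcenter - dx / 2)
  yll <- hdr$yllcorner %||% (hdr$yllcenter - dy / 2)
  if (abs(xll) > 360 || abs(yll) > 90)
    stop_trawlcover("raster origin outside geographic bounds; projected CRS?",
                    "crs_error")
  vals <- scan(path, skip = n_hdr, quiet = TRUE)
  nodata <- hdr$nodata_value
  if (!is.null(nodata)) vals[vals == nodata] <- NA
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  # ASC rows run north to south; internal layout is south-up
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  grid_layer(grid_spec(xll, yll, dx, dy, hdr$ncols, hdr$nrows), m, units)
}

#' @rdname read_grid
#' @param layer A [grid_layer].
#' @export
write_grid <- function(layer, path) {
  stopifnot(inherits(layer, "grid_layer"))
  s <- layer$spec
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", s$ncols),
    sprintf("nrows %d", s$nrows),
    sprintf("xllcorner %.12g", s$lon_origin),
    sprintf("yllcorner %.12g", s$lat_origin),
    if (isTRUE(all.equal(s$dlon, s$dlat)))
      sprintf("cellsize %.12g", s$dlon)
    else c(sprintf("dx %.12g", s$dlon), sprintf("dy %.12g", s$dlat)),
    "NODATA_value -9999"), con)
  m <- layer$values * 1  # logical -> numeric
  m[is.na(m)] <- -9999
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  writeLines(apply(m, 1, function(r) paste(sprintf("%.10g", r),
                                           collapse = " ")), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
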