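# Planar geometry kernel in degree space.  Polygons are closed 2-column
# matrices (rings); a "part" is list(outer_ring, hole_ring, ...); coverage
# within a part is even-odd, so holes need no orientation convention.

ring_area_planar <- function(ring) {
  n <- nrow(ring)
  x <- ring[, 1]; y <- ring[, 2]
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

#' Point-in-polygon test
#'
#' Even-odd (crossing-number) membership against a ring or a part with holes.
#' Points exactly on a boundary edge count as inside, matching the cell-center
#' rasterization convention.
#'
#' @param lon,lat Point coordinates.
#' @param ring Closed 2-column ring matrix.
#' @return Logical vector.
#' @export
point_in_ring <- function(lon, lat, ring) {
  n <- nrow(ring) - 1L
  x1 <- ring[1:n, 1]; y1 <- ring[1:n, 2]
  x2 <- ring[2:(n + 1), 1]; y2 <- ring[2:(n + 1), 2]
  vapply(seq_along(lon), function(i) {
    px <- lon[i]; py <- lat[i]
    # boundary: point on any segment
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    on <- abs(cross) < 1e-12 &
      px >= pmin(x1, x2) - 1e-12 & px <= pmax(x1, x2) + 1e-12 &
      py >= pmin(y1, y2) - 1e-12 & py <= pmax(y1, y2) + 1e-12
    if (any(on)) return(TRUE)
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < x1 + (py - y1) * (x2 - x1) / (y2 - y1))
    sum(crosses) %% 2L == 1L
  }, logical(1))
}

point_in_part <- function(lon, lat, part) {
  inside <- point_in_ring(lon, lat, part[[1]])
  for (hole in part[-1]) {
    # on-hole-boundary still counts as inside the part
    on_h <- point_on_ring(lon, lat, hole)
    in_h <- point_in_ring(lon, lat, hole)
    inside <- inside & (!in_h | on_h)
  }
  inside
}

point_on_ring <- function(lon, lat, ring) {
  n <- nrow(ring) - 1L
  x1 <- ring[1:n, 1]; y1 <- ring[1:n, 2]
  x2 <- ring[2:(n + 1), 1]; y2 <- ring[2:(n + 1), 2]
  vapply(seq_along(lon), function(i) {
    px <- lon[i]; py <- lat[i]
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    any(abs(cross) < 1e-12 &
          px >= pmin(x1, x2) - 1e-12 & px <= pmax(x1, x2) + 1e-12 &
          py >= pmin(y1, y2) - 1e-12 & py <= pmax(y1, y2) + 1e-12)
  }, logical(1))
}

ring_self_intersects <- function(ring) {
  n <- nrow(ring) - 1L
  if (n < 4) return(FALSE)
  segs <- cbind(ring[1:n, , drop = FALSE], ring[2:(n + 1), , drop = FALSE])
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]  # closing edge shares vertex 1
    for (j in js)
      if (segments_cross(segs[i, ], segs[j, ])) return(TRUE)
  }
  FALSE
}

segments_cross <- function(a, b) {
  d1 <- orient2d(b[1:2], b[3:4], a[1:2])
  d2 <- orient2d(b[1:2], b[3:4], a[3:4])
  d3 <- orient2d(a[1:2], a[3:4], b[1:2])
  d4 <- orient2d(a[1:2], a[3:4], b[3:4])
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

orient2d <- function(a, b, c) {
  (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
}

# ---- exact slab-sweep areas --------------------------------------------------
# Area of {covered by >= min_cover of the groups}: event x-coordinates at every
# vertex and every pairwise edge intersection, so within a slab the merged
# coverage length is constant in shape and the midline evaluation is exact.

all_segments <- function(parts) {
  do.call(rbind, lapply(parts, function(part)
    do.call(rbind, lapply(part, function(ring) {
      n <- nrow(ring) - 1L
      cbind(ring[1:n, 1], ring[1:n, 2], ring[2:(n + 1), 1], ring[2:(n + 1), 2])
    }))))
}

segment_intersection_xs <- function(segs) {
  n <- nrow(segs)
  if (n < 2) return(numeric(0))
  out <- numeric(0)
  for (i in seq_len(n - 1)) {
    a <- segs[i, ]
    j <- (i + 1):n
    b <- segs[j, , drop = FALSE]
    d1 <- (b[, 3] - b[, 1]) * (a[2] - b[, 2]) -
          (b[, 4] - b[, 2]) * (a[1] - b[, 1])
    d2 <- (b[, 3] - b[, 1]) * (a[4] - b[, 2]) -
          (b[, 4] - b[, 2]) * (a[3] - b[, 1])
    d3 <- (a[3] - a[1]) * (b[, 2] - a[2]) - (a[4] - a[2]) * (b[, 1] - a[1])
    d4 <- (a[3] - a[1]) * (b[, 4] - a[2]) - (a[4] - a[2]) * (b[, 3] - a[1])
    hit <- (sign(d1) * sign(d2) < 0) & (sign(d3) * sign(d4) < 0)
    if (any(hit)) {
      bb <- b[hit, , drop = FALSE]
      denom <- (a[1] - a[3]) * (bb[, 2] - bb[, 4]) -
               (a[2] - a[4]) * (bb[, 1] - bb[, 3])
      t <- ((a[1] - bb[, 1]) * (bb[, 2] - bb[, 4]) -
            (a[2] - bb[, 2]) * (bb[, 1] - bb[, 3])) / denom
      out <- c(out, a[1] + t * (a[3] - a[1]))
    }
  }
  out
}

# crossing ys of a vertical line x = xm with the rings of one group (even-odd)
covered_intervals_at <- function(xm, segs) {
  x1 <- segs[, 1]; y1 <- segs[, 2]; x2 <- segs[, 3]; y2 <- segs[, 4]
  sel <- (pmin(x1, x2) < xm) & (pmax(x1, x2) > xm)
  if (!any(sel)) return(NULL)
  t <- (xm - x1[sel]) / (x2[sel] - x1[sel])
  ys <- sort(y1[sel] + t * (y2[sel] - y1[sel]))
  if (length(ys) %% 2L != 0L) return(NULL)  # numerically grazing; skip
  matrix(ys, ncol = 2, byrow = TRUE)
}

#' Area of a polygon overlay
#'
#' Area of the region covered by at least `min_cover` of the supplied polygon
#' groups, by a slab-decomposition sweep with event abscissae at every vertex
#' and pairwise edge intersection.  With `min_cover = 1` this is the union
#' area; with `min_cover = length(groups)` the intersection area.  The
#' `"deg2"` measure (square degrees in the lon/lat plane) is exact; `"km2"`
#' integrates the covered intervals over authalic-sphere latitude bands,
#' exact in longitude and first-order in latitude within each slab.
#'
#' @param groups List of polygon groups; each group is a list of parts (each
#'   part a list of rings, outer first), a single part, a bare ring matrix,
#'   a [footprint] or a [region_polygon].
#' @param min_cover Minimum number of groups that must cover a point.
#' @param measure `"deg2"` (planar) or `"km2"` (authalic sphere).
#' @return Area in the requested measure.
#' @export
overlay_area <- function(groups, min_cover = 1, measure = c("deg2", "km2")) {
  measure <- match.arg(measure)
  groups <- lapply(groups, as_parts)
  groups <- groups[lengths(groups) > 0]
  if (!length(groups)) return(0)
  seg_groups <- lapply(groups, all_segments)
  segs_all <- do.call(rbind, seg_groups)
  xs <- sort(unique(c(segs_all[, 1], segs_all[, 3],
                      segment_intersection_xs(segs_all))))
  if (length(xs) < 2) return(0)
  band <- if (measure == "deg2") {
    function(w, y1, y2) w * (y2 - y1)
  } else {
    function(w, y1, y2)
      .authalic_radius_km^2 * (w * pi / 180) *
        (sin(y2 * pi / 180) - sin(y1 * pi / 180))
  }
  area <- 0
  for (k in seq_len(length(xs) - 1)) {
    x1 <- xs[k]; x2 <- xs[k + 1]
    if (x2 - x1 <= 0) next
    xm <- (x1 + x2) / 2
    ivs <- lapply(seg_groups, covered_intervals_at, xm = xm)
    ivs <- ivs[!vapply(ivs, is.null, logical(1))]
    if (length(ivs) < min_cover) next
    # sweep y events with coverage counts
    ys <- do.call(rbind, lapply(seq_along(ivs), function(g)
      cbind(c(ivs[[g]][, 1], ivs[[g]][, 2]),
            rep(c(1, -1), each = nrow(ivs[[g]])))))
    o <- order(ys[, 1])
    ys <- ys[o, , drop = FALSE]
    depth <- cumsum(ys[, 2])
    keep <- depth[-length(depth)] >= min_cover
    if (any(keep))
      area <- area + sum(band(x2 - x1, ys[-nrow(ys), 1][keep],
                              ys[-1, 1][keep]))
  }
  area
}

# normalize polygon-ish input to a list of parts
as_parts <- function(x) {
  if (inherits(x, "footprint")) return(x$parts)
  if (inherits(x, "footprint_union"))
    return(do.call(c, lapply(x$footprints, as_parts)))
  if (inherits(x, "region_polygon")) return(x$geometry)
  if (is.matrix(x)) return(list(list(close_ring(x))))
  if (is.list(x) && length(x) && is.matrix(x[[1]]))
    return(list(lapply(x, close_ring)))
  if (is.list(x)) return(lapply(x, function(p) lapply(p, close_ring)))
  stop_trawlcover("cannot interpret polygon input", "geometry_error")
}

#' Spherical polygon area
#'
#' Area of a simple lon/lat polygon (optionally with holes) by spherical
#' excess on the authalic sphere; orientation-independent, holes subtracted.
#'
#' @param polygon A closed ring matrix, a part (list of rings, outer first),
#'   or a [footprint]; multi-part inputs are summed.
#' @return Area in km².
#' @export
spherical_area_km2 <- function(polygon) {
  parts <- as_parts(polygon)
  r_m <- .authalic_radius_km * 1000
  part_area <- function(part) {
    for (ring in part)
      if (ring_self_intersects(ring))
        stop_trawlcover("self-intersecting ring", "geometry_error")
    outer <- abs(geosphere::areaPolygon(part[[1]], a = r_m, f = 0))
    holes <- sum(vapply(part[-1], function(h)
      abs(geosphere::areaPolygon(h, a = r_m, f = 0)), 0))
    (outer - holes) / 1e6
  }
  sum(vapply(parts, part_area, 0))
}
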