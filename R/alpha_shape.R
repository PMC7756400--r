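#' Alpha-shape footprint of a survey's hauls
#'
#' Builds the alpha-complex of the haul locations — the union of Delaunay
#' triangles whose circumradius is at most `alpha_deg` (radius convention, in
#' degrees, matching the alpha-convex-hull tradition with its default volume
#' shape of 1) — and polygonizes its boundary.  Geometry runs in degree space;
#' areas are evaluated on the authalic sphere.  Interior holes of the complex
#' are dissolved by default, treating the footprint as an effective sampling
#' domain; antimeridian-straddling point sets are recentered to \[0, 360)
#' before hulling and split back at ±180 on output.
#'
#' @param points 2-column matrix (or data.frame with `lon`, `lat`) of haul
#'   positions; duplicated positions are removed before triangulation.
#' @param alpha_deg Disc radius in degrees; triangles with larger circumradius
#'   are discarded.  Default 1.
#' @param survey_id Identifier attached to the footprint.
#' @param keep_holes Keep interior holes instead of dissolving them.
#' @param fallback_buffer_deg If the input is degenerate (fewer than 3
#'   distinct points, or all collinear), buffer each point by this radius
#'   (degrees, square buffer) instead of failing.  `NA` (default) raises a
#'   degenerate-input error.
#' @return An object of class `footprint`: `survey_id`, `parts` (list of
#'   parts, each a list of closed rings with the outer ring first), `alpha_deg`,
#'   `area_km2`, plus the kept `triangles` and deduplicated `points`.
#' @export
alpha_shape <- function(points, alpha_deg = 1, survey_id = "",
                        keep_holes = FALSE, fallback_buffer_deg = NA) {
  if (is.data.frame(points)) points <- cbind(points$lon, points$lat)
  if (!(is.numeric(alpha_deg) && alpha_deg > 0))
    stop_trawlcover("alpha_deg must be positive", "parameter_error")
  pts <- dedup_points(points)
  wrapped <- FALSE
  if (nrow(pts) >= 2 && diff(range(pts[, 1])) > 180) {
    pts[, 1] <- normalize_lon(pts[, 1], "360")  # antimeridian recentering
    pts <- dedup_points(pts)
    wrapped <- TRUE
  }
  degenerate <- nrow(pts) < 3 ||
    abs(max_collinearity(pts)) <
      1e-12 * max(diff(range(pts[, 1])), diff(range(pts[, 2])), 1e-9)^2
  if (degenerate) {
    if (is.na(fallback_buffer_deg))
      stop_trawlcover(
        "fewer than 3 distinct non-collinear points; no alpha shape",
        "degenerate_input")
    b <- fallback_buffer_deg
    parts <- lapply(seq_len(nrow(pts)), function(i)
      list(close_ring(rbind(pts[i, ] + c(-b, -b), pts[i, ] + c(b, -b),
                            pts[i, ] + c(b, b), pts[i, ] + c(-b, b)))))
    parts <- unwrap_parts(parts, wrapped)
    return(structure(list(survey_id = survey_id, parts = parts,
                          alpha_deg = alpha_deg,
                          area_km2 = sum(vapply(parts, spherical_area_km2, 0)),
                          triangles = matrix(integer(0), 0, 3), points = pts),
                     class = "footprint"))
  }
  dt <- delaunay(pts)
  keep <- dt$circumradius <= alpha_deg
  tri <- dt$triangles[keep, , drop = FALSE]
  if (nrow(tri) == 0)
    stop_trawlcover(
      "alpha_deg smaller than every Delaunay circumradius: empty complex",
      "degenerate_input")
  parts <- polygonize_complex(dt$points, tri, keep_holes = keep_holes)
  parts <- unwrap_parts(parts, wrapped)
  structure(list(survey_id = survey_id, parts = parts, alpha_deg = alpha_deg,
                 area_km2 = sum(vapply(parts, spherical_area_km2, 0)),
                 triangles = tri, points = dt$points),
            class = "footprint")
}

# boundary edges (used by exactly one kept triangle) -> closed rings ->
# outer/hole classification by which side of each ring its triangle lies on
polygonize_complex <- function(pts, tri, keep_holes = FALSE) {
  edges <- rbind(tri[, c(1, 2), drop = FALSE], tri[, c(2, 3), drop = FALSE],
                 tri[, c(1, 3), drop = FALSE])
  tri_of <- rep(seq_len(nrow(tri)), 3)
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  once <- !(key %in% key[duplicated(key)])
  bedges <- edges[once, , drop = FALSE]
  btri <- tri_of[once]
  # walk boundary edges into closed rings
  adj <- split(rep(seq_len(nrow(bedges)), 2),
               factor(c(bedges[, 1], bedges[, 2])))
  used <- logical(nrow(bedges))
  ring_ids <- list(); ring_edge1 <- integer(0)
  for (e0 in seq_len(nrow(bedges))) {
    if (used[e0]) next
    start <- bedges[e0, 1]; cur <- bedges[e0, 2]
    used[e0] <- TRUE
    ids <- c(start, cur)
    while (cur != start) {
      cand <- adj[[as.character(cur)]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break  # open chain; numerically impossible, bail
      e <- cand[1]
      used[e] <- TRUE
      nxt <- if (bedges[e, 1] == cur) bedges[e, 2] else bedges[e, 1]
      ids <- c(ids, nxt)
      cur <- nxt
    }
    ring_ids[[length(ring_ids) + 1]] <- ids
    ring_edge1 <- c(ring_edge1, e0)
  }
  rings <- lapply(ring_ids, function(ids) close_ring(pts[ids, , drop = FALSE]))
  # a ring is an outer boundary iff the kept triangle adjacent to its first
  # edge (which lies in the covered region) is inside the ring
  is_outer <- vapply(seq_along(rings), function(k) {
    t <- tri[btri[ring_edge1[k]], ]
    ctr <- colMeans(pts[t, , drop = FALSE])
    point_in_ring(ctr[1], ctr[2], rings[[k]]) &&
      !point_on_ring(ctr[1], ctr[2], rings[[k]])
  }, logical(1))
  outers <- rings[is_outer]
  holes <- rings[!is_outer]
  parts <- lapply(outers, function(o) list(o))
  if (keep_holes && length(holes)) {
    for (h in holes) {
      owner <- which(vapply(parts, function(p)
        all(point_in_ring(h[-1, 1], h[-1, 2], p[[1]])), logical(1)))
      if (length(owner)) {
        # smallest containing outer ring
        ar <- vapply(owner, function(i) abs(ring_area_planar(parts[[i]][[1]])),
                     0)
        i <- owner[which.min(ar)]
        parts[[i]] <- c(parts[[i]], list(h))
      }
    }
  }
  parts
}

unwrap_parts <- function(parts, wrapped) {
  if (!wrapped) return(parts)
  out <- list()
  for (part in parts) {
    # split rings crossing lon = 180 back into +/-180 pieces
    xr <- range(part[[1]][, 1])
    if (xr[2] <= 180) {
      out <- c(out, list(part))
    } else if (xr[1] >= 180) {
      out <- c(out, list(lapply(part, function(r) {
        r[, 1] <- r[, 1] - 360; r
      })))
    } else {
      for (side in c("w", "e")) {
        clipped <- lapply(part, clip_ring_lon, side = side)
        clipped <- clipped[!vapply(clipped, is.null, logical(1))]
        if (length(clipped) && !is.null(clipped[[1]]))
          out <- c(out, list(clipped))
      }
    }
  }
  out
}

# Sutherland-Hodgman clip of one ring against lon = 180 (west keeps < 180,
# east keeps > 180 then shifts by -360)
clip_ring_lon <- function(ring, side) {
  keep <- if (side == "w") function(x) x <= 180 else function(x) x >= 180
  v <- ring[-nrow(ring), , drop = FALSE]
  out <- NULL
  n <- nrow(v)
  for (i in seq_len(n)) {
    a <- v[i, ]; b <- v[if (i == n) 1 else i + 1, ]
    ain <- keep(a[1]); bin <- keep(b[1])
    if (ain) out <- rbind(out, a)
    if (xor(ain, bin)) {
      t <- (180 - a[1]) / (b[1] - a[1])
      out <- rbind(out, c(180, a[2] + t * (b[2] - a[2])))
    }
  }
  if (is.null(out) || nrow(out) < 3) return(NULL)
  if (side == "e") out[, 1] <- out[, 1] - 360
  close_ring(out)
}

#' @export
print.footprint <- function(x, ...) {
  cat(sprintf(
    "footprint %s: %d part(s), alpha = %g deg, area = %.1f km2\n",
    x$survey_id, length(x$parts), x$alpha_deg, x$area_km2))
  invisible(x)
}

#' @export
plot.footprint <- function(x, add = FALSE, col = NA, border = 1, ...) {
  xy <- do.call(rbind, lapply(x$parts, function(p) p[[1]]))
  if (!add)
    plot(xy, type = "n", xlab = "lon", ylab = "lat", ...)
  for (p in x$parts)
    for (r in p)
      graphics::polygon(r[, 1], r[, 2], col = col, border = border)
  invisible(x)
}

#' Union of survey footprints
#'
#' The comparison domain for coverage statistics.  The union is kept as a
#' collection of parts with point-membership semantics (a point is covered if
#' it is inside any part); its area is evaluated by the exact slab sweep of
#' [overlay_area].
#'
#' @param footprints List of [footprint] objects (or polygon-like inputs
#'   accepted by [overlay_area]).  An empty list yields an empty union.
#' @return An object of class `footprint_union`.
#' @export
union_footprints <- function(footprints) {
  if (inherits(footprints, "footprint")) footprints <- list(footprints)
  structure(list(footprints = footprints), class = "footprint_union")
}

#' @rdname union_footprints
#' @param x A `footprint_union`.
#' @param measure `"deg2"` or `"km2"`, see [overlay_area].
#' @export
union_area <- function(x, measure = c("km2", "deg2")) {
  measure <- match.arg(measure)
  if (!length(x$footprints)) return(0)
  overlay_area(x$footprints, min_cover = 1, measure = measure)
}

#' @export
print.footprint_union <- function(x, ...) {
  cat(sprintf("footprint_union of %d footprint(s)\n", length(x$footprints)))
  invisible(x)
}

point_in_geom <- function(lon, lat, geom) {
  parts <- as_parts(geom)
  inside <- rep(FALSE, length(lon))
  for (part in parts) {
    todo <- !inside
    if (!any(todo)) break
    inside[todo] <- point_in_part(lon[todo], lat[todo], part)
  }
  inside
}

#' Convex hull footprint (alpha to infinity limit)
#'
#' @param points 2-column matrix of positions.
#' @return Closed ring matrix of the convex hull.
#' @export
convex_hull_ring <- function(points) {
  if (is.data.frame(points)) points <- cbind(points$lon, points$lat)
  pts <- dedup_points(points)
  close_ring(pts[rev(grDevices::chull(pts)), , drop = FALSE])
}
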