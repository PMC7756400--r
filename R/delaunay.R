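# Bowyer-Watson Delaunay triangulation in the lon/lat plane.  Points are
# deduplicated and lexicographically ordered before insertion so the
# triangulation (and every structure derived from it) is deterministic.
#
# A finite super-triangle can clip near-degenerate hull triangles whose
# circumcircles reach past it, so the construction verifies itself: the
# triangle areas must tile the convex hull exactly, and the super-triangle
# scale escalates (on recentered coordinates, to keep the arithmetic well
# conditioned) until they do.

circumcircle <- function(ax, ay, bx, by, cx, cy) {
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-14 * max(abs(c(ax, ay, bx, by, cx, cy, 1))))
    return(NULL)  # collinear
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  c(ux, uy, (ux - ax)^2 + (uy - ay)^2)  # center x, y, radius^2
}

bw_triangulate <- function(pts, scale_mult) {
  n <- nrow(pts)
  span <- max(diff(range(pts[, 1])), diff(range(pts[, 2])), 1e-9)
  m <- scale_mult * span
  sp <- rbind(c(-2 * m, -m), c(2 * m, -m), c(0, 2 * m))
  P <- rbind(pts, sp)
  s1 <- n + 1L; s2 <- n + 2L; s3 <- n + 3L
  tri <- matrix(c(s1, s2, s3), nrow = 1)
  cc <- circumcircle(P[s1, 1], P[s1, 2], P[s2, 1], P[s2, 2],
                     P[s3, 1], P[s3, 2])
  circ <- matrix(cc, nrow = 1)
  eps <- 1e-12 * span^2
  for (i in seq_len(n)) {
    px <- P[i, 1]; py <- P[i, 2]
    bad <- (px - circ[, 1])^2 + (py - circ[, 2])^2 < circ[, 3] + eps
    bad_tri <- tri[bad, , drop = FALSE]
    # boundary of the cavity: edges used by exactly one bad triangle
    edges <- rbind(bad_tri[, c(1, 2), drop = FALSE],
                   bad_tri[, c(2, 3), drop = FALSE],
                   bad_tri[, c(3, 1), drop = FALSE])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    keep_e <- !(key %in% key[duplicated(key)])
    edges <- edges[keep_e, , drop = FALSE]
    tri <- tri[!bad, , drop = FALSE]
    circ <- circ[!bad, , drop = FALSE]
    if (nrow(edges)) {
      new_tri <- cbind(edges, i)
      new_cc <- t(apply(new_tri, 1, function(tr) {
        cc <- circumcircle(P[tr[1], 1], P[tr[1], 2], P[tr[2], 1], P[tr[2], 2],
                           P[tr[3], 1], P[tr[3], 2])
        if (is.null(cc)) c(NA, NA, Inf) else cc
      }))
      tri <- rbind(tri, new_tri)
      circ <- rbind(circ, new_cc)
    }
  }
  keep <- tri[, 1] <= n & tri[, 2] <= n & tri[, 3] <= n
  tri <- tri[keep, , drop = FALSE]
  if (!nrow(tri)) return(NULL)
  tri <- t(apply(tri, 1, sort))  # canonical vertex order within each triangle
  o <- order(tri[, 1] * (n + 1)^2 + tri[, 2] * (n + 1) + tri[, 3])
  unname(tri[o, , drop = FALSE])
}

tri_areas <- function(pts, tri) {
  ax <- pts[tri[, 1], 1]; ay <- pts[tri[, 1], 2]
  bx <- pts[tri[, 2], 1]; by <- pts[tri[, 2], 2]
  cx <- pts[tri[, 3], 1]; cy <- pts[tri[, 3], 2]
  abs((bx - ax) * (cy - ay) - (by - ay) * (cx - ax)) / 2
}

#' Delaunay triangulation of planar points
#'
#' @param points 2-column matrix of point coordinates (lon, lat degrees).
#' @return List with `points` (deduplicated, lexicographically sorted),
#'   `triangles` (integer matrix, one row of indices into `points` per
#'   triangle, vertex indices sorted within each row) and `circumradius`
#'   (vector, same order as triangles).
#' @export
delaunay <- function(points) {
  pts <- dedup_points(points)
  n <- nrow(pts)
  if (n < 3)
    stop_trawlcover("need at least 3 distinct points", "degenerate_input")
  span <- max(diff(range(pts[, 1])), diff(range(pts[, 2])), 1e-9)
  if (abs(max_collinearity(pts)) < 1e-12 * span^2)
    stop_trawlcover("all points are collinear", "degenerate_input")
  # recenter for conditioning; circumcircles are translation-equivariant
  ctr <- c(mean(range(pts[, 1])), mean(range(pts[, 2])))
  q <- cbind(pts[, 1] - ctr[1], pts[, 2] - ctr[2])
  hull <- grDevices::chull(q)
  hull_area <- abs(ring_area_planar(close_ring(q[hull, , drop = FALSE])))
  tri <- NULL
  for (mult in c(25, 1e3, 1e5, 1e7)) {
    cand <- bw_triangulate(q, mult)
    if (is.null(cand)) next
    tri <- cand
    if (abs(sum(tri_areas(q, tri)) - hull_area) <=
        1e-11 * max(hull_area, 1e-12)) break
  }
  if (is.null(tri))
    stop_trawlcover("triangulation failed", "degenerate_input")
  radii <- apply(tri, 1, function(tr) {
    cc <- circumcircle(q[tr[1], 1], q[tr[1], 2], q[tr[2], 1], q[tr[2], 2],
                       q[tr[3], 1], q[tr[3], 2])
    if (is.null(cc)) Inf else sqrt(cc[3])
  })
  list(points = pts, triangles = tri, circumradius = unname(radii))
}

dedup_points <- function(points) {
  pts <- unname(as.matrix(points))
  stopifnot(ncol(pts) == 2)
  pts <- pts[!duplicated(pts), , drop = FALSE]
  pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
}

max_collinearity <- function(pts) {
  # max |cross product| of any point against the diameter endpoints
  i <- which.min(pts[, 1] + 1e-9 * pts[, 2])
  j <- which.max(pts[, 1] + 1e-9 * pts[, 2])
  if (i == j) j <- which.max(pts[, 2])
  a <- pts[i, ]; b <- pts[j, ]
  max(abs((b[1] - a[1]) * (pts[, 2] - a[2]) -
          (b[2] - a[2]) * (pts[, 1] - a[1])))
}
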