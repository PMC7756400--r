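# Independent brute-force oracles used across the suite.  These deliberately
# avoid the package's own algorithms: the Delaunay oracle enumerates all point
# triples, point-in-polygon uses the winding number, and coverage statistics
# are recomputed by explicit cell loops.

# all triples whose circumcircle contains no other point (relative
# tolerance); vectorized over the full triple enumeration
brute_delaunay <- function(pts) {
  n <- nrow(pts)
  idx <- combn(n, 3)
  ax <- pts[idx[1, ], 1]; ay <- pts[idx[1, ], 2]
  bx <- pts[idx[2, ], 1]; by <- pts[idx[2, ], 2]
  cx <- pts[idx[3, ], 1]; cy <- pts[idx[3, ], 2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ok <- abs(d) > 1e-13
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  r2 <- (ux - ax)^2 + (uy - ay)^2
  # distance^2 of every point to every circumcenter (n x triples)
  d2 <- outer(pts[, 1], ux, `-`)^2 + outer(pts[, 2], uy, `-`)^2
  d2[rbind(cbind(idx[1, ], seq_along(ux)), cbind(idx[2, ], seq_along(ux)),
           cbind(idx[3, ], seq_along(ux)))] <- Inf
  empty <- colSums(d2 < rep(r2 * (1 - 1e-9), each = n)) == 0
  keep <- ok & empty
  cbind(t(idx[, keep, drop = FALSE]), sqrt(r2[keep]))
}

# alpha-complex triangle set by the brute-force construction
brute_alpha_triangles <- function(pts, alpha) {
  bd <- brute_delaunay(pts)
  bd[bd[, 4] <= alpha, 1:3, drop = FALSE]
}

tri_key <- function(tri) paste(tri[, 1], tri[, 2], tri[, 3])

tri_area_sum <- function(pts, tri) {
  if (!nrow(tri)) return(0)
  sum(apply(tri, 1, function(tr)
    abs(trawlcover:::ring_area_planar(
      trawlcover:::close_ring(pts[tr, , drop = FALSE])))))
}

# winding-number point-in-polygon (boundary treated as inside)
winding_inside <- function(px, py, ring) {
  n <- nrow(ring) - 1L
  vapply(seq_along(px), function(q) {
    x <- px[q]; y <- py[q]
    wn <- 0
    for (i in seq_len(n)) {
      x1 <- ring[i, 1]; y1 <- ring[i, 2]
      x2 <- ring[i + 1, 1]; y2 <- ring[i + 1, 2]
      cr <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
      if (abs(cr) < 1e-12 &&
          x >= min(x1, x2) - 1e-12 && x <= max(x1, x2) + 1e-12 &&
          y >= min(y1, y2) - 1e-12 && y <= max(y1, y2) + 1e-12)
        return(TRUE)
      if (y1 <= y) {
        if (y2 > y && cr > 0) wn <- wn + 1
      } else {
        if (y2 <= y && cr < 0) wn <- wn - 1
      }
    }
    wn != 0
  }, logical(1))
}

# random simple (star-shaped) polygon inside a bounding box
random_star_polygon <- function(bbox, n_vert = 8) {
  cx <- runif(1, bbox[1] + 0.3 * (bbox[2] - bbox[1]),
              bbox[2] - 0.3 * (bbox[2] - bbox[1]))
  cy <- runif(1, bbox[3] + 0.3 * (bbox[4] - bbox[3]),
              bbox[4] - 0.3 * (bbox[4] - bbox[3]))
  ang <- sort(runif(n_vert, 0, 2 * pi))
  rad <- runif(n_vert, 0.1, 0.45) *
    min(bbox[2] - bbox[1], bbox[4] - bbox[3])
  ring <- cbind(cx + rad * cos(ang), cy + rad * sin(ang))
  rbind(ring, ring[1, , drop = FALSE])
}

random_box <- function(bbox) {
  x <- sort(runif(2, bbox[1], bbox[2]))
  y <- sort(runif(2, bbox[3], bbox[4]))
  rbind(c(x[1], y[1]), c(x[2], y[1]), c(x[2], y[2]), c(x[1], y[2]),
        c(x[1], y[1]))
}

# exhaustive cell-loop coverage oracle
oracle_coverage <- function(mask, footprint_masks, meta) {
  elig_cells <- which(!is.na(mask$values) & mask$values)
  sids <- names(footprint_masks)
  covered <- 0; by_survey <- setNames(integer(length(sids)), sids)
  by_avail <- setNames(integer(length(trawlcover::availability_classes)),
                       trawlcover::availability_classes)
  for (cell in elig_cells) {
    in_s <- vapply(footprint_masks, function(fm)
      isTRUE(fm$values[cell]), logical(1))
    by_survey[in_s] <- by_survey[in_s] + 1L
    if (any(in_s)) {
      covered <- covered + 1
      ranks <- trawlcover::availability_rank(
        meta$availability[match(sids[in_s], meta$survey_id)])
      best <- trawlcover::availability_classes[min(ranks)]
      by_avail[best] <- by_avail[best] + 1L
    }
  }
  list(covered = covered, eligible = length(elig_cells),
       fraction = covered / length(elig_cells),
       by_survey = by_survey, by_availability = by_avail)
}

# small default world used by several suites
tiny_world <- function(seed = 42, ncols = 30, nrows = 24, d = 0.25) {
  gen_world(grid_spec(0, 50, d, d, ncols, nrows), seed = seed)
}

# haul-free survey metadata helper
meta_of <- function(ids, avail) {
  survey_meta(ids, avail, years_sampled = rep(list(2001:2019), length(ids)))
}
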