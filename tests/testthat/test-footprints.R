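test_that("survey inclusion filter applies the three criteria", {
  meta <- survey_meta(
    c("A", "B", "C"),
    rep("publicly_available", 3),
    list(c(2012, 2014, 2016, 2018), c(2016, 2017, 2018),
         c(2002, 2004, 2006, 2008)))
  hauls <- data.frame(survey_id = c("A", "B", "C"),
                      lon = 1:3, lat = c(50, 51, 52), year = 2016)
  part <- filter_surveys(meta, hauls)
  expect_equal(part$included, "A")
  expect_equal(part$excluded$reason[part$excluded$survey_id == "B"],
               "min_years")
  expect_equal(part$excluded$reason[part$excluded$survey_id == "C"],
               "recent_year")

  # near-shore exclusion via median distance to coast
  meta2 <- survey_meta("D", "publicly_available", list(c(2012, 2014, 2016,
                                                         2018)))
  hauls2 <- data.frame(survey_id = "D", lon = 1, lat = 50, year = 2016,
                       distance_to_coast_nm = c(1, 2, 2.5))
  expect_equal(filter_surveys(meta2, hauls2)$excluded$reason, "near_shore")
  expect_error(filter_surveys(meta, transform(hauls, survey_id = "Z")),
               class = "linkage_error")
})

test_that("filter partition equals brute-force predicate re-application", {
  set.seed(21)
  n <- 50
  ids <- sprintf("S%02d", 1:n)
  years <- lapply(1:n, function(i) sort(sample(1998:2021, sample(2:12, 1))))
  meta <- survey_meta(ids, sample(availability_classes, n, TRUE), years)
  hauls <- data.frame(survey_id = rep(ids, each = 3),
                      lon = runif(3 * n, 0, 5), lat = runif(3 * n, 50, 55),
                      year = 2016,
                      distance_to_coast_nm = runif(3 * n, 0, 20))
  part <- filter_surveys(meta, hauls)
  for (i in 1:n) {
    yrs <- years[[i]][years[[i]] >= 2001 & years[[i]] <= 2019]
    d <- hauls$distance_to_coast_nm[hauls$survey_id == ids[i]]
    ok <- length(yrs) >= 4 && any(yrs >= 2015) && median(d) >= 3
    expect_equal(ids[i] %in% part$included, ok, label = ids[i])
  }
})

test_that("alpha shape equals the convex hull in the large-alpha limit", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  fp <- alpha_shape(sq, alpha_deg = 10)
  expect_length(fp$parts, 1)
  expect_equal(sort(unique(as.vector(fp$parts[[1]][[1]][, 1]))), c(0, 1))
  expect_equal(abs(trawlcover:::ring_area_planar(fp$parts[[1]][[1]])), 1,
               tolerance = 1e-12)
  expect_equal(formals(alpha_shape)$alpha_deg, 1)  # the documented default

  for (seed in 1:10) {
    set.seed(seed)
    pts <- cbind(runif(30, 0, 2), runif(30, 50, 52))
    fp_inf <- alpha_shape(pts, alpha_deg = 1e6)
    hull <- convex_hull_ring(pts)
    expect_equal(fp_inf$area_km2, spherical_area_km2(hull),
                 tolerance = 1e-9)
  }
})

test_that("alpha complex matches the triangle-by-triangle oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    pts <- cbind(runif(20, 0, 2), runif(20, 50, 52))
    fp <- alpha_shape(pts, alpha_deg = 0.5)
    oracle <- brute_alpha_triangles(fp$points, 0.5)
    expect_setequal(tri_key(fp$triangles), tri_key(oracle))
    # every boundary vertex is an input point
    verts <- unique(do.call(rbind, lapply(fp$parts, function(p)
      do.call(rbind, p))))
    expect_true(all(apply(verts, 1, function(v)
      any(abs(pts[, 1] - v[1]) < 1e-12 & abs(pts[, 2] - v[2]) < 1e-12))))
  }
})

test_that("alpha shape area is monotone in alpha and covers all points", {
  set.seed(33)
  pts <- cbind(runif(40, 0, 3), runif(40, 48, 51))
  alphas <- c(0.4, 0.7, 1.0, 2, 1e6)
  areas <- vapply(alphas, function(a) {
    fp <- tryCatch(alpha_shape(pts, alpha_deg = a),
                   trawlcover_error = function(e) NULL)
    if (is.null(fp)) 0 else fp$area_km2
  }, 0)
  expect_true(all(diff(areas) >= -1e-9))
  dt <- delaunay(pts)
  fp <- alpha_shape(pts, alpha_deg = max(dt$circumradius) + 1e-9)
  expect_true(all(trawlcover:::point_in_geom(pts[, 1], pts[, 2], fp)))
})

test_that("degenerate inputs error or fall back to buffered points", {
  expect_error(alpha_shape(rbind(c(0, 0), c(1, 1))),
               class = "degenerate_input")
  coll <- cbind(seq(0, 1, length.out = 5), seq(0, 2, length.out = 5))
  expect_error(alpha_shape(coll), class = "degenerate_input")
  fb <- alpha_shape(rbind(c(0, 0), c(1, 1)), fallback_buffer_deg = 0.25)
  expect_length(fb$parts, 2)
  expect_gt(fb$area_km2, 0)
})

test_that("antimeridian-straddling point sets are recentered and split back", {
  set.seed(2)
  lon <- c(runif(25, 176, 180), runif(25, -180, -176))
  lat <- runif(50, 55, 58)
  fp <- alpha_shape(cbind(lon, lat), alpha_deg = 3)
  expect_gt(length(fp$parts), 1)
  all_lon <- unlist(lapply(fp$parts, function(p) p[[1]][, 1]))
  expect_true(all(all_lon >= -180 & all_lon <= 180))
  expect_gt(fp$area_km2, 0)
})

test_that("spherical areas agree with closed-form spherical excess", {
  # degenerate zero-width polygon
  sliver <- rbind(c(0, 0), c(1, 0), c(0, 0))
  expect_equal(spherical_area_km2(rbind(sliver, sliver[1, ])), 0,
               tolerance = 1e-9)
  # octant triangle: exactly 1/8 of the sphere
  oct <- rbind(c(0, 0), c(90, 0), c(0, 90), c(0, 0))
  r <- 6371.0072
  expect_equal(spherical_area_km2(oct), 4 * pi * r^2 / 8,
               tolerance = 1e-6)
  # 1x1 degree quadrangle at the equator vs the zonal band formula
  quad <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  band <- r^2 * (pi / 180) * (sin(pi / 180) - 0)
  expect_equal(spherical_area_km2(quad), band, tolerance = 1e-4)
  expect_error(
    spherical_area_km2(rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2), c(0, 0))),
    class = "geometry_error")
})

test_that("footprint unions behave as set unions", {
  sq1 <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  sq2 <- sq1
  u <- union_footprints(list(sq1, sq2))
  expect_equal(union_area(u, "deg2"), 1, tolerance = 1e-12)
  sq3 <- sq1; sq3[, 1] <- sq3[, 1] + 5
  expect_equal(union_area(union_footprints(list(sq1, sq3)), "deg2"), 2,
               tolerance = 1e-12)
  expect_equal(union_area(union_footprints(list())), 0)

  # Monte-Carlo oracle on random overlapping boxes
  set.seed(14)
  boxes <- lapply(1:10, function(i) random_box(c(0, 4, 50, 54)))
  a <- union_area(union_footprints(boxes), "deg2")
  px <- runif(200000, 0, 4); py <- runif(200000, 50, 54)
  hit <- rep(FALSE, length(px))
  for (b in boxes) hit <- hit | (px >= b[1, 1] & px <= b[2, 1] &
                                   py >= b[1, 2] & py <= b[3, 2])
  mc <- mean(hit) * 16
  se <- 16 * sqrt(mean(hit) * (1 - mean(hit)) / length(px))
  expect_lt(abs(a - mc), 4 * se)

  # permutation invariance
  for (k in 1:20) {
    perm <- sample(boxes)
    expect_equal(union_area(union_footprints(perm), "deg2"), a,
                 tolerance = 1e-9)
  }
  # union bounds
  singles <- vapply(boxes, function(b) overlay_area(list(b)), 0)
  expect_lte(a, sum(singles) + 1e-9)
  expect_gte(a, max(singles) - 1e-9)
})
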