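hs <- grid_spec(0, 50, 0.5, 0.5, 12, 10)

test_that("habitat masking is strict at the probability threshold", {
  v <- matrix(seq(0, 1, length.out = 120), 10, 12)
  v[1, 1] <- 0.5
  hm <- habitat_mask(grid_layer(hs, v, "probability"))
  expect_false(hm$values[1, 1])             # p = 0.5 exactly is excluded
  expect_equal(hm$values, v > 0.5)
  zero <- habitat_mask(grid_layer(hs, matrix(0, 10, 12), "probability"))
  expect_equal(sum(zero$values), 0)
  expect_error(habitat_mask(grid_layer(hs, matrix(2, 10, 12))),
               class = "validation_error")
})

test_that("range coverage fields equal an exhaustive cell-loop oracle", {
  set.seed(55)
  gs <- grid_spec(0, 50, 0.2, 0.2, 30, 30)
  hab <- grid_layer(gs, matrix(runif(900) < 0.4, 30, 30))
  sids <- sprintf("S%d", 1:8)
  meta <- meta_of(sids, sample(availability_classes[1:5], 8, TRUE))
  fps <- setNames(lapply(1:8, function(i)
    grid_layer(gs, matrix(runif(900) < 0.25, 30, 30))), sids)
  rc <- range_coverage(hab, fps, meta, target = 0.5, species_code = "XXX")

  helig <- which(hab$values)
  in_s <- vapply(fps, function(f) {
    hit <- rep(FALSE, 900); hit[helig] <- f$values[helig]; hit
  }, logical(900))
  expect_equal(rc$habitat_cells, length(helig))
  expect_equal(rc$covered_fraction,
               sum(apply(in_s, 1, any)) / length(helig))
  marg <- colSums(in_s) / length(helig)
  expect_equal(rc$n_overlapping, sum(marg > 0))
  for (i in seq_len(nrow(rc$overlapping_surveys)))
    expect_equal(rc$overlapping_surveys$marginal_fraction[i],
                 marg[[rc$overlapping_surveys$survey_id[i]]])
  # availability ordering is most-open first
  ranks <- availability_rank(rc$overlapping_surveys$availability)
  expect_true(all(diff(ranks) >= 0))
  expect_equal(rc$n_to_target,
               if (rc$covered_fraction >= 0.5) rc$n_overlapping
               else NA_integer_)
})

test_that("range coverage trivial geometries and error cases", {
  hab <- grid_layer(hs, matrix(FALSE, 10, 12))
  hab$values[3:5, 3:5] <- TRUE
  meta <- meta_of(c("BIG", "FAR"), rep("publicly_available", 2))
  big <- grid_layer(hs, matrix(TRUE, 10, 12))
  rc <- range_coverage(hab, list(BIG = big), meta)
  expect_equal(rc$covered_fraction, 1)
  expect_equal(rc$n_overlapping, 1)
  expect_equal(rc$n_to_target, 1)
  far <- grid_layer(hs, matrix(FALSE, 10, 12))
  rc2 <- range_coverage(hab, list(FAR = far), meta)
  expect_equal(rc2$covered_fraction, 0)
  expect_true(is.na(rc2$n_to_target))
  expect_error(range_coverage(grid_layer(hs, matrix(FALSE, 10, 12)),
                              list(BIG = big), meta),
               class = "undefined_coverage")
  # monotone in the footprint set
  expect_gte(range_coverage(hab, list(BIG = big, FAR = far),
                            meta)$covered_fraction,
             rc2$covered_fraction)
})

test_that("greedy and exact set cover verified against subset enumeration", {
  gs <- grid_spec(0, 50, 0.5, 0.5, 10, 10)
  hab <- grid_layer(gs, matrix(TRUE, 10, 10))
  # nested footprints: greedy needs only the largest
  nested <- setNames(lapply(c(2, 5, 9), function(k) {
    v <- matrix(FALSE, 10, 10); v[1:k, 1:k] <- TRUE
    grid_layer(gs, v)
  }), c("SM", "MD", "LG"))
  g <- surveys_to_target(hab, nested, target = 0.5, method = "greedy")
  expect_equal(g$surveys, "LG")
  expect_equal(g$n, 1)
  # two half-range footprints, full-coverage target
  halves <- setNames(lapply(list(1:5, 6:10), function(rows) {
    v <- matrix(FALSE, 10, 10); v[rows, ] <- TRUE
    grid_layer(gs, v)
  }), c("N", "S"))
  expect_equal(surveys_to_target(hab, halves, 1, "greedy")$n, 2)
  expect_equal(surveys_to_target(hab, halves, 1, "exact")$n, 2)

  set.seed(66)
  fps <- setNames(lapply(1:10, function(i)
    grid_layer(gs, matrix(runif(100) < 0.15, 10, 10))), sprintf("S%02d", 1:10))
  g <- surveys_to_target(hab, fps, 0.5, "greedy")
  e <- surveys_to_target(hab, fps, 0.5, "exact")
  expect_true(all(diff(g$cumulative_fraction) >= 0))
  expect_true(all(diff(e$cumulative_fraction) >= 0))
  # greedy marginal gains are non-increasing
  expect_true(all(diff(diff(c(0, g$cumulative_fraction))) <= 1e-12))
  if (!is.na(e$n) && !is.na(g$n)) expect_lte(e$n, g$n)
  # independent subset enumeration for the optimum
  hit <- lapply(fps, function(f) which(f$values))
  best <- NA_integer_
  for (k in 1:10) {
    found <- any(vapply(combn(names(fps), k, simplify = FALSE), function(cs)
      length(unique(unlist(hit[cs]))) / 100 >= 0.5, logical(1)))
    if (found) { best <- k; break }
  }
  expect_equal(e$n, best)
  expect_error(
    surveys_to_target(hab, rep(fps, 3)[1:21], 0.5, "exact"),
    class = "size_guard")
})

test_that("top species per FAO area ranks by mean annual catch", {
  ct <- expand.grid(species = c("AAA", "BBB", "CCC", "DDD"),
                    fao_area = c(21, 27), year = 2001:2010)
  ct$tons <- 10
  ct$tons[ct$species == "AAA" & ct$fao_area == 21] <- 100
  ct$tons[ct$species == "BBB" & ct$fao_area == 21] <- 50
  ct$tons[ct$species == "CCC" & ct$fao_area == 21] <- 30
  ct$tons[ct$species == "DDD" & ct$fao_area == 27] <- 99
  top <- top_species_per_area(ct, window = c(2001, 2019))
  expect_equal(top$per_area[["21"]], c("AAA", "BBB", "CCC"))
  expect_equal(top$per_area[["27"]][1], "DDD")
  expect_length(top$per_area[["27"]], 3)
  expect_true(!anyDuplicated(top$species))
  one <- data.frame(species = "EEE", fao_area = 34, year = 2005, tons = 5)
  expect_equal(top_species_per_area(one)$species, "EEE")
  expect_warning(
    top_species_per_area(rbind(ct, data.frame(species = "FFF", fao_area = 47,
                                              year = 1990, tons = 1))),
    "no catch data")
  expect_equal(eval(formals(top_species_per_area)$k), 3)
})

test_that("transboundary accounting matches cell and area oracles", {
  regions <- lapply(1:4, function(i)
    region_polygon(sprintf("R%d", i), "eez",
                   rbind(c(i - 1, 50), c(i, 50), c(i, 54), c(i - 1, 54))))
  gs <- grid_spec(0, 50, 0.25, 0.25, 16, 16)
  hab <- grid_layer(gs, matrix(FALSE, 16, 16))
  hab$values[4:8, 2:3] <- TRUE  # inside lon 0.25..0.75: region R1 only
  tb <- region_overlap(hab, regions, "one")
  expect_equal(tb$n_regions, 1)
  expect_false(tb$transboundary)

  set.seed(9)
  hab2 <- grid_layer(gs, matrix(runif(256) < 0.3, 16, 16))
  tb2 <- region_overlap(hab2, regions, "rand")
  cc <- cell_centers(gs)
  on <- as.vector(hab2$values)
  want <- sum(vapply(regions, function(r)
    any(winding_inside(cc$lon[on], cc$lat[on], r$geometry[[1]][[1]])),
    logical(1)))
  expect_equal(tb2$n_regions, want)

  # stock polygon exactly bisected by a region boundary
  stock <- region_polygon("ST", "stock",
                          rbind(c(0.5, 51), c(1.5, 51), c(1.5, 52),
                                c(0.5, 52)))
  tb3 <- region_overlap(stock, regions, "ST")
  expect_equal(tb3$n_regions, 2)
  expect_true(tb3$transboundary)
  # a habitat mask confined to k tiling regions returns k
  hab3 <- grid_layer(gs, matrix(FALSE, 16, 16))
  hab3$values[8, c(2, 6, 10)] <- TRUE  # lon 0.375, 1.375, 2.375
  expect_equal(region_overlap(hab3, regions)$n_regions, 3)
})
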