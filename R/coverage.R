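#' Analysis thresholds
#'
#' The default thresholds of the coverage and range analyses: productive shelf
#' cells lie at 30–500 m depth (inclusive) with chlorophyll-a strictly above
#' 0.5 mg/m³; a cell is fished when more than one trawling event was detected;
#' species habitat is the cells with occurrence probability strictly above 0.5;
#' the survey-sufficiency target is 50% of the habitat cells; footprints use a
#' 1-degree alpha radius; density surfaces are masked below 0.1% of their
#' maximum.  All are configurable (alternative thresholds are a standard
#' sensitivity analysis).
#'
#' @param depth_min_m,depth_max_m Productive depth band, metres.
#' @param chl_min_mg_m3 Chlorophyll-a threshold (strict), mg/m³.
#' @param fished_min_events Fished when at least this many events were
#'   detected; the default 2 is the "more than one trawling activity" rule.
#' @param habitat_p_min Habitat probability threshold (strict).
#' @param range_cover_target Target fraction of habitat cells.
#' @param alpha_deg Alpha-shape radius, degrees.
#' @param density_mask_frac Density mask, fraction of the surface maximum.
#' @return A list of class `threshold_config`.
#' @export
threshold_config <- function(depth_min_m = 30, depth_max_m = 500,
                             chl_min_mg_m3 = 0.5, fished_min_events = 2,
                             habitat_p_min = 0.5, range_cover_target = 0.5,
                             alpha_deg = 1.0, density_mask_frac = 0.001) {
  cfg <- list(depth_min_m = depth_min_m, depth_max_m = depth_max_m,
              chl_min_mg_m3 = chl_min_mg_m3,
              fished_min_events = fished_min_events,
              habitat_p_min = habitat_p_min,
              range_cover_target = range_cover_target,
              alpha_deg = alpha_deg, density_mask_frac = density_mask_frac)
  if (any(vapply(cfg, function(x) !is.numeric(x) || x <= 0, logical(1))))
    stop_trawlcover("all thresholds must be positive", "parameter_error")
  for (f in c("habitat_p_min", "range_cover_target", "density_mask_frac"))
    if (cfg[[f]] >= 1)
      stop_trawlcover(sprintf("%s must lie in (0, 1)", f), "parameter_error")
  structure(cfg, class = "threshold_config")
}

#' Classify productive shelf cells
#'
#' A cell is a productive shelf site iff its depth lies within the
#' `[depth_min_m, depth_max_m]` band (inclusive at both ends) and its
#' chlorophyll-a concentration is strictly above `chl_min_mg_m3`.  Cells
#' missing in either layer are `NA`: never productive and excluded from every
#' denominator.
#'
#' @param depth Depth [grid_layer] (m, positive down).
#' @param chl Chlorophyll-a [grid_layer] (mg/m³), same grid.
#' @param cfg A [threshold_config].
#' @return Logical [grid_layer].
#' @export
classify_productive <- function(depth, chl, cfg = threshold_config()) {
  if (!grid_spec_equal(depth$spec, chl$spec))
    stop_trawlcover("depth and chl grids do not match", "grid_mismatch")
  d <- depth$values; c_ <- chl$values
  v <- d >= cfg$depth_min_m & d <= cfg$depth_max_m & c_ > cfg$chl_min_mg_m3
  grid_layer(depth$spec, v, units = "boolean")
}

#' Classify fished cells
#'
#' A cell is fished iff at least `fished_min_events` trawling events were
#' detected there; the default of 2 encodes the "more than one trawling
#' activity" rule.
#'
#' @param effort Trawl-event count [grid_layer].
#' @param cfg A [threshold_config].
#' @return Logical [grid_layer].
#' @export
classify_fished <- function(effort, cfg = threshold_config()) {
  v <- effort$values
  if (any(v < 0, na.rm = TRUE))
    stop_trawlcover("negative effort counts", "validation_error")
  grid_layer(effort$spec, v >= cfg$fished_min_events, units = "boolean")
}

#' Rasterize polygons onto a grid
#'
#' Cell membership is decided by the cell center (boundary counts as inside),
#' matching the half-open, center-registered grid convention and keeping an
#' exact counting oracle.
#'
#' @param geom A [footprint], [footprint_union], [region_polygon], ring
#'   matrix, or list of parts.  An empty union rasterizes to all-`FALSE`.
#' @param spec Target [grid_spec].
#' @return Logical [grid_layer].
#' @export
rasterize_polygons <- function(geom, spec) {
  cc <- cell_centers(spec)
  empty <- inherits(geom, "footprint_union") && !length(geom$footprints)
  inside <- if (empty) rep(FALSE, nrow(cc))
            else point_in_geom(cc$lon, cc$lat, geom)
  grid_layer(spec, matrix(inside, spec$nrows, spec$ncols), units = "boolean")
}

#' Survey coverage of an eligible-cell mask
#'
#' Counts eligible cells (true, non-missing cells of `mask`) covered by the
#' union of the survey footprint masks.  `by_survey` gives each survey's
#' marginal eligible-cell count; `by_availability` attributes each covered
#' cell once, to the most open availability class among the surveys covering
#' it (public > partly > on-request > not-public > incomplete > unavailable),
#' answering "could data for this cell be obtained?".
#'
#' @param mask Logical eligibility [grid_layer] (productive, fished, ...).
#' @param footprint_masks Named list (survey_id -> logical [grid_layer]).
#' @param meta A [survey_meta] table covering all survey ids.
#' @return A list of class `coverage_result`: `covered_cells`,
#'   `eligible_cells`, `fraction`, `by_survey`, `by_availability`.
#' @export
coverage_fraction <- function(mask, footprint_masks, meta) {
  for (fm in footprint_masks)
    if (!grid_spec_equal(mask$spec, fm$spec))
      stop_trawlcover("footprint mask grid does not match", "grid_mismatch")
  elig <- !is.na(mask$values) & mask$values
  eligible <- sum(elig)
  sids <- names(footprint_masks)
  if (length(footprint_masks) && is.null(sids))
    stop_trawlcover("footprint_masks must be named by survey_id",
                    "validation_error")
  cover_any <- matrix(FALSE, nrow(elig), ncol(elig))
  best_rank <- matrix(Inf, nrow(elig), ncol(elig))
  by_survey <- integer(length(sids)); names(by_survey) <- sids
  ranks <- if (length(sids))
    availability_rank(meta$availability[match(sids, meta$survey_id)])
  else integer(0)
  if (length(sids) && anyNA(ranks))
    stop_trawlcover("footprint survey missing from metadata", "linkage_error")
  for (k in seq_along(sids)) {
    fm <- footprint_masks[[k]]$values
    fm[is.na(fm)] <- FALSE
    hit <- elig & fm
    by_survey[k] <- sum(hit)
    cover_any <- cover_any | hit
    best_rank[hit] <- pmin(best_rank[hit], ranks[k])
  }
  covered <- sum(cover_any)
  by_avail <- integer(length(availability_classes))
  names(by_avail) <- availability_classes
  if (covered) {
    tab <- table(factor(availability_classes[best_rank[cover_any]],
                        levels = availability_classes))
    by_avail[names(tab)] <- as.integer(tab)
  }
  structure(list(covered_cells = covered, eligible_cells = eligible,
                 fraction = if (eligible > 0) covered / eligible else NA_real_,
                 by_survey = by_survey, by_availability = by_avail),
            class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("coverage_result: %d / %d eligible cells covered (%.1f%%)\n",
              x$covered_cells, x$eligible_cells, 100 * x$fraction))
  invisible(x)
}

#' Landings-weighted coverage
#'
#' Ratio of total landings (tons/year) in covered cells to total landings in
#' all non-missing cells.
#'
#' @param landings Landings [grid_layer] (tons/year, non-negative).
#' @param union_mask Logical [grid_layer], the rasterized footprint union.
#' @return Fraction in \[0, 1\]; `NA` when total landings are zero.
#' @export
landings_coverage <- function(landings, union_mask) {
  if (!grid_spec_equal(landings$spec, union_mask$spec))
    stop_trawlcover("landings and mask grids do not match", "grid_mismatch")
  v <- landings$values
  if (any(v < 0, na.rm = TRUE))
    stop_trawlcover("negative landings", "validation_error")
  total <- sum(v, na.rm = TRUE)
  if (total == 0) return(NA_real_)
  m <- union_mask$values
  m[is.na(m)] <- FALSE
  sum(v[m], na.rm = TRUE) / total
}

#' Availability tallies over hauls
#'
#' Counts surveys and hauls per availability class.  Haul shares sum to one
#' over the six classes; the aggregate share of effectively unavailable data
#' (`not_publicly_available` + `incomplete_metadata`) is also reported.
#'
#' @param meta A [survey_meta] table.
#' @param hauls Haul data.frame; every haul's survey must have metadata.
#' @return A data.frame (class, surveys, hauls, haul_share) with attribute
#'   `not_available_share`.
#' @export
tally_availability <- function(meta, hauls) {
  orphan <- setdiff(unique(hauls$survey_id), meta$survey_id)
  if (length(orphan))
    stop_trawlcover(sprintf("hauls without metadata: %s",
                            paste(orphan, collapse = ", ")), "linkage_error")
  av <- meta$availability[match(hauls$survey_id, meta$survey_id)]
  haul_tab <- table(factor(av, levels = availability_classes))
  surv_tab <- table(factor(meta$availability, levels = availability_classes))
  out <- data.frame(class = availability_classes,
                    surveys = as.integer(surv_tab),
                    hauls = as.integer(haul_tab),
                    haul_share = as.numeric(haul_tab) / max(1, nrow(hauls)),
                    stringsAsFactors = FALSE)
  attr(out, "not_available_share") <-
    sum(out$haul_share[out$class %in%
                         c("not_publicly_available", "incomplete_metadata")])
  out
}
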