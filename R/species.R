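#' Species habitat mask
#'
#' Thresholds a probability-of-occurrence surface (AquaMaps-style, typically
#' 0.5°) into a habitat mask: cells with probability strictly above `p_min`.
#'
#' @param habitat Probability [grid_layer] in \[0, 1\].
#' @param p_min Threshold (strict); default 0.5.
#' @return Logical [grid_layer].
#' @export
habitat_mask <- function(habitat, p_min = 0.5) {
  v <- habitat$values
  if (any(v < 0 | v > 1, na.rm = TRUE))
    stop_trawlcover("habitat probabilities outside [0, 1]", "validation_error")
  grid_layer(habitat$spec, v > p_min, units = "boolean")
}

#' Species range coverage by survey footprints
#'
#' Fraction of habitat cells covered by the footprint union, the surveys
#' overlapping the range (most-open availability first, largest overlap
#' first), and the number of surveys "needed": by default the count of
#' overlapping surveys when union coverage reaches `target` (the survey-count
#' convention of coverage tallies), with the greedy/exact minimal-set planner
#' available through [surveys_to_target].
#'
#' @param hmask Logical habitat [grid_layer] (see [habitat_mask]).
#' @param footprints Named list of [footprint] objects or of logical
#'   footprint masks on the habitat grid (survey_id -> footprint).
#' @param meta A [survey_meta] table.
#' @param target Target fraction of habitat cells; default 0.5.
#' @param species_code ASFIS 3-letter code attached to the result.
#' @return A list of class `range_coverage`: `species_code`, `habitat_cells`,
#'   `covered_fraction`, `overlapping_surveys` (data.frame of survey_id,
#'   marginal_fraction, availability), `n_overlapping`, `n_to_target`
#'   (`NA` = unattainable).
#' @export
range_coverage <- function(hmask, footprints, meta, target = 0.5,
                           species_code = "") {
  masks <- footprint_masks_on(hmask$spec, footprints)
  helig <- !is.na(hmask$values) & hmask$values
  n_hab <- sum(helig)
  if (n_hab == 0)
    stop_trawlcover("empty habitat mask: coverage undefined",
                    "undefined_coverage")
  sids <- names(masks)
  marg <- vapply(masks, function(m) {
    v <- m$values; v[is.na(v)] <- FALSE
    sum(helig & v)
  }, 0)
  cover_any <- Reduce(`|`, lapply(masks, function(m) {
    v <- m$values; v[is.na(v)] <- FALSE; v
  }), matrix(FALSE, hmask$spec$nrows, hmask$spec$ncols))
  frac <- sum(helig & cover_any) / n_hab
  av <- meta$availability[match(sids, meta$survey_id)]
  keep <- marg > 0
  o <- order(availability_rank(av[keep]), -marg[keep], sids[keep])
  overlapping <- data.frame(
    survey_id = sids[keep][o],
    marginal_fraction = unname(marg[keep][o]) / n_hab,
    availability = av[keep][o],
    stringsAsFactors = FALSE)
  structure(list(
    species_code = species_code,
    habitat_cells = n_hab,
    covered_fraction = frac,
    overlapping_surveys = overlapping,
    n_overlapping = nrow(overlapping),
    n_to_target = if (frac >= target) nrow(overlapping) else NA_integer_),
    class = "range_coverage")
}

#' @export
print.range_coverage <- function(x, ...) {
  cat(sprintf(
    "range_coverage %s: %.1f%% of %d habitat cells; %d overlapping survey(s)%s\n",
    x$species_code, 100 * x$covered_fraction, x$habitat_cells,
    x$n_overlapping,
    if (is.na(x$n_to_target)) " (target unattainable)"
    else sprintf("; n_to_target = %d", x$n_to_target)))
  invisible(x)
}

footprint_masks_on <- function(spec, footprints) {
  if (length(footprints) && is.null(names(footprints)))
    stop_trawlcover("footprints must be named by survey_id",
                    "validation_error")
  lapply(footprints, function(f) {
    if (inherits(f, "grid_layer")) {
      if (!grid_spec_equal(f$spec, spec))
        stop_trawlcover("footprint mask grid does not match habitat grid",
                        "grid_mismatch")
      f
    } else rasterize_polygons(f, spec)
  })
}

#' Minimal survey sets reaching a habitat-coverage target
#'
#' Greedy: repeatedly add the footprint with the largest marginal habitat
#' gain (ties broken lexicographically by survey id) until the cumulative
#' covered fraction reaches `target`.  Exact: minimum-cardinality subset
#' reaching the target, by exhaustive subset enumeration (guarded to at most
#' 20 footprints).
#'
#' @param hmask Logical habitat [grid_layer].
#' @param footprints Named list of [footprint]s or footprint masks.
#' @param target Target fraction of habitat cells.
#' @param method `"greedy"` or `"exact"`.
#' @return List with `surveys` (ordered ids), `cumulative_fraction`
#'   (non-decreasing, same length), `n` (`NA` when the target is
#'   unattainable even with every footprint).
#' @export
surveys_to_target <- function(hmask, footprints, target = 0.5,
                              method = c("greedy", "exact")) {
  method <- match.arg(method)
  if (!length(footprints))
    stop_trawlcover("need at least one footprint", "parameter_error")
  masks <- footprint_masks_on(hmask$spec, footprints)
  helig <- !is.na(hmask$values) & hmask$values
  n_hab <- sum(helig)
  if (n_hab == 0)
    stop_trawlcover("empty habitat mask", "undefined_coverage")
  hit <- lapply(masks, function(m) {
    v <- m$values; v[is.na(v)] <- FALSE
    which(helig & v)
  })
  sids <- names(masks)
  all_cov <- length(unique(unlist(hit))) / n_hab
  if (method == "greedy") {
    chosen <- character(0); cum <- numeric(0)
    covered <- integer(0)
    remaining <- sids
    while (length(remaining)) {
      gain <- vapply(remaining, function(s)
        length(setdiff(hit[[s]], covered)), 0L)
      o <- order(-gain, remaining)
      best <- remaining[o[1]]
      if (gain[o[1]] == 0L) break
      covered <- union(covered, hit[[best]])
      chosen <- c(chosen, best)
      cum <- c(cum, length(covered) / n_hab)
      remaining <- setdiff(remaining, best)
      if (utils::tail(cum, 1) >= target) break
    }
    reached <- length(cum) > 0 && utils::tail(cum, 1) >= target
    return(list(surveys = chosen, cumulative_fraction = cum,
                n = if (reached) length(chosen) else NA_integer_))
  }
  # exact: exhaustive subset search by increasing cardinality
  if (length(sids) > 20)
    stop_trawlcover("exact set cover guarded to at most 20 footprints",
                    "size_guard")
  if (all_cov < target)
    return(list(surveys = character(0), cumulative_fraction = numeric(0),
                n = NA_integer_))
  for (k in seq_along(sids)) {
    combos <- utils::combn(sids, k, simplify = FALSE)
    for (cs in combos) {
      cov <- length(unique(unlist(hit[cs])))
      if (cov / n_hab >= target) {
        cum <- numeric(0); covered <- integer(0)
        for (s in cs) {
          covered <- union(covered, hit[[s]])
          cum <- c(cum, length(covered) / n_hab)
        }
        return(list(surveys = cs, cumulative_fraction = cum, n = k))
      }
    }
  }
  list(surveys = character(0), cumulative_fraction = numeric(0),
       n = NA_integer_)  # unreachable
}

#' Top commercial species per FAO area
#'
#' Ranks species by mean annual catch over a window within each FAO fishing
#' area and returns the top `k` (default 3) per area, plus the deduplicated
#' union across areas.
#'
#' @param catch_table data.frame with `species`, `fao_area`, `year`, `tons`.
#' @param window Inclusive year window for the mean.
#' @param k Species per area.
#' @return List with `per_area` (named list of character vectors) and
#'   `species` (deduplicated union).  Areas with no data in the window are
#'   skipped with a warning.
#' @export
top_species_per_area <- function(catch_table, window = c(2001, 2019), k = 3) {
  stopifnot(all(c("species", "fao_area", "year", "tons") %in%
                  names(catch_table)))
  if (!nrow(catch_table))
    stop_trawlcover("empty catch table", "validation_error")
  ct <- catch_table[catch_table$year >= window[1] &
                      catch_table$year <= window[2], ]
  per_area <- list()
  for (a in sort(unique(catch_table$fao_area))) {
    sub <- ct[ct$fao_area == a, ]
    if (!nrow(sub)) {
      warning(sprintf("FAO area %s has no catch data in the window; skipped",
                      a))
      next
    }
    mean_catch <- tapply(sub$tons, sub$species, mean)
    o <- order(-mean_catch, names(mean_catch))
    per_area[[as.character(a)]] <-
      names(mean_catch)[o][seq_len(min(k, length(mean_catch)))]
  }
  list(per_area = per_area, species = unique(unlist(per_area)))
}

#' Transboundary overlap of a range or stock with regions
#'
#' For a habitat mask, a region is overlapped when at least one habitat cell
#' center falls inside it; for a stock polygon, when the polygon-region
#' intersection area exceeds a relative tolerance (1e-6 of the smaller area).
#' A subject is transboundary when it overlaps more than one region.
#'
#' @param subject Logical habitat [grid_layer] or a [region_polygon] /
#'   polygon-like stock boundary.
#' @param regions List of [region_polygon] objects.
#' @param subject_id Identifier for the report.
#' @param tol Relative intersection-area tolerance for polygon subjects.
#' @return A list of class `transboundary_report`: `subject_id`, `kind`,
#'   `regions_overlapped`, `n_regions`, `transboundary`.
#' @export
region_overlap <- function(subject, regions, subject_id = "", tol = 1e-6) {
  ids <- vapply(regions, function(r) r$region_id, "")
  if (inherits(subject, "grid_layer")) {
    cc <- cell_centers(subject$spec)
    hab <- as.vector(!is.na(subject$values) & subject$values)
    hit <- vapply(regions, function(r)
      any(point_in_geom(cc$lon[hab], cc$lat[hab], r)), logical(1))
    kind <- "species_range"
  } else {
    sub_area <- overlay_area(list(subject), 1, "deg2")
    hit <- vapply(regions, function(r) {
      reg_area <- overlay_area(list(r), 1, "deg2")
      inter <- overlay_area(list(subject, r), 2, "deg2")
      inter > tol * min(sub_area, reg_area)
    }, logical(1))
    kind <- "stock"
  }
  structure(list(subject_id = subject_id, kind = kind,
                 regions_overlapped = ids[hit],
                 n_regions = sum(hit), transboundary = sum(hit) > 1),
            class = "transboundary_report")
}

#' @export
print.transboundary_report <- function(x, ...) {
  cat(sprintf("transboundary_report %s [%s]: %d region(s)%s\n",
              x$subject_id, x$kind, x$n_regions,
              if (x$transboundary) " (transboundary)" else ""))
  invisible(x)
}
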