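#' Default pipeline configuration
#'
#' A complete synthetic-study configuration: a 0.2° shelf world with five
#' surveys in four EEZ-like regions, coverage thresholds at their defaults,
#' two species habitat surfaces on a 0.5° grid, and a two-survey delta-gamma
#' density stage.  Any element can be overridden through `run_pipeline`'s
#' `config` argument (lists are merged shallowly per stage).
#'
#' @param seed Integer seed recorded in every artifact.
#' @return A nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    grid = list(lon_origin = 0, lat_origin = 50, dlon = 0.2, dlat = 0.2,
                ncols = 50, nrows = 40),
    world = list(coast_axis = "W", n_regions = 4),
    surveys = list(
      n_hauls = 400,
      defs = list(
        list(survey_id = "SVA", region = c(0, 6, 50, 52), years = 2001:2018,
             availability = "publicly_available"),
        list(survey_id = "SVB", region = c(0, 6, 52, 54), years = 2005:2019,
             availability = "publicly_available"),
        list(survey_id = "SVC", region = c(0, 6, 54, 56), years = 2001:2019,
             availability = "available_upon_request"),
        list(survey_id = "SVD", region = c(0, 6, 56, 58), years = 2010:2019,
             availability = "not_publicly_available"),
        list(survey_id = "SVE", region = c(0, 4, 52, 56), years = 2012:2014,
             availability = "incomplete_metadata"))),
    thresholds = list(),
    species = list(
      habitat_dlon = 0.5,
      list(code = "AAA", center = c(1.5, 53), decay_scale = 40,
           midpoint_km = 180),
      list(code = "BBB", center = c(1.2, 55), decay_scale = 60,
           midpoint_km = 280)),
    density = list(
      enabled = TRUE,
      surveys = c("SVB", "SVE"),
      years = 2010:2015,
      hauls_per_year = 150,
      beta_n_start = 3, beta_n_trend = 0.05,
      beta_w = -1.2, cv = 0.8,
      drift_deg_per_year = 0.1,
      mask_frac = 0.001),
    stages = list(footprints = TRUE, coverage = TRUE, species = TRUE,
                  transboundary = TRUE, density = TRUE),
    out_dir = NULL)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(config, f)
  unname(tools::md5sum(f))
}

#' Run the full synthetic-study pipeline
#'
#' Executes the stages in dependency order — simulate world and hauls,
#' survey inclusion filtering, alpha-shape footprints, productive/fished
#' coverage and landings coverage, availability tallies, species range
#' coverage and survey sufficiency, transboundary accounting, and the
#' delta-gamma density stage with a center-of-gravity track — and collates a
#' report stamped with the seed and a configuration hash.  Re-running with an
#' unchanged configuration reproduces the report bit for bit.
#'
#' @param config A configuration list (see [default_config]); may be partial
#'   (merged over the defaults) or a path to a YAML file.
#' @param seed Overrides `config$seed` when not `NULL`.
#' @param verbose Print per-stage progress.
#' @return The report list (invisibly also written as JSON to
#'   `config$out_dir` when set).
#' @export
run_pipeline <- function(config = list(), seed = NULL, verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_config(), config)
  if (!is.null(seed)) cfg$seed <- seed
  say <- function(...) if (verbose) message(sprintf(...))
  thr <- do.call(threshold_config, cfg$thresholds)
  report <- list(seed = cfg$seed, config_hash = config_hash(cfg))

  say("stage: simulate")
  spec <- with(cfg$grid, grid_spec(lon_origin, lat_origin, dlon, dlat,
                                   ncols, nrows))
  world <- gen_world(spec, seed = cfg$seed, coast_axis = cfg$world$coast_axis,
                     n_regions = cfg$world$n_regions)
  defs <- lapply(cfg$surveys$defs, function(d) {
    d$n_hauls <- d$n_hauls %||% cfg$surveys$n_hauls
    d$region <- unlist(d$region)
    d
  })
  sim <- gen_hauls(world, defs, seed = cfg$seed + 1)
  hauls <- sim$hauls; meta <- sim$meta
  part <- filter_surveys(meta, hauls,
                         window = range(unlist(meta$years_sampled)))
  report$surveys <- list(
    n_surveys = nrow(meta), n_hauls = nrow(hauls),
    included = part$included, excluded = part$excluded)

  fps <- NULL
  if (isTRUE(cfg$stages$footprints)) {
    say("stage: footprints")
    fps <- lapply(part$included, function(sid) {
      h <- hauls[hauls$survey_id == sid, ]
      alpha_shape(cbind(h$lon, h$lat), alpha_deg = thr$alpha_deg,
                  survey_id = sid)
    })
    names(fps) <- part$included
    report$footprints <- list(
      alpha_deg = thr$alpha_deg,
      areas_km2 = vapply(fps, function(f) f$area_km2, 0),
      union_area_km2 = union_area(union_footprints(fps), "km2"))
  }

  if (isTRUE(cfg$stages$coverage) && !is.null(fps)) {
    say("stage: coverage")
    productive <- classify_productive(world$depth, world$chl, thr)
    fished <- classify_fished(world$effort, thr)
    fmasks <- lapply(fps, rasterize_polygons, spec = spec)
    cov_p <- coverage_fraction(productive, fmasks, meta)
    cov_f <- coverage_fraction(fished, fmasks, meta)
    umask <- rasterize_polygons(union_footprints(fps), spec)
    tal <- tally_availability(meta, hauls)
    report$coverage <- list(
      productive_fraction = cov_p$fraction,
      fished_fraction = cov_f$fraction,
      landings_fraction = landings_coverage(world$landings, umask),
      productive = unclass(cov_p), fished = unclass(cov_f),
      availability = tal,
      not_available_share = attr(tal, "not_available_share"))
  }

  if (isTRUE(cfg$stages$species) && !is.null(fps)) {
    say("stage: species")
    hd <- cfg$species$habitat_dlon
    hspec <- grid_spec(spec$lon_origin, spec$lat_origin, hd, hd,
                       ceiling(spec$ncols * spec$dlon / hd),
                       ceiling(spec$nrows * spec$dlat / hd))
    sp_defs <- Filter(function(x) is.list(x) && !is.null(x$code),
                      cfg$species)
    report$species <- lapply(sp_defs, function(sd) {
      hab <- gen_habitat(hspec, unlist(sd$center), sd$decay_scale,
                         midpoint_km = sd$midpoint_km)
      hm <- habitat_mask(hab, thr$habitat_p_min)
      rc <- range_coverage(hm, fps, meta, target = thr$range_cover_target,
                           species_code = sd$code)
      planner <- surveys_to_target(hm, fps,
                                   target = thr$range_cover_target,
                                   method = "greedy")
      tb <- if (isTRUE(cfg$stages$transboundary))
        region_overlap(hm, world$regions, subject_id = sd$code)
      list(code = sd$code, habitat_cells = rc$habitat_cells,
           covered_fraction = rc$covered_fraction,
           n_overlapping = rc$n_overlapping, n_to_target = rc$n_to_target,
           greedy_n = planner$n, greedy_surveys = planner$surveys,
           n_eez = if (!is.null(tb)) tb$n_regions,
           transboundary = if (!is.null(tb)) tb$transboundary)
    })
  }

  if (isTRUE(cfg$stages$density) && isTRUE(cfg$density$enabled)) {
    say("stage: density")
    dc <- cfg$density
    # basis scaling and prediction grid span the density surveys' combined
    # region: the model interpolates within the survey domain, it does not
    # extrapolate beyond it
    drings <- lapply(dc$surveys, function(sid)
      def_region_ring(unlist(Filter(function(d) d$survey_id == sid,
                                    defs)[[1]]$region)))
    bbox <- c(range(unlist(lapply(drings, function(r) r[, 1]))),
              range(unlist(lapply(drings, function(r) r[, 2]))))
    basis <- spatial_basis("poly2", bbox)
    years <- dc$years
    ny <- length(years)
    # drifting unimodal truth: bump center moves north at the stated rate
    ctr_lat0 <- mean(bbox[3:4]) - dc$drift_deg_per_year * (ny - 1) / 2
    gam <- vapply(seq_len(ny), function(t)
      drift_gamma_poly2(bbox, mean(bbox[1:2]),
                        ctr_lat0 + dc$drift_deg_per_year * (t - 1)),
      numeric(8))
    truth <- delta_gamma_truth(
      years = years, surveys = dc$surveys,
      beta_n = dc$beta_n_start + dc$beta_n_trend * (seq_len(ny) - 1),
      beta_w = rep(dc$beta_w, ny),
      eta = c(0, rep(0.2, length(dc$surveys) - 1)),
      gamma = gam, basis = basis, cv = dc$cv)
    dhauls <- do.call(rbind, lapply(dc$surveys, function(sid) {
      def <- Filter(function(d) d$survey_id == sid, defs)[[1]]
      ring <- def_region_ring(unlist(def$region))
      do.call(rbind, lapply(years, function(y) {
        # spatially balanced stations (uniform), as survey designs intend
        pts <- sample_survey_points(world, ring, c(range(ring[, 1]),
                                                   range(ring[, 2])),
                                    dc$hauls_per_year, NULL, 20)
        data.frame(survey_id = sid, year = y, lon = pts[, 1], lat = pts[, 2])
      }))
    }))
    catches <- gen_catches(truth, dhauls, seed = cfg$seed + 2)
    fit <- fit_delta_gamma(catches, basis = basis,
                           reference_survey = dc$surveys[1])
    dspec <- grid_spec(bbox[1], bbox[3], 0.25, 0.25,
                       ceiling((bbox[2] - bbox[1]) / 0.25),
                       ceiling((bbox[4] - bbox[3]) / 0.25))
    track <- cog_track(fit, dspec, mask_frac = 0,
                       domain = union_footprints(drings))
    report$density <- list(
      converged = fit$convergence, loglik = fit$loglik, cv = fit$cv,
      n_obs = fit$n_obs,
      eta = as.list(fit$eta), beta_n = as.list(fit$beta_n),
      cog_track = track,
      net_displacement_km = track$displacement_km[nrow(track)],
      net_bearing_deg = track$bearing_deg[nrow(track)],
      mask_frac = dc$mask_frac)
  }

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  report
}

# quadratic-basis coefficients of a north-drifting log-density bump:
# log n(x, y) ~ -((y - c)^2) / (2 s^2) in scaled coordinates, expanded onto
# the poly2 terms (y, y^2); the linear term carries the drift
drift_gamma_poly2 <- function(bbox, ctr_lon, ctr_lat, s = 0.45) {
  yc <- 2 * (ctr_lat - bbox[3]) / (bbox[4] - bbox[3]) - 1
  g <- numeric(8)  # terms: x, y, xy, x^2, y^2, x^2 y, x y^2, x^2 y^2
  g[2] <- yc / s^2
  g[5] <- -1 / (2 * s^2)
  g
}
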