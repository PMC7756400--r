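# Seeded generators for every input the pipeline consumes: a shelf-like world
# (bathymetry, chlorophyll, trawl effort, landings, region tiling), clustered
# survey haul point patterns, unimodal habitat probability surfaces, and
# catches drawn from the Poisson-link delta-gamma generative model.  Each
# generator seeds one RNG at entry and records its parameters in `truth`, so
# every expected value downstream is recomputable in closed form.

#' Generate a synthetic shelf world
#'
#' Depth increases monotonically with distance from the designated coast edge
#' (0 at the coast to `depth_max_m` offshore); chlorophyll-a decays
#' exponentially from the coast; trawl-effort counts are Poisson, concentrated
#' where depth lies in the trawlable 30–500 m band; landings are positive
#' exactly where effort is positive; rectangular regions tile the domain with
#' no overlap.  Depth and chlorophyll are deterministic closed-form fields of
#' position, so classification fractions can be enumerated exactly from
#' `truth`.
#'
#' @param spec A [grid_spec] for all layers.
#' @param seed Integer seed.
#' @param coast_axis Which edge is the coast: `"W"`, `"E"`, `"S"` or `"N"`.
#' @param n_regions Number of rectangular regions tiling the domain.
#' @param depth_max_m,depth_power Offshore depth profile `depth_max * f^power`
#'   of the fractional distance `f` from the coast.
#' @param chl_max,chl_min Coastal and far-field chlorophyll (mg/m³).
#' @param chl_scale_frac e-folding scale of the chlorophyll decay, as a
#'   fraction of the domain width.
#' @param effort_lambda_in,effort_lambda_out Poisson means of trawl events
#'   inside / outside the 30–500 m band.
#' @return A list of class `synthetic_world`: `spec`, layers `depth`, `chl`,
#'   `effort`, `landings`, `regions`, and `truth` (all generating parameters).
#' @export
gen_world <- function(spec, seed, coast_axis = "W", n_regions = 4,
                      depth_max_m = 2000, depth_power = 1,
                      chl_max = 5, chl_min = 0.05, chl_scale_frac = 1 / 3,
                      effort_lambda_in = 6, effort_lambda_out = 0.2) {
  stopifnot(inherits(spec, "grid_spec"))
  coast_axis <- match.arg(coast_axis, c("W", "E", "S", "N"))
  set.seed(seed)
  cc <- cell_centers(spec)
  width_lon <- spec$ncols * spec$dlon
  width_lat <- spec$nrows * spec$dlat
  f <- switch(coast_axis,
    W = (cc$lon - spec$lon_origin) / width_lon,
    E = (spec$lon_origin + width_lon - cc$lon) / width_lon,
    S = (cc$lat - spec$lat_origin) / width_lat,
    N = (spec$lat_origin + width_lat - cc$lat) / width_lat)
  depth_v <- depth_max_m * f^depth_power
  chl_v <- chl_min + (chl_max - chl_min) * exp(-f / chl_scale_frac)
  shape <- function(v) matrix(v, spec$nrows, spec$ncols)
  depth <- grid_layer(spec, shape(depth_v), "m")
  chl <- grid_layer(spec, shape(chl_v), "mg/m3")
  in_band <- depth_v >= 30 & depth_v <= 500
  lam <- ifelse(in_band, effort_lambda_in, effort_lambda_out)
  effort_v <- stats::rpois(length(lam), lam)
  effort <- grid_layer(spec, shape(effort_v), "events")
  landings_v <- ifelse(effort_v > 0,
                       effort_v * stats::rlnorm(length(effort_v), 2, 0.5), 0)
  landings <- grid_layer(spec, shape(landings_v), "tons/year")
  # rectangular tiling along the axis orthogonal to the coast gradient
  breaks <- if (coast_axis %in% c("W", "E"))
    seq(spec$lat_origin, spec$lat_origin + width_lat, length.out = n_regions + 1)
  else
    seq(spec$lon_origin, spec$lon_origin + width_lon, length.out = n_regions + 1)
  regions <- lapply(seq_len(n_regions), function(i) {
    if (coast_axis %in% c("W", "E")) {
      y1 <- breaks[i]; y2 <- breaks[i + 1]
      x1 <- spec$lon_origin; x2 <- spec$lon_origin + width_lon
    } else {
      x1 <- breaks[i]; x2 <- breaks[i + 1]
      y1 <- spec$lat_origin; y2 <- spec$lat_origin + width_lat
    }
    region_polygon(sprintf("EEZ%02d", i), "eez",
                   rbind(c(x1, y1), c(x2, y1), c(x2, y2), c(x1, y2)))
  })
  truth <- list(seed = seed, coast_axis = coast_axis,
                depth_max_m = depth_max_m, depth_power = depth_power,
                chl_max = chl_max, chl_min = chl_min,
                chl_scale_frac = chl_scale_frac,
                effort_lambda_in = effort_lambda_in,
                effort_lambda_out = effort_lambda_out,
                n_regions = n_regions)
  structure(list(spec = spec, depth = depth, chl = chl, effort = effort,
                 landings = landings, regions = regions, truth = truth),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("synthetic_world (seed %d): %s, %d regions, coast %s\n",
              x$truth$seed, format(x$spec), length(x$regions),
              x$truth$coast_axis))
  invisible(x)
}

#' Generate clustered survey hauls
#'
#' Haul positions follow a parent-offspring (Neyman-Scott-like) process
#' mimicking stratified survey designs: cluster parents are placed inside the
#' survey's region, preferentially within the trawlable 30–500 m band, and
#' offspring scatter around them (rejected back into the region).  Uniform
#' placement is the degenerate `cluster_sd_deg = NULL` option.  Each haul
#' carries its year (uniform over the survey's sampled years), the depth read
#' from the world's bathymetry, and its distance to the coast edge in
#' nautical miles.
#'
#' @param world A [gen_world] world.
#' @param survey_defs List of definitions: each a list with `survey_id`,
#'   `region` (ring matrix, [region_polygon], or `c(lon1, lon2, lat1, lat2)`
#'   box), `n_hauls`, `years`, and optional `availability`.
#' @param seed Integer seed.
#' @param availability_probs Distribution over the six [availability_classes]
#'   used to draw availability labels for definitions that do not fix one.
#' @param cluster_sd_deg Offspring scatter (degrees); `NULL` for uniform.
#' @param hauls_per_cluster Mean offspring per parent.
#' @return List with `hauls` (validated data.frame) and `meta`
#'   (a [survey_meta]).
#' @export
gen_hauls <- function(world, survey_defs, seed,
                      availability_probs = c(0.35, 0.1, 0.15, 0.2, 0.1, 0.1),
                      cluster_sd_deg = 0.15, hauls_per_cluster = 20) {
  set.seed(seed)
  spec <- world$spec
  dom <- c(spec$lon_origin, spec$lon_origin + spec$ncols * spec$dlon,
           spec$lat_origin, spec$lat_origin + spec$nrows * spec$dlat)
  hauls <- NULL
  avail <- character(0)
  for (def in survey_defs) {
    ring <- def_region_ring(def$region)
    bb <- c(range(ring[, 1]), range(ring[, 2]))
    if (bb[1] < dom[1] - 1e-9 || bb[2] > dom[2] + 1e-9 ||
        bb[3] < dom[3] - 1e-9 || bb[4] > dom[4] + 1e-9)
      stop_trawlcover(sprintf("survey %s region outside the world domain",
                              def$survey_id), "domain_error")
    n <- def$n_hauls
    avail <- c(avail, def$availability %||%
                 sample(availability_classes, 1, prob = availability_probs))
    if (n == 0) next
    pts <- sample_survey_points(world, ring, bb, n, cluster_sd_deg,
                                hauls_per_cluster)
    depth <- lookup_layer(world$depth, pts[, 1], pts[, 2])
    d_coast_nm <- coast_distance_nm(world, pts[, 1], pts[, 2])
    hauls <- rbind(hauls, data.frame(
      survey_id = def$survey_id, lon = pts[, 1], lat = pts[, 2],
      year = sample(rep(def$years, length.out = max(n, length(def$years))),
                    n, replace = TRUE),
      depth_m = depth, distance_to_coast_nm = d_coast_nm,
      stringsAsFactors = FALSE))
  }
  meta <- survey_meta(
    survey_id = vapply(survey_defs, `[[`, "", "survey_id"),
    availability = avail,
    years_sampled = lapply(survey_defs, `[[`, "years"))
  if (is.null(hauls))
    hauls <- data.frame(survey_id = character(0), lon = numeric(0),
                        lat = numeric(0), year = integer(0),
                        depth_m = numeric(0),
                        distance_to_coast_nm = numeric(0))
  list(hauls = validate_hauls(hauls, year_window = range(unlist(
         lapply(survey_defs, `[[`, "years")))),
       meta = meta)
}

def_region_ring <- function(region) {
  if (inherits(region, "region_polygon")) return(region$geometry[[1]][[1]])
  if (is.matrix(region)) return(close_ring(region))
  if (is.numeric(region) && length(region) == 4)
    return(close_ring(rbind(c(region[1], region[3]), c(region[2], region[3]),
                            c(region[2], region[4]), c(region[1], region[4]))))
  stop_trawlcover("cannot interpret survey region", "domain_error")
}

sample_survey_points <- function(world, ring, bb, n, cluster_sd_deg,
                                 hauls_per_cluster) {
  in_region <- function(lon, lat) point_in_ring(lon, lat, ring)
  draw_uniform <- function(m) {
    out <- NULL
    while (is.null(out) || nrow(out) < m) {
      lon <- stats::runif(2 * m, bb[1], bb[2])
      lat <- stats::runif(2 * m, bb[3], bb[4])
      ok <- in_region(lon, lat)
      out <- rbind(out, cbind(lon[ok], lat[ok]))
    }
    out[seq_len(m), , drop = FALSE]
  }
  if (is.null(cluster_sd_deg)) return(draw_uniform(n))
  n_parents <- max(1, ceiling(n / hauls_per_cluster))
  # parents preferentially in the trawlable band
  cand <- draw_uniform(50 * n_parents)
  d <- lookup_layer(world$depth, cand[, 1], cand[, 2])
  band <- !is.na(d) & d >= 30 & d <= 500
  pool <- if (sum(band) >= n_parents) cand[band, , drop = FALSE] else cand
  parents <- pool[sample(nrow(pool), n_parents), , drop = FALSE]
  out <- NULL
  while (is.null(out) || nrow(out) < n) {
    k <- n - if (is.null(out)) 0 else nrow(out)
    p <- parents[sample(n_parents, 2 * k, replace = TRUE), , drop = FALSE]
    lon <- p[, 1] + stats::rnorm(2 * k, 0, cluster_sd_deg)
    lat <- p[, 2] + stats::rnorm(2 * k, 0, cluster_sd_deg)
    ok <- in_region(lon, lat)
    out <- rbind(out, cbind(lon[ok], lat[ok]))
  }
  out[seq_len(n), , drop = FALSE]
}

lookup_layer <- function(layer, lon, lat) {
  ci <- cell_index(layer$spec, lon, lat)
  v <- rep(NA_real_, length(lon))
  ok <- !is.na(ci$col)
  v[ok] <- layer$values[cbind(ci$row[ok], ci$col[ok])]
  v
}

coast_distance_nm <- function(world, lon, lat) {
  spec <- world$spec
  deg <- switch(world$truth$coast_axis,
    W = (lon - spec$lon_origin) * cos(lat * pi / 180),
    E = (spec$lon_origin + spec$ncols * spec$dlon - lon) * cos(lat * pi / 180),
    S = lat - spec$lat_origin,
    N = spec$lat_origin + spec$nrows * spec$dlat - lat)
  deg * 60
}

#' Generate a habitat probability surface
#'
#' AquaMaps-style unimodal probability-of-occurrence field on a (typically
#' 0.5°) grid: a logistic function of great-circle distance to the range
#' center, equal to 0.5 at `midpoint_km` and maximal at the center.
#'
#' @param spec_coarse Habitat [grid_spec] (typically 0.5° cells).
#' @param center `c(lon, lat)` of the range center.
#' @param decay_scale Logistic scale of the distance decay, km (> 0).
#' @param seed Accepted for generator-interface uniformity; the field is a
#'   deterministic function of its parameters.
#' @param midpoint_km Distance at which probability crosses 0.5.
#' @return A probability [grid_layer].
#' @export
gen_habitat <- function(spec_coarse, center, decay_scale, seed = 0,
                        midpoint_km = 500) {
  if (!(is.numeric(decay_scale) && decay_scale > 0))
    stop_trawlcover("decay_scale must be positive", "parameter_error")
  cc <- cell_centers(spec_coarse)
  d <- geosphere::distHaversine(cbind(cc$lon, cc$lat), center,
                                r = .mean_radius_km * 1000) / 1000
  p <- stats::plogis((midpoint_km - d) / decay_scale)
  grid_layer(spec_coarse,
             matrix(p, spec_coarse$nrows, spec_coarse$ncols), "probability")
}

#' Delta-gamma generative truth
#'
#' The generating parameters of the Poisson-link delta-gamma catch model:
#' year effects for log numbers-density and log mean weight, per-survey log
#' catchability with the reference survey fixed at 0, year-varying spatial
#' basis coefficients, the gamma CV, and the lognormal area-swept
#' distribution.
#'
#' @param years Integer years.
#' @param surveys Survey ids; the first is the reference.
#' @param beta_n,beta_w Year effects (length of `years`).
#' @param eta Per-survey log-catchability; `eta[1]` must be exactly 0.
#' @param gamma Basis-coefficient matrix (terms x years), or `NULL`.
#' @param basis A [spatial_basis] matching `gamma`, or `NULL`.
#' @param cv Gamma coefficient of variation (> 0).
#' @param area_swept_lnorm `c(meanlog, sdlog)` of area swept in km².
#' @return A list of class `delta_gamma_truth`.
#' @export
delta_gamma_truth <- function(years, surveys, beta_n, beta_w,
                              eta = rep(0, length(surveys)), gamma = NULL,
                              basis = NULL, cv = 0.8,
                              area_swept_lnorm = c(log(0.05), 0.2)) {
  stopifnot(length(beta_n) == length(years), length(beta_w) == length(years),
            length(eta) == length(surveys))
  if (eta[1] != 0)
    stop_trawlcover("reference survey catchability must be exactly 0",
                    "parameter_error")
  if (!(cv > 0))
    stop_trawlcover("cv must be positive", "parameter_error")
  if (!is.null(gamma)) {
    stopifnot(is.matrix(gamma), ncol(gamma) == length(years))
    if (is.null(basis))
      stop_trawlcover("gamma supplied without a basis", "parameter_error")
  }
  structure(list(years = years, surveys = surveys,
                 beta_n = stats::setNames(beta_n, years),
                 beta_w = stats::setNames(beta_w, years),
                 eta = stats::setNames(eta, surveys),
                 gamma = gamma, basis = basis, cv = cv,
                 area_swept_lnorm = area_swept_lnorm),
            class = "delta_gamma_truth")
}

#' Expected numbers-density under a truth
#'
#' @param truth A [delta_gamma_truth].
#' @param lon,lat,year,survey_id Observation coordinates.
#' @return Expected numbers-density n (per km²).
#' @export
truth_density_n <- function(truth, lon, lat, year, survey_id) {
  t <- match(year, truth$years)
  s <- match(survey_id, truth$surveys)
  if (anyNA(t) || anyNA(s))
    stop_trawlcover("year or survey not present in truth", "parameter_error")
  spat <- if (!is.null(truth$gamma))
    rowSums(truth$basis(lon, lat) * t(truth$gamma)[t, , drop = FALSE])
  else 0
  exp(truth$beta_n[t] + spat + truth$eta[s])
}

#' Simulate catches from a delta-gamma truth
#'
#' For each haul, area swept is lognormal, expected numbers caught is
#' `mu = a * n`, the encounter probability is `p = 1 - exp(-mu)`, and a
#' positive catch is Gamma with mean `a * n * w / p` and the truth's CV.
#'
#' @param truth A [delta_gamma_truth].
#' @param hauls data.frame with `survey_id`, `lon`, `lat`, `year`; every
#'   haul's survey must be present in the truth.
#' @param seed Integer seed.
#' @return A catch data.frame (`survey_id`, `year`, `lon`, `lat`,
#'   `area_swept_km2`, `catch_kg`).
#' @export
gen_catches <- function(truth, hauls, seed) {
  if (!all(hauls$survey_id %in% truth$surveys))
    stop_trawlcover("haul survey missing from truth", "parameter_error")
  set.seed(seed)
  n_i <- truth_density_n(truth, hauls$lon, hauls$lat, hauls$year,
                         hauls$survey_id)
  a <- stats::rlnorm(nrow(hauls), truth$area_swept_lnorm[1],
                     truth$area_swept_lnorm[2])
  if (any(a <= 0))
    stop_trawlcover("non-positive area swept", "parameter_error")
  mu <- a * n_i
  p <- -expm1(-mu)
  w <- exp(truth$beta_w[match(hauls$year, truth$years)])
  enc <- stats::runif(nrow(hauls)) < p
  catch <- numeric(nrow(hauls))
  if (any(enc)) {
    r <- mu[enc] * w[enc] / p[enc]
    k <- 1 / truth$cv^2
    catch[enc] <- stats::rgamma(sum(enc), shape = k, scale = r / k)
  }
  data.frame(survey_id = hauls$survey_id, year = hauls$year,
             lon = hauls$lon, lat = hauls$lat,
             area_swept_km2 = a, catch_kg = catch,
             stringsAsFactors = FALSE)
}
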