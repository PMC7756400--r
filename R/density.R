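# Poisson-link delta-gamma catch model with per-survey catchability and a
# low-rank spatial basis.  For observation i with area swept a_i (km2):
#   log n_i = beta_n(t_i) + sum_b gamma_b(t_i) B_b(lon_i, lat_i) + eta(s_i)
#   p_i     = 1 - exp(-a_i n_i)                    (encounter probability)
#   r_i     = a_i n_i w_i / p_i,  log w_i = beta_w(t_i)  (positive-catch mean)
#   catch_i = 0 w.p. 1 - p_i, else Gamma(mean r_i, CV sigma)
# The reference survey's catchability is fixed at 0; density surfaces are
# n * w with catchability excluded, i.e. in the reference survey's gear scale.

#' Low-rank spatial basis
#'
#' A fixed basis over lon/lat standing in for spatial random fields: either
#' tensor-product quadratic polynomials (`"poly2"`, 8 non-constant terms) or
#' `K` Gaussian radial bases at supplied knots (`"rbf"`).  Coordinates are
#' rescaled to \[-1, 1\] over the bounding box fixed at construction, so basis
#' values are comparable across datasets.
#'
#' @param type `"poly2"` or `"rbf"`.
#' @param bbox Numeric `c(lon_min, lon_max, lat_min, lat_max)` fixing the
#'   scaling (and, for `"rbf"`, the default knot lattice).
#' @param knots Optional 2-column matrix of rbf knots (lon, lat).
#' @param rbf_scale Radial-basis length scale in scaled units.
#' @return A function `(lon, lat) -> matrix` with one column per basis term,
#'   carrying attribute `n_terms`.
#' @export
spatial_basis <- function(type = c("poly2", "rbf"), bbox, knots = NULL,
                          rbf_scale = 0.5) {
  type <- match.arg(type)
  stopifnot(length(bbox) == 4, bbox[2] > bbox[1], bbox[4] > bbox[3])
  sx <- function(lon) 2 * (lon - bbox[1]) / (bbox[2] - bbox[1]) - 1
  sy <- function(lat) 2 * (lat - bbox[3]) / (bbox[4] - bbox[3]) - 1
  if (type == "poly2") {
    f <- function(lon, lat) {
      x <- sx(lon); y <- sy(lat)
      cbind(x, y, x * y, x^2, y^2, x^2 * y, x * y^2, x^2 * y^2)
    }
    attr(f, "n_terms") <- 8L
  } else {
    if (is.null(knots)) {
      g <- expand.grid(lon = seq(bbox[1], bbox[2], length.out = 3),
                       lat = seq(bbox[3], bbox[4], length.out = 3))
      knots <- as.matrix(g)
    }
    kx <- sx(knots[, 1]); ky <- sy(knots[, 2])
    f <- function(lon, lat) {
      x <- sx(lon); y <- sy(lat)
      out <- vapply(seq_along(kx), function(k)
        exp(-((x - kx[k])^2 + (y - ky[k])^2) / (2 * rbf_scale^2)),
        numeric(length(x)))
      if (!is.matrix(out)) out <- matrix(out, nrow = length(x))
      out
    }
    attr(f, "n_terms") <- nrow(knots)
  }
  attr(f, "type") <- type
  attr(f, "bbox") <- bbox
  f
}

#' Validate catch observations
#'
#' @param obs data.frame with `survey_id`, `year`, `lon`, `lat`,
#'   `area_swept_km2` (> 0) and `catch_kg` (>= 0).
#' @return The validated data.frame.
#' @export
validate_catches <- function(obs) {
  need <- c("survey_id", "year", "lon", "lat", "area_swept_km2", "catch_kg")
  miss <- setdiff(need, names(obs))
  if (length(miss))
    stop_trawlcover(sprintf("missing catch column(s): %s",
                            paste(miss, collapse = ", ")), "schema_error")
  if (any(obs$area_swept_km2 <= 0, na.rm = TRUE))
    stop_trawlcover("area swept must be positive", "validation_error")
  if (any(obs$catch_kg < 0, na.rm = TRUE))
    stop_trawlcover("catches must be non-negative", "validation_error")
  obs
}

# parameter packing: theta = (beta_n[T], beta_w[T], eta[S-1], gamma[B*T], log_sigma)
dg_unpack <- function(theta, T_, S_, B_) {
  i <- 0
  bn <- theta[i + seq_len(T_)]; i <- i + T_
  bw <- theta[i + seq_len(T_)]; i <- i + T_
  eta <- if (S_ > 1) theta[i + seq_len(S_ - 1)] else numeric(0)
  i <- i + S_ - 1
  gam <- matrix(theta[i + seq_len(B_ * T_)], B_, T_); i <- i + B_ * T_
  list(bn = bn, bw = bw, eta = c(0, eta), gam = gam, log_sigma = theta[i + 1])
}

# negative log-likelihood and analytic gradient, shared environment
dg_nll_factory <- function(obs, Bmat, year_idx, surv_idx, T_, S_) {
  B_ <- ncol(Bmat)
  a <- obs$area_swept_km2
  c_ <- obs$catch_kg
  pos <- c_ > 0
  lc <- ifelse(pos, log(pmax(c_, 1e-300)), 0)
  n_par <- 2 * T_ + (S_ - 1) + B_ * T_ + 1
  common <- function(theta) {
    p <- dg_unpack(theta, T_, S_, B_)
    gam_i <- rowSums(Bmat * t(p$gam)[year_idx, , drop = FALSE])
    ell <- p$bn[year_idx] + gam_i + p$eta[surv_idx]
    mu <- a * exp(ell)
    penc <- -expm1(-mu)                       # 1 - exp(-mu), accurate
    list(p = p, ell = ell, mu = mu, penc = penc)
  }
  nll <- function(theta) {
    cm <- common(theta)
    k <- exp(-2 * cm$p$log_sigma)             # gamma shape = 1 / CV^2
    log_r <- log(cm$mu) + cm$p$bw[year_idx] - log(cm$penc)
    ll_zero <- -cm$mu[!pos]
    lp <- log(cm$penc[pos]); lr <- log_r[pos]
    ll_pos <- lp + k * log(k) - lgamma(k) - k * lr +
      (k - 1) * lc[pos] - k * c_[pos] / exp(lr)
    val <- -(sum(ll_zero) + sum(ll_pos))
    if (!is.finite(val)) val <- 1e10
    val
  }
  grad <- function(theta) {
    cm <- common(theta)
    p <- cm$p
    k <- exp(-2 * p$log_sigma)
    mu <- cm$mu; penc <- cm$penc
    log_r <- log(mu) + p$bw[year_idx] - log(penc)
    r <- exp(log_r)
    q <- mu * exp(-mu) / penc                 # d log p / d ell
    dL_dell <- numeric(length(mu))
    dL_dell[!pos] <- -mu[!pos]
    gshape <- (-k + k * c_[pos] / r[pos])     # d log f / d log r
    dL_dell[pos] <- q[pos] + gshape * (1 - q[pos])
    dL_dbw <- numeric(length(mu))
    dL_dbw[pos] <- gshape
    # d log f / d k, then d k / d log_sigma = -2k
    dldk <- -digamma(k) + log(k) + 1 - log_r[pos] + lc[pos] -
      c_[pos] / r[pos]
    g <- numeric(length(theta))
    i <- 0
    g[i + seq_len(T_)] <- tapply_sum(dL_dell, year_idx, T_); i <- i + T_
    g[i + seq_len(T_)] <- tapply_sum(dL_dbw, year_idx, T_); i <- i + T_
    if (S_ > 1) {
      by_s <- tapply_sum(dL_dell, surv_idx, S_)
      g[i + seq_len(S_ - 1)] <- by_s[-1]
      i <- i + S_ - 1
    }
    gmat <- matrix(0, ncol(Bmat), T_)
    for (t in seq_len(T_)) {
      sel <- year_idx == t
      if (any(sel))
        gmat[, t] <- colSums(Bmat[sel, , drop = FALSE] * dL_dell[sel])
    }
    g[i + seq_len(ncol(Bmat) * T_)] <- as.vector(gmat)
    i <- i + ncol(Bmat) * T_
    g[i + 1] <- sum(dldk) * (-2 * k)
    -g
  }
  list(nll = nll, grad = grad, n_par = n_par)
}

tapply_sum <- function(x, idx, n) {
  out <- numeric(n)
  s <- tapply(x, factor(idx, levels = seq_len(n)), sum)
  out[as.integer(names(s))] <- ifelse(is.na(s), 0, s)
  out[is.na(out)] <- 0
  out
}

#' Fit the Poisson-link delta-gamma model
#'
#' Maximum-likelihood fit of the catch model described above, by BFGS with
#' analytic gradients from moment-based starting values (year encounter rates
#' for numbers-density, mean positive catch for weight).  Catchability enters
#' the numbers-density predictor; the Gamma distribution is parameterized by
#' mean and a CV shared across years and surveys.
#'
#' @param obs Catch observations (see [validate_catches]).
#' @param basis A [spatial_basis]; `NULL` fits a spatially constant model.
#' @param reference_survey Survey whose catchability is fixed at 0; default
#'   the first survey id in sort order.
#' @param cfg List of optimizer settings: `maxit` (default 1000), `gtol`
#'   (gradient-norm convergence check, default 1e-6), `hessian` (compute
#'   standard errors, default TRUE).
#' @return An object of class `delta_gamma_model` with per-year effects
#'   (`beta_n`, `beta_w`), per-survey `eta`, basis coefficients `gamma`
#'   (terms x years), `cv`, `loglik`, `convergence` diagnostics and standard
#'   errors (`se` carries the same packing as the parameter vector).
#' @export
fit_delta_gamma <- function(obs, basis = NULL, reference_survey = NULL,
                            cfg = list()) {
  obs <- validate_catches(obs)
  if (all(obs$catch_kg == 0))
    stop_trawlcover("all catches are zero: no information", "no_information")
  years <- sort(unique(obs$year))
  if (length(years) < 2)
    stop_trawlcover("need at least 2 years", "validation_error")
  surveys <- sort(unique(obs$survey_id))
  if (is.null(reference_survey)) reference_survey <- surveys[1]
  if (!reference_survey %in% surveys)
    stop_trawlcover("reference survey has no observations", "linkage_error")
  surveys <- c(reference_survey, setdiff(surveys, reference_survey))
  year_idx <- match(obs$year, years)
  surv_idx <- match(obs$survey_id, surveys)
  pos <- obs$catch_kg > 0
  flagged <- years[!(years %in% obs$year[pos]) |
                     !(years %in% obs$year[!pos])]
  Bmat <- if (is.null(basis)) matrix(0, nrow(obs), 0)
          else basis(obs$lon, obs$lat)
  T_ <- length(years); S_ <- length(surveys); B_ <- ncol(Bmat)
  f <- dg_nll_factory(obs, Bmat, year_idx, surv_idx, T_, S_)
  # moment initializers
  mean_a <- mean(obs$area_swept_km2)
  enc_t <- tapply(pos, year_idx, mean)
  enc_t <- pmin(pmax(as.numeric(enc_t), 0.02), 0.98)
  bn0 <- log(-log(1 - enc_t) / mean_a)
  wpos_t <- tapply(ifelse(pos, obs$catch_kg, NA), year_idx,
                   function(x) mean(x, na.rm = TRUE))
  wpos_t[is.na(wpos_t)] <- mean(obs$catch_kg[pos])
  mu0 <- mean_a * exp(bn0)
  bw0 <- log(as.numeric(wpos_t) * (-expm1(-mu0)) / mu0)
  theta0 <- c(bn0, bw0, rep(0, S_ - 1), rep(0, B_ * T_), log(0.8))
  ctl <- list(maxit = cfg$maxit %||% 1000, reltol = 1e-12)
  opt <- stats::optim(theta0, f$nll, f$grad, method = "BFGS", control = ctl)
  gnorm <- sqrt(sum(f$grad(opt$par)^2))
  converged <- opt$convergence == 0 &&
    gnorm < (cfg$gtol %||% 1e-6) * max(1, abs(opt$value))
  se <- rep(NA_real_, f$n_par)
  vcov <- NULL
  if (isTRUE(cfg$hessian %||% TRUE)) {
    H <- stats::optimHess(opt$par, f$nll, f$grad)
    vc <- try(solve(H), silent = TRUE)
    if (!inherits(vc, "try-error") && all(diag(vc) > 0)) {
      vcov <- vc
      se <- sqrt(diag(vc))
    }
  }
  est <- dg_unpack(opt$par, T_, S_, B_)
  ses <- dg_unpack(se, T_, S_, B_)
  ses$eta[1] <- 0
  structure(list(
    years = years, surveys = surveys, reference_survey = reference_survey,
    beta_n = stats::setNames(est$bn, years),
    beta_w = stats::setNames(est$bw, years),
    eta = stats::setNames(est$eta, surveys),
    gamma = est$gam, cv = exp(est$log_sigma),
    basis = basis, flagged_years = flagged,
    loglik = -opt$value, convergence = converged, gradient_norm = gnorm,
    se = list(beta_n = stats::setNames(ses$bn, years),
              beta_w = stats::setNames(ses$bw, years),
              eta = stats::setNames(ses$eta, surveys),
              gamma = ses$gam, log_sigma = ses$log_sigma),
    par = opt$par, vcov = vcov, n_obs = nrow(obs)),
    class = "delta_gamma_model")
  }

#' @export
print.delta_gamma_model <- function(x, ...) {
  cat(sprintf(
    "delta_gamma_model: %d obs, %d years, %d surveys (ref %s)\n",
    x$n_obs, length(x$years), length(x$surveys), x$reference_survey))
  cat(sprintf("  logLik %.2f, CV %.3f, converged: %s\n",
              x$loglik, x$cv, x$convergence))
  if (length(x$flagged_years))
    cat("  years without both encounters and zeros:",
        paste(x$flagged_years, collapse = ", "), "\n")
  invisible(x)
}

#' Predict a density surface
#'
#' Evaluates `d = n * w` (kg/km²) at every cell center of the grid for one
#' fitted year, with catchability excluded: densities are expressed in the
#' reference survey's gear scale and are survey-free.
#'
#' @param model A fitted [fit_delta_gamma] model.
#' @param spec Target [grid_spec].
#' @param year A fitted year.
#' @return An object of class `density_surface`: a kg/km² [grid_layer] plus
#'   `year` and `mask_frac` (0 = unmasked).
#' @export
predict_density <- function(model, spec, year) {
  t <- match(year, model$years)
  if (is.na(t))
    stop_trawlcover(sprintf("year %s was not fitted", year), "parameter_error")
  cc <- cell_centers(spec)
  spat <- if (!is.null(model$basis) && ncol(model$gamma) >= t &&
              nrow(model$gamma) > 0)
    as.vector(model$basis(cc$lon, cc$lat) %*% model$gamma[, t])
  else 0
  d <- exp(model$beta_n[[t]] + spat + model$beta_w[[t]])
  layer <- grid_layer(spec, matrix(d, spec$nrows, spec$ncols),
                      units = "kg/km2")
  structure(list(layer = layer, year = year, mask_frac = 0),
            class = "density_surface")
}

#' @export
print.density_surface <- function(x, ...) {
  v <- x$layer$values
  cat(sprintf(
    "density_surface %s: %d cells, %d masked, max %.3g kg/km2\n",
    x$year, length(v), sum(is.na(v)), max(v, na.rm = TRUE)))
  invisible(x)
}

#' Mask low densities
#'
#' Masks cells at or below `frac` of the surface maximum (default 0.1%),
#' separating occupied from essentially unoccupied area; masked cells become
#' `NA`, never silently zeroed, and the maximum cell always survives.
#'
#' @param surface A [predict_density] surface.
#' @param frac Mask fraction of the maximum.
#' @return A masked `density_surface` with `mask_frac` recorded.
#' @export
mask_low_density <- function(surface, frac = 0.001) {
  v <- surface$layer$values
  mx <- max(v, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0)
    stop_trawlcover("surface has no positive density", "validation_error")
  v[v <= frac * mx & v < mx] <- NA
  structure(list(layer = grid_layer(surface$layer$spec, v, "kg/km2"),
                 year = surface$year, mask_frac = frac),
            class = "density_surface")
}

#' Center of gravity of a density surface
#'
#' Density-weighted centroid over unmasked cells, weighting each cell by its
#' density times its spherical cell area.  Against a reference (typically the
#' first year) the haversine great-circle displacement (km), bearing, and the
#' relative (delta lon, delta lat) convention are reported.
#'
#' @param surface A `density_surface`.
#' @param reference Optional `center_of_gravity` to compute displacement from.
#' @return An object of class `center_of_gravity`: `year`, `lon`, `lat`, and
#'   (with a reference) `displacement_km`, `bearing_deg`, `dlon`, `dlat`.
#' @export
center_of_gravity <- function(surface, reference = NULL) {
  v <- surface$layer$values
  ok <- !is.na(v) & v > 0
  if (!any(ok))
    stop_trawlcover("no unmasked positive density", "validation_error")
  w <- v * cell_areas_km2(surface$layer$spec)
  w[!ok] <- 0
  cc <- cell_centers(surface$layer$spec)
  W <- sum(w)
  lon <- sum(cc$lon * as.vector(w)) / W
  lat <- sum(cc$lat * as.vector(w)) / W
  out <- list(year = surface$year, lon = lon, lat = lat,
              displacement_km = NA_real_, bearing_deg = NA_real_,
              dlon = NA_real_, dlat = NA_real_)
  if (!is.null(reference)) {
    out$displacement_km <- geosphere::distHaversine(
      c(reference$lon, reference$lat), c(lon, lat),
      r = .mean_radius_km * 1000) / 1000
    out$bearing_deg <- geosphere::bearing(
      c(reference$lon, reference$lat), c(lon, lat))
    out$dlon <- lon - reference$lon
    out$dlat <- lat - reference$lat
  }
  structure(out, class = "center_of_gravity")
}

#' @export
print.center_of_gravity <- function(x, ...) {
  cat(sprintf("center_of_gravity %s: (%.4f, %.4f)", x$year, x$lon, x$lat))
  if (!is.na(x$displacement_km))
    cat(sprintf("; %.1f km at bearing %.0f deg from reference",
                x$displacement_km, x$bearing_deg))
  cat("\n")
  invisible(x)
}

#' Center-of-gravity track across fitted years
#'
#' @param model A fitted [fit_delta_gamma] model.
#' @param spec Prediction [grid_spec].
#' @param mask_frac Density mask applied before the centroid (0 = none, the
#'   default; the masked variant is available for map-consistent tracks).
#' @param domain Optional survey-domain restriction (anything
#'   [rasterize_polygons] accepts, or a logical [grid_layer] on `spec`):
#'   cells outside it are excluded.  The model interpolates within the
#'   combined survey domain; it is not meant to extrapolate beyond it.
#' @return data.frame with year, lon, lat, displacement_km, bearing_deg,
#'   dlon, dlat (relative to the first year).
#' @export
cog_track <- function(model, spec, mask_frac = 0, domain = NULL) {
  dom <- if (is.null(domain)) NULL
         else if (inherits(domain, "grid_layer")) domain
         else rasterize_polygons(domain, spec)
  ref <- NULL
  rows <- lapply(model$years, function(y) {
    s <- predict_density(model, spec, y)
    if (!is.null(dom)) {
      v <- s$layer$values
      v[!dom$values] <- NA
      s$layer <- grid_layer(spec, v, s$layer$units)
    }
    if (mask_frac > 0) s <- mask_low_density(s, mask_frac)
    cg <- center_of_gravity(s, ref)
    if (is.null(ref)) {
      ref <<- cg
      cg <- center_of_gravity(s, ref)  # zero displacement to itself
    }
    data.frame(year = y, lon = cg$lon, lat = cg$lat,
               displacement_km = cg$displacement_km,
               bearing_deg = cg$bearing_deg, dlon = cg$dlon, dlat = cg$dlat)
  })
  do.call(rbind, rows)
}
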