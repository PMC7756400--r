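# small simulated dataset shared by several blocks
dg_sim <- function(seed = 3, n_per = 200, years = 2001:2004,
                   surveys = c("A", "B"), eta = c(0, 0.4), basis = NULL,
                   gamma = NULL, beta_n = NULL, cv = 0.7) {
  set.seed(seed)
  if (is.null(beta_n)) beta_n <- seq(2.6, 3.2, length.out = length(years))
  truth <- delta_gamma_truth(
    years = years, surveys = surveys, beta_n = beta_n,
    beta_w = rep(-1, length(years)), eta = eta, gamma = gamma,
    basis = basis, cv = cv)
  hauls <- do.call(rbind, lapply(surveys, function(s)
    do.call(rbind, lapply(years, function(y)
      data.frame(survey_id = s, year = y, lon = runif(n_per, 0, 4),
                 lat = runif(n_per, 50, 54))))))
  list(truth = truth, catches = gen_catches(truth, hauls, seed = seed + 1))
}

test_that("catch observations are validated", {
  ok <- data.frame(survey_id = "A", year = 2001, lon = 0, lat = 50,
                   area_swept_km2 = 0.05, catch_kg = 1)
  expect_identical(validate_catches(ok), ok)
  expect_error(validate_catches(ok[, -5]), class = "schema_error")
  expect_error(validate_catches(transform(ok, area_swept_km2 = 0)),
               class = "validation_error")
  expect_error(validate_catches(transform(ok, catch_kg = -1)),
               class = "validation_error")
})

test_that("the Poisson link maps density to (0,1) with the right limits", {
  an <- 10^seq(-8, 1.4, length.out = 40)
  p <- -expm1(-an)
  expect_true(all(p > 0 & p < 1))
  expect_equal(p[an < 1e-6] / an[an < 1e-6], rep(1, sum(an < 1e-6)),
               tolerance = 1e-5)
  expect_equal(-expm1(-c(100, 1e4)), c(1, 1))
})

test_that("analytic likelihood gradient matches numerical differentiation", {
  skip_if_not_installed("pracma")
  sim <- dg_sim(seed = 8, n_per = 60, years = 2001:2002,
                basis = spatial_basis("poly2", c(0, 4, 50, 54)),
                gamma = matrix(rnorm(16, 0, 0.2), 8, 2))
  obs <- sim$catches
  years <- sort(unique(obs$year)); surveys <- c("A", "B")
  basis <- spatial_basis("poly2", c(0, 4, 50, 54))
  f <- trawlcover:::dg_nll_factory(
    obs, basis(obs$lon, obs$lat), match(obs$year, years),
    match(obs$survey_id, surveys), length(years), length(surveys))
  set.seed(2)
  theta <- rnorm(f$n_par, 0, 0.3)
  theta[2 * 2 + 1 + 8 * 2 + 1] <- log(0.8)
  g_num <- pracma::grad(f$nll, theta, heps = 1e-6)
  expect_equal(f$grad(theta), g_num, tolerance = 1e-4)
})

test_that("year effects and catchability are recovered from simulation", {
  sim <- dg_sim(seed = 3, n_per = 400)
  fit <- fit_delta_gamma(sim$catches, reference_survey = "A")
  expect_true(fit$convergence)
  expect_equal(fit$eta[["A"]], 0)
  z_bn <- (fit$beta_n - sim$truth$beta_n) / fit$se$beta_n
  z_bw <- (fit$beta_w - sim$truth$beta_w) / fit$se$beta_w
  z_eta <- (fit$eta[-1] - sim$truth$eta[-1]) / fit$se$eta[-1]
  expect_true(all(abs(c(z_bn, z_bw, z_eta)) < 3))
  expect_gt(fit$cv, 0)
})

test_that("identical-gear truth yields catchability near zero", {
  sim <- dg_sim(seed = 12, n_per = 400, eta = c(0, 0))
  fit <- fit_delta_gamma(sim$catches, reference_survey = "A")
  expect_lt(abs(fit$eta[["B"]]), 3 * fit$se$eta[["B"]])
})

test_that("constant model matches the encounter-rate moment solution", {
  sim <- dg_sim(seed = 5, n_per = 1200, years = 2001:2002,
                surveys = "A", eta = 0)
  obs <- sim$catches
  fit <- fit_delta_gamma(obs, reference_survey = "A", cfg = list(hessian = FALSE))
  for (t in 1:2) {
    sel <- obs$year == sort(unique(obs$year))[t]
    p_hat <- mean(-expm1(-obs$area_swept_km2[sel] *
                           exp(fit$beta_n[[t]])))
    expect_equal(p_hat, mean(obs$catch_kg[sel] > 0), tolerance = 0.02)
  }
})

test_that("density prediction evaluates the fitted formula cell by cell", {
  gs <- grid_spec(0, 50, 0.5, 0.5, 8, 8)
  sim <- dg_sim(seed = 9, n_per = 150, years = 2001:2002)
  fit <- fit_delta_gamma(sim$catches, cfg = list(hessian = FALSE))
  s <- predict_density(fit, gs, 2001)
  # constant model: flat surface at exp(beta_n + beta_w)
  expect_equal(as.vector(s$layer$values),
               rep(exp(fit$beta_n[[1]] + fit$beta_w[[1]]), 64))
  expect_error(predict_density(fit, gs, 1999), class = "parameter_error")

  # linear-in-latitude basis with positive coefficient: increases northward
  basis <- spatial_basis("rbf", c(0, 4, 50, 54),
                         knots = cbind(2, c(50, 54)), rbf_scale = 5)
  m <- fit
  m$basis <- function(lon, lat) cbind(0 * lon, (lat - 52) / 4)
  m$gamma <- matrix(c(0, 2), 2, 2)
  s2 <- predict_density(m, gs, 2001)
  expect_true(all(apply(s2$layer$values, 2, function(col) all(diff(col) > 0))))
  # cell values equal direct formula evaluation
  cc <- cell_centers(gs)
  want <- exp(m$beta_n[[1]] + 2 * (cc$lat - 52) / 4 + m$beta_w[[1]])
  expect_equal(as.vector(s2$layer$values), want)
})

test_that("low-density masking keeps the maximum and thresholds the rest", {
  gs <- grid_spec(0, 50, 1, 1, 4, 4)
  flat <- structure(list(layer = grid_layer(gs, matrix(2, 4, 4), "kg/km2"),
                         year = 2001, mask_frac = 0),
                    class = "density_surface")
  expect_equal(sum(is.na(mask_low_density(flat)$layer$values)), 0)
  v <- matrix(1e-6, 4, 4); v[2, 3] <- 1
  dom <- structure(list(layer = grid_layer(gs, v, "kg/km2"), year = 2001,
                        mask_frac = 0), class = "density_surface")
  masked <- mask_low_density(dom)
  expect_equal(sum(!is.na(masked$layer$values)), 1)
  expect_equal(masked$layer$values[2, 3], 1)
  set.seed(4)
  v2 <- matrix(rexp(16), 4, 4)
  rnd <- structure(list(layer = grid_layer(gs, v2, "kg/km2"), year = 2001,
                        mask_frac = 0), class = "density_surface")
  out <- mask_low_density(rnd, frac = 0.2)
  expect_equal(is.na(out$layer$values),
               v2 <= 0.2 * max(v2) & v2 < max(v2))
  zero <- structure(list(layer = grid_layer(gs, matrix(0, 4, 4), "kg/km2"),
                         year = 2001, mask_frac = 0),
                    class = "density_surface")
  expect_error(mask_low_density(zero), class = "validation_error")
})

test_that("center of gravity reduces to symmetry centers", {
  gs <- grid_spec(0, 50, 0.5, 0.5, 8, 8)
  one <- matrix(0, 8, 8); one[3, 5] <- 7
  s1 <- structure(list(layer = grid_layer(gs, one, "kg/km2"), year = 2001,
                       mask_frac = 0), class = "density_surface")
  cg1 <- center_of_gravity(s1)
  expect_equal(c(cg1$lon, cg1$lat), c(0 + 4.5 * 0.5, 50 + 2.5 * 0.5))
  expect_equal(center_of_gravity(s1, cg1)$displacement_km, 0)
  # two equal cells on one parallel: centroid at the midpoint longitude
  two <- matrix(0, 8, 8); two[4, c(2, 7)] <- 3
  s2 <- structure(list(layer = grid_layer(gs, two, "kg/km2"), year = 2001,
                       mask_frac = 0), class = "density_surface")
  cg2 <- center_of_gravity(s2)
  expect_equal(cg2$lon, (0.75 + 3.25) / 2)
  expect_equal(cg2$lat, 51.75)
  expect_error(center_of_gravity(
    structure(list(layer = grid_layer(gs, matrix(0, 8, 8), "kg/km2"),
                   year = 2001, mask_frac = 0), class = "density_surface")),
    class = "validation_error")
})

test_that("center-of-gravity drift recovery tracks a known northward shift", {
  gs <- grid_spec(0, 50, 0.1, 0.1, 40, 80)
  cc <- cell_centers(gs)
  mk <- function(lat0) {
    v <- exp(-((cc$lon - 2)^2 + (cc$lat - lat0)^2) / (2 * 0.6^2))
    structure(list(layer = grid_layer(gs, matrix(v, 80, 40), "kg/km2"),
                   year = lat0, mask_frac = 0), class = "density_surface")
  }
  lats <- 52 + 0.5 * (0:4)   # 0.5 degrees north per year
  cogs <- lapply(lats, function(l) center_of_gravity(mk(l)))
  for (i in 2:5) {
    d <- center_of_gravity(mk(lats[i]), cogs[[i - 1]])
    want <- geosphere::distHaversine(c(2, lats[i - 1]), c(2, lats[i]),
                                     r = 6371008.8) / 1000
    expect_lt(abs(d$displacement_km - want) / want, 0.05)
    expect_lt(abs(d$bearing_deg), 2)  # due north
  }
})

test_that("relabeling the reference survey only rescales densities", {
  sim <- dg_sim(seed = 21, n_per = 300, years = 2001:2002)
  fit_a <- fit_delta_gamma(sim$catches, reference_survey = "A",
                           cfg = list(hessian = FALSE))
  fit_b <- fit_delta_gamma(sim$catches, reference_survey = "B",
                           cfg = list(hessian = FALSE))
  gs <- grid_spec(0, 50, 1, 1, 4, 4)
  da <- predict_density(fit_a, gs, 2001)$layer$values
  db <- predict_density(fit_b, gs, 2001)$layer$values
  # reparameterization invariance: surfaces agree after the catchability
  # offset of the new reference is divided back out
  expect_equal(db * exp(fit_b$eta[["A"]]), da, tolerance = 1e-3)
  expect_equal(fit_b$eta[["A"]], -fit_a$eta[["B"]], tolerance = 1e-3)
})

test_that("the likelihood prefers the truth over perturbations on average", {
  set.seed(31)
  diffs <- replicate(12, {
    seed <- sample.int(1e6, 1)
    sim <- dg_sim(seed = seed, n_per = 120, years = 2001:2002)
    obs <- sim$catches
    years <- sort(unique(obs$year))
    f <- trawlcover:::dg_nll_factory(
      obs, matrix(0, nrow(obs), 0), match(obs$year, years),
      match(obs$survey_id, c("A", "B")), 2, 2)
    th_true <- c(sim$truth$beta_n, sim$truth$beta_w, sim$truth$eta[2],
                 log(sim$truth$cv))
    f$nll(th_true + rnorm(length(th_true), 0, 0.3)) - f$nll(th_true)
  })
  expect_gt(mean(diffs), 0)
})

test_that("degenerate catch data is rejected with informative errors", {
  obs <- data.frame(survey_id = "A", year = rep(2001:2002, each = 5),
                    lon = 0, lat = 50, area_swept_km2 = 0.05, catch_kg = 0)
  expect_error(fit_delta_gamma(obs), class = "no_information")
  obs$catch_kg <- 1
  obs1 <- obs[obs$year == 2001, ]
  expect_error(fit_delta_gamma(obs1), class = "validation_error")
})
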