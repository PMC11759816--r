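# Isotope standardization chains, environmental interpolation and the
# two-stage kriging isoscape, with a closed-form Gaussian-process oracle.

test_that("VPDB standardization returns nominal values at the reference ratio", {
  expect_equal(delta_vpdb(1, 1, 1.95), 1.95)
  expect_equal(delta_vpdb(1, 1, -2.20), -2.20)
  expect_equal(delta_vpdb(2, 2, 0), 0)
  expect_error(delta_vpdb(-1, 1, 0), "positive")
  expect_error(delta_vpdb(1, 0, 0), "positive")
  # chain with a non-reference ratio: hand computation
  d_sn <- 1000 * (1 - 0.999)
  expect_equal(delta_vpdb(0.999, 1, 1.95),
               ((d_sn / 1000 + 1) * (1.95 / 1000 + 1) - 1) * 1000)
})

test_that("SMOW to VPDB conversion is the printed affine map", {
  expect_equal(smow_to_vpdb(0), -29.94)
  expect_equal(smow_to_vpdb(29.94 / 0.97006), 0, tolerance = 1e-12)
  a <- 3.2; b <- -1.7
  expect_equal(smow_to_vpdb(a) + smow_to_vpdb(b) - smow_to_vpdb(0),
               smow_to_vpdb(a + b), tolerance = 1e-12)
  expect_equal(vpdb_to_smow(smow_to_vpdb(a)), a, tolerance = 1e-12)
})

test_that("scale flags prevent double conversion", {
  obs <- data.frame(d18O = c(0, 1), scale = c("SMOW", "VPDB"))
  out <- convert_water_obs(obs)
  expect_equal(out$d18O, c(-29.94, 1))
  expect_equal(convert_water_obs(out)$d18O, out$d18O)  # idempotent once VPDB
  expect_error(convert_water_obs(data.frame(d18O = 1)), "scale")
  expect_error(convert_water_obs(data.frame(d18O = 1, scale = "PDB")), "unknown")
})

test_that("environmental interpolation recovers planar fields exactly", {
  set.seed(40)
  strata <- make_strata(c(0, 100))
  obs <- data.frame(lon = runif(25, -30, -20), lat = runif(25, -62, -55),
                    depth = 50)
  obs$value <- 2 + 0.5 * obs$lon - 0.25 * obs$lat
  fld <- interpolate_env(obs, "temperature", lon = seq(-30, -20, 2),
                         lat = seq(-62, -55, 1), strata = strata)
  # exactness at observation sites (the plane is in the trend space)
  grid <- expand.grid(lon = fld$lon, lat = fld$lat)
  truth <- 2 + 0.5 * grid$lon - 0.25 * grid$lat
  expect_equal(as.vector(fld$values[, , 1]), truth, tolerance = 1e-6)
  expect_lt(attr(fld, "loo_rmse")[1], 1e-6)
})

test_that("single-observation strata give constant fields with a warning", {
  strata <- make_strata(c(0, 50, 100))
  obs <- data.frame(lon = c(-25, -24, -26, -25.5), lat = c(-60, -59, -58, -60.5),
                    depth = c(10, 20, 30, 75), value = c(1, 2, 3, 9))
  expect_warning(
    fld <- interpolate_env(obs, "salinity", lon = c(-26, -24), lat = c(-60, -58),
                           strata = strata),
    "single")
  expect_true(all(fld$values[, , 2] == 9))
})

test_that("interpolation error stays near the noise floor on a smooth field", {
  set.seed(41)
  strata <- make_strata(c(0, 100))
  obs <- data.frame(lon = runif(80, -30, -20), lat = runif(80, -62, -55),
                    depth = 50)
  truth <- sin(obs$lon / 2) + cos(obs$lat / 3)
  noise_sd <- 0.05
  obs$value <- truth + rnorm(80, 0, noise_sd)
  fld <- interpolate_env(obs, "temperature", lon = seq(-30, -20, 1),
                         lat = seq(-62, -55, 1), strata = strata)
  expect_lt(attr(fld, "loo_rmse")[1], 1.5 * (noise_sd + 0.05))
})

test_that("kriging matches the closed-form GP posterior on three points", {
  # hand-specified exponential covariance, no covariates
  olon <- c(-25, -24, -23); olat <- c(-60, -59.5, -60.5)
  y <- c(0.4, -0.2, 0.1)
  range_km <- 150; sill <- 0.3; nugget <- 0.05
  plon <- c(-24.5, -26); plat <- c(-60, -59)
  kr <- krige_exp(olon, olat, y, plon, plat, range_km, sill, nugget)
  # oracle: conditional mean/variance of a joint multivariate normal
  D <- gc_dist_matrix(c(olon, plon), c(olat, plat))
  K <- sill * exp(-D / range_km)
  Koo <- K[1:3, 1:3] + diag(nugget, 3)
  Kop <- K[1:3, 4:5]
  mu <- drop(t(Kop) %*% solve(Koo) %*% y)
  v <- sill - diag(t(Kop) %*% solve(Koo) %*% Kop)
  expect_equal(kr$mean, mu, tolerance = 1e-8)
  expect_equal(kr$var, v, tolerance = 1e-8)
})

test_that("kriging interpolates exactly with zero nugget", {
  set.seed(42)
  olon <- runif(12, -30, -20); olat <- runif(12, -62, -55)
  y <- rnorm(12)
  kr <- krige_exp(olon, olat, y, olon, olat, range_km = 200, sill = 1, nugget = 0)
  expect_equal(kr$mean, y, tolerance = 1e-6)
  expect_true(all(kr$var < 1e-6))
})

test_that("prediction variance grows monotonically away from the data", {
  kr <- krige_exp(-25, -60, 1, seq(-25, -15, 1), rep(-60, 11),
                  range_km = 100, sill = 1, nugget = 0.1)
  expect_true(all(diff(kr$var) >= -1e-12))
  expect_true(all(kr$var >= 0))
})

test_that("gp_ml recovers covariance parameters on a dense draw", {
  set.seed(43)
  n <- 120
  lon <- runif(n, -30, -20); lat <- runif(n, -62, -55)
  D <- gc_dist_matrix(lon, lat)
  K <- 0.5 * exp(-D / 120) + diag(0.05, n)
  y <- drop(crossprod(chol(K), rnorm(n)))
  fit <- gp_ml(lon, lat, y)
  expect_gt(fit$sill, 0.1); expect_lt(fit$sill, 2)
  expect_gt(fit$range_km, 30); expect_lt(fit$range_km, 500)
})

test_that("fit_isoscape validates inputs and reports sane diagnostics", {
  set.seed(44)
  sim <- sim_dataset(sim_scenario(seed = 44, n_water_obs = 220))
  expect_error(fit_isoscape(sim$env$water_obs[1:10, ], sim$env$temperature,
                            sim$env$salinity), "30")
  iso <- suppressWarnings(
    fit_isoscape(sim$env$water_obs, sim$env$temperature, sim$env$salinity))
  expect_true(all(iso$sd >= 0, na.rm = TRUE))
  expect_gt(iso$diagnostics$deviance_explained, 0.3)
  expect_lt(iso$diagnostics$deviance_explained, 0.95)
  expect_equal(dim(iso$mean), c(20, 20, 6))
  # prediction roughly reproduces a held observation's neighbourhood value
  o <- convert_water_obs(sim$env$water_obs)[1, ]
  k <- stratum_of_depth(o$depth, iso$strata)
  i <- which.min(abs(iso$lon - o$lon)); j <- which.min(abs(iso$lat - o$lat))
  expect_lt(abs(iso$mean[i, j, k] - o$d18O), 1)
  # year filter reduces the observation count actually used
  iso_w <- suppressWarnings(
    fit_isoscape(sim$env$water_obs, sim$env$temperature, sim$env$salinity,
                 year_window = c(1989, 2002)))
  expect_lt(iso_w$diagnostics$n_obs, iso$diagnostics$n_obs)
})
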