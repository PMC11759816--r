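# Fractionation predictions, capture-site averaging, bias testing, Monte-Carlo
# expected distributions, occurrence probabilities, synoptic maps, area
# summaries and top-percentile origin regions.

test_that("the fractionation equation evaluates exactly", {
  eq <- fractionation_equation()
  expect_equal(predict_oto(eq, 0, 0), 4.64)
  expect_equal(predict_oto(eq, 10, 0), 2.54)
  expect_equal(predict_oto(eq, 3, 2) - predict_oto(eq, 3, 1), 1)  # unit water coef
})

test_that("capture-site averaging windows cells and strata correctly", {
  iso <- toy_isoscape(water_mean = 2, temp = 1)
  ex <- capture_site_expectation(iso, -29, -59, 100, radius_km = 100)
  expect_equal(ex$d18O_water, 2)
  expect_equal(ex$temperature, 1)

  # radius below grid spacing degrades to the nearest cell
  vals <- array(seq_len(18), c(3, 3, 2))
  iso2 <- toy_isoscape(water_mean = vals, temp = vals)
  ex2 <- capture_site_expectation(iso2, -29.9, -59.9, 50, radius_km = 1)
  expect_equal(ex2$n_cells, 1)
  expect_equal(ex2$d18O_water, vals[1, 1, 1])

  # hand-built 3-cell neighbourhood with values 1, 2, 3 in one stratum
  vals3 <- array(NA_real_, c(3, 3, 2))
  vals3[, 1, 1] <- c(1, 2, 3)
  iso3 <- toy_isoscape(water_mean = vals3, temp = vals3)
  ex3 <- capture_site_expectation(iso3, -29, -60, 50, radius_km = 200,
                                  layer_m = 100)
  expect_equal(ex3$d18O_water, 2)
})

test_that("bias test is unbiased for the generating equation and shifts exactly", {
  set.seed(50)
  iso <- toy_isoscape(lon = seq(-30, -26, 1), lat = seq(-61, -57, 1),
                      water_mean = -0.8, temp = 1.5)
  eq <- fractionation_equation(residual_sd = 0.1)
  n <- 12
  fish <- data.frame(fish_id = sprintf("F%d", 1:n),
                     capture_lon = runif(n, -30, -26),
                     capture_lat = runif(n, -61, -57),
                     capture_depth = 100)
  edge <- data.frame(fish_id = fish$fish_id,
                     d18O = predict_oto(eq, 1.5, -0.8) + rnorm(n, 0, 0.1))
  eq_shift <- fractionation_equation("shifted", intercept = 4.64 + 0.5,
                                     residual_sd = 0.1)
  rep <- bias_test(list(thorrold = eq, shifted = eq_shift), edge, fish, iso)
  b <- rep$mean_bias[rep$equation == "thorrold"]
  expect_lt(abs(b), 2 * 0.1 / sqrt(n))
  expect_equal(rep$mean_bias[rep$equation == "shifted"], b - 0.5,
               tolerance = 1e-12)
  expect_equal(rep$equation[1], "thorrold")  # ranked by |mean bias|

  fish$capture_lon[1] <- NA
  rep2 <- bias_test(list(thorrold = eq), edge, fish, iso)
  expect_equal(rep2$n_fish, n - 1)
  expect_error(bias_test(list(e = eq), edge[1:4, ], fish[1:4, ], iso), "5")
})

test_that("expected distributions degenerate and converge as specified", {
  iso <- toy_isoscape(water_mean = -1, temp = 2)
  eq0 <- fractionation_equation(residual_sd = 0)
  d0 <- expected_distribution(iso, eq0, -29, -59, 1, n_mc = 2000, seed = 1)
  expect_true(all(d0$mc_samples == predict_oto(eq0, 2, -1)))

  isov <- toy_isoscape(water_mean = -1, water_sd = 0.3, temp = 2)
  dv <- expected_distribution(isov, eq0, -29, -59, 1, n_mc = 5000, seed = 2)
  expect_lt(abs(sd(dv$mc_samples) - 0.3) / 0.3, 0.05)

  d1 <- expected_distribution(isov, eq0, -29, -59, 1, n_mc = 1000, seed = 9)
  d2 <- expected_distribution(isov, eq0, -29, -59, 1, n_mc = 1000, seed = 9)
  expect_identical(d1$mc_samples, d2$mc_samples)
})

test_that("occurrence probability is a calibrated two-sided tail", {
  iso <- toy_isoscape(water_mean = 4, water_sd = 0.3, temp = 0)
  eq <- fractionation_equation(intercept = 0, temp_slope = 0, residual_sd = 0)
  d <- expected_distribution(iso, eq, -29, -59, 1, n_mc = 50000, seed = 3)
  # at the Monte-Carlo median the probability is 1
  expect_equal(occurrence_probability(median(d$mc_samples), d), 1,
               tolerance = 2e-3)
  # far outside all draws it collapses to ~0
  expect_lt(occurrence_probability(10, d), 1e-3)
  # draws ~ N(4, 0.3^2), observed 4.3: analytic two-sided tail 2(1 - Phi(1))
  p <- occurrence_probability(4.3, d)
  expect_lt(abs(p - 2 * (1 - pnorm(1))), 0.02)
  # likelihood variant: normalised to 1 at the mode
  pl <- occurrence_probability(4, d, method = "likelihood")
  expect_gt(pl, 0.99)
  expect_error(occurrence_probability(1, list(mc_samples = rnorm(10))), "1000")
})

test_that("synoptic maps average fish and floor zero probabilities", {
  iso <- toy_isoscape(water_mean = 4, water_sd = 0.2, temp = 0)
  eq <- fractionation_equation(intercept = 0, temp_slope = 0, residual_sd = 0)
  obs <- data.frame(fish_id = c("a", "b"), d18O = c(4.0, 4.2))
  om <- occurrence_maps(iso, eq, obs, n_mc = 2000, seed = 4)
  expect_true(all(om$probs >= 0 & om$probs <= 1))

  syn <- synoptic_map(om)
  expect_equal(syn$by_stratum$mean_prob, rowMeans(om$probs))
  eps <- 1 / (2 * om$n_mc)
  expect_equal(syn$by_stratum$loglik,
               rowSums(log(pmax(om$probs, eps))))

  # single fish: synoptic equals its own map
  om1 <- om; om1$probs <- om$probs[, 1, drop = FALSE]; om1$fish_ids <- "a"
  syn1 <- synoptic_map(om1)
  expect_equal(syn1$by_stratum$mean_prob, om$probs[, 1])

  # hand arithmetic: probabilities 0.2 and 0.4 at one location
  om2 <- om1
  om2$probs <- matrix(c(0.2, 0.4), 1, 2)
  om2$grid <- om$grid[1, ]; om2$fish_ids <- c("a", "b")
  s2 <- synoptic_map(om2)
  expect_equal(s2$by_stratum$mean_prob, 0.3)
  expect_equal(s2$by_stratum$loglik, log(0.2) + log(0.4))

  # uniform maps stay spatially constant
  omu <- om; omu$probs[] <- 0.5
  expect_true(all(synoptic_map(omu)$across_strata$mean_prob == 0.5))
})

test_that("area summaries aggregate cells inside polygons over 0-200 m", {
  iso <- toy_isoscape(lon = c(-30, -29, -28, -27), lat = c(-60, -59, -58, -57),
                      water_mean = 4, water_sd = 0.2, temp = 0)
  eq <- fractionation_equation(intercept = 0, temp_slope = 0, residual_sd = 0)
  obs <- data.frame(fish_id = "a", d18O = 4.0)
  om <- occurrence_maps(iso, eq, obs, n_mc = 2000, seed = 5)

  whole <- area_polygon("all", cbind(c(-31, -26, -26, -31), c(-61, -61, -56, -56)))
  a <- area_summary(om, list(all = whole), depth_range = c(0, 200))
  # whole-domain polygon equals the global mean over in-window strata
  keep <- om$grid$stratum %in% which(iso$strata$upper <= 200)
  agg <- rowsum(om$probs[keep, 1], paste(om$grid$lon[keep], om$grid$lat[keep])) /
    nrow(iso$strata[iso$strata$upper <= 200, ])
  expect_equal(a$mean_prob, mean(agg), tolerance = 1e-12)

  west <- area_polygon("W", cbind(c(-31, -28.5, -28.5, -31), c(-61, -61, -56, -56)))
  east <- area_polygon("E", cbind(c(-28.5, -26, -26, -28.5), c(-61, -61, -56, -56)))
  ab <- area_summary(om, list(W = west, E = east))
  expect_equal(sum(ab$n_cells), 16)
  expect_equal(sum(ab$n_cells * ab$mean_prob) / 16, mean(agg), tolerance = 1e-12)

  empty <- area_polygon("none", cbind(c(10, 11, 11, 10), c(10, 10, 11, 11)))
  ae <- area_summary(om, list(none = empty))
  expect_equal(ae$n_cells, 0)
  expect_true(is.na(ae$mean_prob))
})

test_that("top-percentile regions honour quantiles and ties", {
  iso <- toy_isoscape(lon = seq(-34.5, -25.5, 1), lat = seq(-64.5, -55.5, 1),
                      water_mean = 4, water_sd = 0.2, temp = 0)
  eq <- fractionation_equation(intercept = 0, temp_slope = 0, residual_sd = 0)
  obs <- data.frame(fish_id = c("a", "b"), d18O = c(4, 4))
  om <- occurrence_maps(iso, eq, obs, n_mc = 1500, seed = 6)

  # uniform map: all 100 cells tie at q = 0.95 and all are returned
  omu <- om; omu$probs[] <- 0.4
  top <- top_percentile_region(omu, c(1, 1), q = 0.95)
  expect_equal(nrow(top[["1"]]), 100)

  # single hot cell ends up in the top-5% set (continuous probabilities, so
  # the 95th-percentile threshold keeps ~5 of 100 cells)
  omh <- om
  hot <- which(omh$grid$lon == -30.5 & omh$grid$lat == -60.5)
  omh$probs[hot, ] <- 0.9999
  toph <- top_percentile_region(omh, c(1, 1), q = 0.95)
  expect_true(any(toph[["1"]]$lon == -30.5 & toph[["1"]]$lat == -60.5))
  expect_lte(nrow(toph[["1"]]), 10)

  # q = 0 returns every cell; clusters are split by label
  top0 <- top_percentile_region(om, c(1, 2), q = 0)
  expect_equal(nrow(top0[["1"]]), 100)
  expect_equal(nrow(top0[["2"]]), 100)
})
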