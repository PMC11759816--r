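# The synthetic-data generator: determinism, stated-world distributions, and
# compatibility with the preprocessing filters.

test_that("datasets are byte-identical under a fixed seed and differ across seeds", {
  a <- sim_dataset(sim_scenario(n_fish = 6, n_water_obs = 60, seed = 5))
  b <- sim_dataset(sim_scenario(n_fish = 6, n_water_obs = 60, seed = 5))
  expect_identical(a$signatures, b$signatures)
  expect_identical(a$env$water_obs, b$env$water_obs)
  expect_identical(lapply(a$transects, `[[`, "points"),
                   lapply(b$transects, `[[`, "points"))
  c2 <- sim_dataset(sim_scenario(n_fish = 6, n_water_obs = 60, seed = 6))
  expect_false(identical(a$signatures$Sr, c2$signatures$Sr))
})

test_that("degenerate proportions give a single source", {
  sim <- sim_fish(sim_scenario(n_fish = 25, source_proportions = c(1, 0)),
                  seed = 7)
  expect_true(all(sim$truth$source == 1))
})

test_that("source labels and signature means follow the stated two-source world", {
  sc <- sim_scenario(n_fish = 2000, seed = 8)
  env <- sim_environment(sc, seed = 8)
  sim <- sim_fish(sc, env, seed = 8)
  # law of large numbers on the 0.74/0.26 mixing proportions
  expect_lt(abs(mean(sim$truth$source == 1) - 0.74), 0.03)

  # per-source sample means sit within 3 standard errors of generator means
  nuc <- sim$signatures[sim$signatures$region == "nuclear", ]
  for (g in 1:2) {
    idx <- sim$truth$source == g
    for (e in c("Sr", "Ba", "Li")) {
      ei <- match(e, sc$elements)
      m <- mean(nuc[[e]][idx])
      se <- sc$source_sds[ei, g] / sqrt(sum(idx))
      # lognormal matching is to mean/SD, allow 3 SE plus 1% parameterization slack
      expect_lt(abs(m - sc$source_means[ei, g]),
                3 * se + 0.01 * sc$source_means[ei, g])
    }
  }
})

test_that("marginal signatures carry the stage shifts and event effects", {
  sc <- sim_scenario(n_fish = 400, seed = 9)
  env <- sim_environment(sc, seed = 9)
  sim <- sim_fish(sc, env, seed = 9)
  nuc <- sim$signatures[sim$signatures$region == "nuclear", ]
  mar <- sim$signatures[sim$signatures$region == "marginal", ]
  expect_equal(mean(mar$Sr / nuc$Sr), 15683.1 / 4461.9, tolerance = 0.05)
  expect_equal(mean(mar$d18O - nuc$d18O), 0.7, tolerance = 0.1)
  expect_equal(mean(mar$d13C - nuc$d13C), 3.1, tolerance = 0.1)
})

test_that("a perfect covariate share reproduces the deterministic water field", {
  sc <- sim_scenario(covariate_share = 1, n_water_obs = 80, seed = 10)
  env <- sim_environment(sc, seed = 10)
  obs <- convert_water_obs(env$water_obs)
  cf <- sc$water_coefs
  f <- cf["b0"] + cf["b_sal"] * (obs$salinity - 34) + cf["b_temp"] * obs$temperature +
    cf["b_depth"] * (obs$depth / 500)
  expect_equal(obs$d18O, unname(f), tolerance = 1e-9)
})

test_that("the covariate share of water-isotope variance matches its target", {
  sc <- sim_scenario(seed = 11)  # default 500 observations, share 0.61
  env <- sim_environment(sc, seed = 11)
  obs <- convert_water_obs(env$water_obs)
  r2 <- summary(lm(d18O ~ I(salinity - 34) + temperature + I(depth / 500),
                   data = obs))$r.squared
  expect_lt(abs(r2 - 0.61), 0.05)
})

test_that("noise-free transects are exact step functions at the true shift", {
  sc <- sim_scenario(n_fish = 5, transect_sdlog = 0, al_spike_rate = 0, seed = 12)
  sim <- sim_dataset(sc)
  for (i in seq_len(5)) {
    fid <- sim$shift_table$fish_id[i]
    pts <- sim$transects[[fid]]$points
    s <- sim$shift_table$shift_ablation[i]
    nucv <- sim$signatures[sim$signatures$region == "nuclear" &
                             sim$signatures$fish_id == fid, ]
    expect_equal(unique(pts$Sr[pts$index < s]), nucv$Sr, tolerance = 1e-12)
    expect_equal(unique(pts$Sr[pts$index >= s]), nucv$Sr * 3.5, tolerance = 1e-12)
    expect_equal(unique(pts$Ba[pts$index >= s]), nucv$Ba * 3.0, tolerance = 1e-12)
    expect_equal(unique(pts$Sn), nucv$Sn, tolerance = 1e-12)  # stationary element
  }
})

test_that("Al spikes are injected at the marked points only", {
  sc <- sim_scenario(n_fish = 10, al_spike_rate = 0.1, transect_sdlog = 0.01,
                     seed = 13)
  sim <- sim_dataset(sc)
  expect_gt(nrow(sim$al_spikes), 0)
  for (r in seq_len(nrow(sim$al_spikes))) {
    pts <- sim$transects[[sim$al_spikes$fish_id[r]]]$points
    expect_gt(pts$Al[pts$index == sim$al_spikes$index[r]], 5 * sc$al_base)
  }
  clean <- !paste(rep(names(sim$transects), each = 24), 1:24) %in%
    paste(sim$al_spikes$fish_id, sim$al_spikes$index)
  # unspiked points stay near baseline
  allal <- unlist(lapply(sim$transects, function(tr) {
    sp <- sim$al_spikes$index[sim$al_spikes$fish_id == tr$fish_id]
    tr$points$Al[!tr$points$index %in% sp]
  }))
  expect_true(all(allal < 5 * sc$al_base))
})

test_that("generated data pass the preprocessing validity checks", {
  sim <- sim_dataset(sim_scenario(n_fish = 15, seed = 14))
  # transect lengths in the expected range with contiguous indices
  for (tr in sim$transects) {
    expect_gte(nrow(tr$points), 14)
    expect_lte(nrow(tr$points), 24)
    expect_equal(tr$points$index, seq_len(nrow(tr$points)))
  }
  # the whole roster survives region extraction and the cohort window is sane
  reg <- extract_all_regions(sim$transects)
  expect_equal(sort(unique(reg$fish_id)), sort(sim$fish$fish_id))
  expect_true(all(sim$fish$birth_year >= 1985 & sim$fish$birth_year <= 2004))
  # write/read round trip of the full input bundle
  d <- tempfile()
  write_sim_inputs(sim, d)
  trs <- read_transects(file.path(d, "transects.csv"))
  expect_equal(length(trs), 15)
  expect_equal(trs[[sim$fish$fish_id[3]]]$points$Sr,
               sim$transects[[sim$fish$fish_id[3]]]$points$Sr)
  fld <- read_env_field(file.path(d, "temperature.grid.csv"))
  expect_identical(fld$values, sim$env$temperature$values)
})

test_that("true shift ablations always lie inside their transects", {
  sim <- sim_dataset(sim_scenario(n_fish = 40, seed = 15))
  expect_true(all(sim$shift_table$shift_ablation >= 2))
  expect_true(all(sim$shift_table$shift_ablation <= sim$shift_table$n_ablations))
})
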