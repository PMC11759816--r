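# Shared fixtures built in code. Tests keep simulations small; the stated-world
# defaults are exercised where a criterion depends on them.

options(otogeo.verbose = FALSE)

# A minimal transect with known values: element X ramps 1..n, Sr constant.
toy_transect <- function(fish_id = "T1", n = 17) {
  otolith_transect(fish_id, data.frame(
    index = seq_len(n),
    distance = (seq_len(n) - 1) * 95,
    X = as.numeric(seq_len(n)),
    Sr = rep(5, n)))
}

# Two-fish toy transect table on disk; returns the path.
toy_transect_csv <- function(path = tempfile(fileext = ".csv"), shuffle = FALSE) {
  tab <- data.frame(
    fish_id = rep(c("A", "B"), each = 3),
    index = rep(1:3, 2),
    distance = rep(c(0, 95, 190), 2),
    Sr = c(1, 2, 3, 4, 5, 6),
    Ba = c(6, 5, 4, 3, 2, 1))
  if (shuffle) tab <- tab[c(4, 2, 6, 1, 3, 5), ]
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  path
}

# Tiny 4 x 4 x 2 environmental field with one value pattern.
toy_env_field <- function(with_missing_stratum = FALSE) {
  strata <- make_strata(c(0, 50, 100))
  vals <- array(seq_len(4 * 4 * 2) + 0.123456789012345, c(4, 4, 2))
  if (with_missing_stratum) vals[, , 2] <- NA_real_
  env_field("temperature", lon = c(-30, -29, -28, -27),
            lat = c(-60, -59, -58, -57), strata = strata, values = vals,
            variance = vals * 0 + 0.25, units = "degC")
}

# Hand-built isoscape-like object for geolocation unit tests: constant or
# user-supplied mean/temperature surfaces, zero uncertainty by default.
toy_isoscape <- function(lon = c(-30, -29, -28), lat = c(-60, -59, -58),
                         strata = make_strata(c(0, 100, 200)),
                         water_mean = 0, water_sd = 0,
                         temp = 0, temp_sd = 0) {
  dims <- c(length(lon), length(lat), nrow(strata))
  fill <- function(x) if (length(x) == 1) array(x, dims) else x
  structure(list(lon = lon, lat = lat, strata = strata,
                 mean = fill(water_mean), sd = fill(water_sd),
                 temperature = fill(temp), temperature_sd = fill(temp_sd),
                 extrapolated = array(FALSE, dims),
                 diagnostics = list(deviance_explained = NA_real_)),
            class = "isoscape")
}

# Monte-Carlo standard error of a posterior probability estimated from k kept
# Gibbs samples with effective-sample-size deflation factor `ess_frac`.
mc_se <- function(p, kept, ess_frac = 0.2) {
  sqrt(pmax(p * (1 - p), 1e-6) / (kept * ess_frac))
}
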