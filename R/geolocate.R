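# Geo-location of juvenile origin: fractionation equations, Monte-Carlo
# propagation of isoscape + temperature + fractionation errors into expected
# otolith delta-18O distributions per cell and depth stratum, per-fish
# occurrence probabilities, synoptic maps, area summaries and top-percentile
# origin regions.

#' Construct an otolith delta-18O fractionation equation
#'
#' `predicted = intercept + temp_slope * T + water_coefficient * d18O_water`.
#' The default is the aragonite equilibrium relation
#' `4.64 - 0.21 T + d18O_water` (per mil, T in degrees C). The residual SD is
#' the fractionation scatter propagated in the Monte-Carlo stage; it is not a
#' published constant and defaults to 0.2 per mil.
#'
#' @param name label used in reports.
#' @param intercept per-mil intercept.
#' @param temp_slope per-mil per degree C.
#' @param water_coefficient coefficient on water delta-18O (default 1).
#' @param residual_sd fractionation residual SD (per mil).
#' @return object of class `fractionation_eq`.
#' @export
fractionation_equation <- function(name = "thorrold", intercept = 4.64,
                                   temp_slope = -0.21, water_coefficient = 1,
                                   residual_sd = 0.2) {
  structure(list(name = name, intercept = intercept, temp_slope = temp_slope,
                 water_coefficient = water_coefficient,
                 residual_sd = residual_sd),
            class = "fractionation_eq")
}

#' Predicted otolith delta-18O from temperature and water delta-18O
#'
#' @param eq a [fractionation_equation()].
#' @param temperature water temperature, degrees C.
#' @param d18O_water water delta-18O (per mil, same scale the equation was
#'   calibrated on).
#' @return per-mil predicted otolith delta-18O.
#' @export
predict_oto <- function(eq, temperature, d18O_water) {
  eq$intercept + eq$temp_slope * temperature + eq$water_coefficient * d18O_water
}

#' Mean temperature and water delta-18O around a capture site
#'
#' Unweighted mean over grid cells whose centre lies within `radius_km`
#' (great-circle) of the capture position -- the nearest cell is always
#' included, so a radius smaller than the grid spacing degrades to
#' nearest-cell lookup -- and over strata overlapping a `layer_m`-thick depth
#' layer centred on the capture depth (nearest stratum when none overlaps).
#'
#' @param isoscape a fitted [fit_isoscape()] object.
#' @param lon,lat,depth capture position (degrees, metres).
#' @param radius_km averaging radius (default 100 km).
#' @param layer_m averaging depth-layer thickness (default 100 m).
#' @return list with `temperature`, `d18O_water`, `n_cells`, `strata`.
#' @export
capture_site_expectation <- function(isoscape, lon, lat, depth,
                                     radius_km = 100, layer_m = 100) {
  grid <- expand.grid(lon = isoscape$lon, lat = isoscape$lat)
  dists <- gc_dist_km(grid$lon, grid$lat, lon, lat)
  incell <- dists <= radius_km
  if (!any(incell)) incell[which.min(dists)] <- TRUE
  lo <- depth - layer_m / 2; hi <- depth + layer_m / 2
  st <- which(isoscape$strata$upper > lo & isoscape$strata$lower < hi)
  if (!length(st)) {
    st <- which.min(abs(isoscape$strata$mid - depth))
  }
  tvals <- c(); wvals <- c()
  for (k in st) {
    tvals <- c(tvals, as.vector(isoscape$temperature[, , k])[incell])
    wvals <- c(wvals, as.vector(isoscape$mean[, , k])[incell])
  }
  if (all(is.na(wvals))) stop("no isoscape values available around the capture site")
  list(temperature = mean(tvals, na.rm = TRUE),
       d18O_water = mean(wvals, na.rm = TRUE),
       n_cells = sum(incell), strata = st)
}

#' Fractionation-equation bias test at capture sites
#'
#' Compares observed otolith-edge delta-18O to the value each candidate
#' equation predicts from the isoscape averaged around the capture site
#' (100 km radius, 100 m depth layer by default). Equations are ranked by
#' absolute mean bias (observed minus predicted).
#'
#' @param equations named list of [fractionation_equation()]s.
#' @param edge_obs data.frame with `fish_id` and `d18O` (edge values, VPDB).
#' @param fish fish records with `fish_id`, `capture_lon`, `capture_lat` and
#'   `capture_depth` (m; missing depth defaults to mid-domain).
#' @param isoscape fitted isoscape for the edge temporal window.
#' @param radius_km,layer_m averaging window (defaults 100 km, 100 m).
#' @return data.frame of class `bias_report`: per equation `mean_bias`,
#'   `sd_bias`, `n_fish`, ranked by `abs(mean_bias)`.
#' @export
bias_test <- function(equations, edge_obs, fish, isoscape,
                      radius_km = 100, layer_m = 100) {
  if (is.null(fish$capture_depth)) {
    fish$capture_depth <- mean(range(isoscape$strata$lower, isoscape$strata$upper))
  }
  m <- merge(edge_obs, fish, by = "fish_id")
  ok <- !is.na(m$capture_lon) & !is.na(m$capture_lat)
  if (any(!ok)) {
    og_log("bias_test", "%d fish skipped (missing capture location)", sum(!ok))
  }
  m <- m[ok, , drop = FALSE]
  if (nrow(m) < 5) stop("bias test needs >= 5 fish with capture coordinates")
  site <- lapply(seq_len(nrow(m)), function(i) {
    capture_site_expectation(isoscape, m$capture_lon[i], m$capture_lat[i],
                             m$capture_depth[i], radius_km, layer_m)
  })
  tbar <- vapply(site, `[[`, 0, "temperature")
  wbar <- vapply(site, `[[`, 0, "d18O_water")
  rows <- lapply(names(equations), function(nm) {
    eq <- equations[[nm]]
    bias <- m$d18O - predict_oto(eq, tbar, wbar)
    data.frame(equation = nm, mean_bias = mean(bias), sd_bias = sd(bias),
               n_fish = nrow(m))
  })
  out <- do.call(rbind, rows)
  out <- out[order(abs(out$mean_bias)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("bias_report", "data.frame")
  out
}

#' Monte-Carlo expected otolith delta-18O distribution at one location
#'
#' Each draw composes a water draw `N(isoscape mean, isoscape sd)`, a
#' temperature draw `N(env mean, env sd)` and fractionation noise
#' `N(0, eq$residual_sd)` through [predict_oto()]. Non-positive SDs are treated
#' as 0 with a warning.
#'
#' @param isoscape fitted isoscape.
#' @param eq a [fractionation_equation()].
#' @param cell_lon,cell_lat cell-centre coordinates (nearest cell used).
#' @param stratum stratum index.
#' @param n_mc Monte-Carlo draws (default 5000).
#' @param seed optional RNG seed.
#' @return list of class `expected_oto_distribution` with `mc_samples`,
#'   `mean`, `sd`.
#' @export
expected_distribution <- function(isoscape, eq, cell_lon, cell_lat, stratum,
                                  n_mc = 5000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  i <- which.min(abs(isoscape$lon - cell_lon))
  j <- which.min(abs(isoscape$lat - cell_lat))
  wm <- isoscape$mean[i, j, stratum]; ws <- isoscape$sd[i, j, stratum]
  tm <- isoscape$temperature[i, j, stratum]
  ts <- isoscape$temperature_sd[i, j, stratum]
  if (is.na(wm) || is.na(tm)) stop("cell has no isoscape mean/temperature")
  sds <- c(ws, ts, eq$residual_sd)
  if (any(sds < 0, na.rm = TRUE)) {
    warning("negative SD treated as 0")
    sds <- pmax(sds, 0)
  }
  draws <- predict_oto(eq, rnorm(n_mc, tm, sds[2]), rnorm(n_mc, wm, sds[1])) +
    rnorm(n_mc, 0, sds[3])
  structure(list(cell = c(lon = isoscape$lon[i], lat = isoscape$lat[j]),
                 stratum = stratum, mc_samples = draws,
                 mean = mean(draws), sd = sd(draws)),
            class = "expected_oto_distribution")
}

# Two-sided empirical tail probability of x under draws (midpoint-adjusted so
# x at the empirical median gives p = 1).
tail_prob <- function(x, draws_sorted, n_mc) {
  below <- findInterval(x, draws_sorted)        # draws <= x (strictly sorted)
  Fx <- below / n_mc
  pmin(1, 2 * pmin(Fx, 1 - Fx) + 1 / n_mc)
}

#' Occurrence probability of an observed otolith value under an expected
#' distribution
#'
#' The default metric is the two-sided Monte-Carlo tail probability
#' `p = 2 * min(F(x), 1 - F(x))`, which is 1 when the observation sits at the
#' centre of the expected distribution and falls to 0 far outside it. The
#' `"likelihood"` alternative returns the normal likelihood normalised to its
#' mode, `exp(-z^2 / 2)`.
#'
#' @param observed_d18O observed value (per mil VPDB).
#' @param dist an [expected_distribution()] (needs >= 1000 draws).
#' @param method `"tail"` (default) or `"likelihood"`.
#' @return probability in `[0, 1]`.
#' @export
occurrence_probability <- function(observed_d18O, dist,
                                   method = c("tail", "likelihood")) {
  method <- match.arg(method)
  draws <- dist$mc_samples
  if (length(draws) < 1000) stop("expected distribution needs >= 1000 draws")
  if (method == "likelihood") {
    return(exp(-0.5 * ((observed_d18O - mean(draws)) / sd(draws))^2))
  }
  tail_prob(observed_d18O, sort(draws), length(draws))
}

#' Per-fish occurrence-probability maps
#'
#' For every grid cell and depth stratum, draws the expected otolith delta-18O
#' distribution once (shared across fish) and scores each fish's nuclear value
#' against it. Rows of the `grid` element index locations (cell x stratum);
#' `probs` holds one column per fish.
#'
#' @param isoscape fitted isoscape (juvenile temporal window).
#' @param eq a [fractionation_equation()].
#' @param nuclear_obs data.frame with `fish_id`, `d18O` (nuclear, VPDB).
#' @param n_mc Monte-Carlo draws per location (default 5000).
#' @param seed optional RNG seed.
#' @param method see [occurrence_probability()].
#' @return object of class `occurrence_map`: list(grid, probs, fish_ids, n_mc).
#' @export
occurrence_maps <- function(isoscape, eq, nuclear_obs, n_mc = 5000,
                            seed = NULL, method = c("tail", "likelihood")) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  ns <- nrow(isoscape$strata)
  grid <- expand.grid(lon = isoscape$lon, lat = isoscape$lat)
  cells <- do.call(rbind, lapply(seq_len(ns), function(k)
    cbind(grid, stratum = k)))
  nf <- nrow(nuclear_obs)
  probs <- matrix(NA_real_, nrow(cells), nf)
  x <- nuclear_obs$d18O
  row0 <- 0
  for (k in seq_len(ns)) {
    wm <- as.vector(isoscape$mean[, , k]); ws <- as.vector(isoscape$sd[, , k])
    tm <- as.vector(isoscape$temperature[, , k])
    ts <- as.vector(isoscape$temperature_sd[, , k])
    for (c0 in seq_along(wm)) {
      r <- row0 + c0
      if (is.na(wm[c0]) || is.na(tm[c0])) next
      draws <- predict_oto(eq, rnorm(n_mc, tm[c0], max(ts[c0], 0)),
                           rnorm(n_mc, wm[c0], max(ws[c0], 0))) +
        rnorm(n_mc, 0, eq$residual_sd)
      if (method == "tail") {
        probs[r, ] <- tail_prob(x, sort(draws), n_mc)
      } else {
        probs[r, ] <- exp(-0.5 * ((x - mean(draws)) / sd(draws))^2)
      }
    }
    row0 <- row0 + length(wm)
  }
  structure(list(grid = cells, probs = probs,
                 fish_ids = as.character(nuclear_obs$fish_id), n_mc = n_mc,
                 strata = isoscape$strata, method = method),
            class = "occurrence_map")
}

#' Synoptic occurrence maps and per-location log-likelihood
#'
#' Averages individual occurrence probabilities over fish within each stratum
#' and (unweighted over strata) across strata, and computes each location's
#' log-likelihood as the sum of log individual probabilities. Zero
#' probabilities are floored at `eps = 1 / (2 * n_mc)` (the Monte-Carlo
#' resolution limit) before the log.
#'
#' @param om an [occurrence_maps()] object.
#' @return list with `by_stratum` (grid + `mean_prob`, `loglik`) and
#'   `across_strata` (lon/lat + `mean_prob`, `loglik` computed on per-fish
#'   probabilities first averaged over strata).
#' @export
synoptic_map <- function(om) {
  eps <- 1 / (2 * om$n_mc)
  if (any(om$probs == 0, na.rm = TRUE)) {
    og_log("synoptic_map", "zero probabilities floored at %.2g before log", eps)
  }
  P <- pmax(om$probs, eps)
  by_stratum <- cbind(om$grid,
                      mean_prob = rowMeans(om$probs),
                      loglik = rowSums(log(P)))
  # aggregate per lon/lat cell: per-fish mean over strata, then synoptic stats
  key <- paste(om$grid$lon, om$grid$lat)
  ucells <- !duplicated(key)
  agg <- rowsum(om$probs, key, na.rm = TRUE) /
    as.vector(rowsum((!is.na(om$probs)) * 1, key))
  ord <- match(key[ucells], rownames(agg))
  aggP <- pmax(agg[ord, , drop = FALSE], eps)
  across <- data.frame(lon = om$grid$lon[ucells], lat = om$grid$lat[ucells],
                       mean_prob = rowMeans(agg[ord, , drop = FALSE]),
                       loglik = rowSums(log(aggP)))
  list(by_stratum = by_stratum, across_strata = across)
}

#' Summarise occurrence by sub-population area
#'
#' Per area polygon: the mean synoptic probability and the mean per-location
#' log-likelihood over the grid cells inside it, using only strata contained in
#' `depth_range` and averaging each fish's probability over those strata before
#' taking logs.
#'
#' @param om an [occurrence_maps()] object.
#' @param polygons named list of [area_polygon()].
#' @param depth_range depth window in metres (default 0--200).
#' @return data.frame per area: `n_cells`, `mean_prob`, `loglik`; areas with no
#'   cells are flagged with `n_cells = 0` and NA statistics.
#' @export
area_summary <- function(om, polygons, depth_range = c(0, 200)) {
  eps <- 1 / (2 * om$n_mc)
  keep_strata <- which(om$strata$lower >= depth_range[1] &
                         om$strata$upper <= depth_range[2])
  if (!length(keep_strata)) stop("no strata contained in the requested depth range")
  sel <- om$grid$stratum %in% keep_strata
  key <- paste(om$grid$lon[sel], om$grid$lat[sel])
  agg <- rowsum(om$probs[sel, , drop = FALSE], key, na.rm = TRUE) /
    as.vector(rowsum((!is.na(om$probs[sel, , drop = FALSE])) * 1, key))
  cells <- unique(data.frame(lon = om$grid$lon[sel], lat = om$grid$lat[sel]))
  agg <- agg[match(paste(cells$lon, cells$lat), rownames(agg)), , drop = FALSE]
  rows <- lapply(polygons, function(p) {
    inside <- point_in_polygon(cells$lon, cells$lat, p)
    if (!any(inside)) {
      return(data.frame(area = p$name, n_cells = 0L, mean_prob = NA_real_,
                        loglik = NA_real_))
    }
    sub <- agg[inside, , drop = FALSE]
    data.frame(area = p$name, n_cells = sum(inside),
               mean_prob = mean(sub, na.rm = TRUE),
               loglik = mean(rowSums(log(pmax(sub, eps)))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Top-percentile origin regions per mixture cluster
#'
#' For each cluster of fish (hard mixture labels), builds the across-strata
#' synoptic map of that cluster and returns the cells at or above the
#' `q`-quantile of its probabilities (ties included, so a flat map returns all
#' cells; `q = 0` returns all cells).
#'
#' @param om an [occurrence_maps()] object.
#' @param cluster_assignments vector of cluster labels, one per fish, aligned
#'   with `om$fish_ids`.
#' @param q quantile threshold (default 0.95 = highest 5 percent).
#' @return named list (per cluster) of data.frames `lon`, `lat`, `mean_prob`.
#' @export
top_percentile_region <- function(om, cluster_assignments, q = 0.95) {
  stopifnot(length(cluster_assignments) == length(om$fish_ids))
  out <- list()
  for (cl in sort(unique(cluster_assignments))) {
    sub <- om
    keep <- cluster_assignments == cl
    sub$probs <- om$probs[, keep, drop = FALSE]
    sub$fish_ids <- om$fish_ids[keep]
    syn <- synoptic_map(sub)$across_strata
    thr <- quantile(syn$mean_prob, q, na.rm = TRUE, names = FALSE)
    out[[as.character(cl)]] <- syn[!is.na(syn$mean_prob) & syn$mean_prob >= thr,
                                   c("lon", "lat", "mean_prob")]
  }
  out
}
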