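# Isotope standardization and the seawater delta-18O isoscape: an additive
# penalized-spline covariate stage (salinity, temperature, depth; mgcv) plus a
# per-stratum residual Gaussian process with exponential covariance (ML
# parameters, plug-in universal kriging) for spatial prediction with variance.

#' Chain a measured isotope ratio onto the VPDB scale
#'
#' Standardization against a primary reference:
#' `delta_sample/ref = 1000 * (1 - R_sample / R_reference)` (per mil), then
#' `delta_VPDB = ((d_s/1000 + 1) * (d_ref/1000 + 1) - 1) * 1000` where `d_ref`
#' is the reference's nominal per-mil value on VPDB (NBS-19: +1.95 for
#' delta13C, -2.20 for delta18O). A sample whose ratio equals the reference's
#' returns exactly the nominal value.
#'
#' @param R_sample measured isotopic ratio of the sample (> 0).
#' @param R_reference measured ratio of the primary standard (> 0).
#' @param nominal_ref_vpdb nominal per-mil value of the standard on VPDB.
#' @return per-mil value on the VPDB scale.
#' @export
delta_vpdb <- function(R_sample, R_reference, nominal_ref_vpdb) {
  if (any(R_sample <= 0) || any(R_reference <= 0)) {
    stop("isotopic ratios must be positive")
  }
  d_sn <- 1000 * (1 - R_sample / R_reference)
  ((d_sn / 1000 + 1) * (nominal_ref_vpdb / 1000 + 1) - 1) * 1000
}

#' Nominal NBS-19 values on the VPDB scale (per mil)
#'
#' `c(d13C = 1.95, d18O = -2.20)`.
#' @export
nbs19_nominal <- c(d13C = 1.95, d18O = -2.20)

#' Convert seawater delta-18O from SMOW to VPDB
#'
#' Affine map `0.97006 * x - 29.94` (per mil), applied exactly.
#'
#' @param d18O_smow per-mil value(s) on the SMOW scale.
#' @return per-mil value(s) on the VPDB scale.
#' @export
smow_to_vpdb <- function(d18O_smow) 0.97006 * d18O_smow - 29.94

#' Inverse of [smow_to_vpdb()]
#' @param d18O_vpdb per-mil value(s) on the VPDB scale.
#' @return per-mil value(s) on the SMOW scale.
#' @export
vpdb_to_smow <- function(d18O_vpdb) (d18O_vpdb + 29.94) / 0.97006

#' Convert water-isotope observations to the VPDB scale
#'
#' Requires an explicit `scale` column (`"SMOW"` or `"VPDB"`) so the affine
#' conversion can never be applied twice.
#'
#' @param obs data.frame with columns `d18O` and `scale`.
#' @return same data.frame with `d18O` on VPDB and `scale = "VPDB"`.
#' @export
convert_water_obs <- function(obs) {
  if (is.null(obs$scale)) stop("water observations need an explicit 'scale' column")
  bad <- !obs$scale %in% c("SMOW", "VPDB")
  if (any(bad)) stop("unknown isotope scale: ", paste(unique(obs$scale[bad]), collapse = ", "))
  sm <- obs$scale == "SMOW"
  obs$d18O[sm] <- smow_to_vpdb(obs$d18O[sm])
  obs$scale <- "VPDB"
  obs
}

## ---- residual Gaussian process ------------------------------------------------

# Exponential covariance: sill * exp(-d / range), distances in km.
exp_cov <- function(D, range_km, sill) sill * exp(-D / range_km)

# Negative log-likelihood of a zero-mean GP with exponential covariance plus
# nugget, given pairwise distances D and values y.
gp_nll <- function(par, D, y) {
  range_km <- exp(par[1]); sill <- exp(par[2]); nugget <- exp(par[3])
  K <- exp_cov(D, range_km, sill)
  diag(K) <- diag(K) + nugget
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  a <- backsolve(ch, backsolve(ch, y, transpose = TRUE))
  0.5 * (sum(y * a) + 2 * sum(log(diag(ch))) + length(y) * log(2 * pi))
}

#' Maximum-likelihood exponential-covariance parameters
#'
#' Fits range, sill and nugget of a zero-mean Gaussian process with
#' exponential covariance to (already detrended) values at lon/lat points.
#'
#' @param lon,lat observation coordinates (degrees).
#' @param values detrended observations.
#' @return list with `range_km`, `sill`, `nugget`, `nll`.
#' @export
gp_ml <- function(lon, lat, values) {
  D <- gc_dist_matrix(lon, lat)
  v <- var(values)
  if (v == 0) return(list(range_km = 1, sill = 0, nugget = 1e-12, nll = NA_real_))
  med <- median(D[upper.tri(D)])
  start <- log(c(max(med, 1), 0.7 * v, 0.3 * v + 1e-8))
  opt <- optim(start, gp_nll, D = D, y = values, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-10))
  list(range_km = exp(opt$par[1]), sill = exp(opt$par[2]),
       nugget = exp(opt$par[3]), nll = opt$value)
}

#' Kriging prediction under an exponential-covariance Gaussian process
#'
#' Plug-in (simple) kriging of zero-mean values: posterior mean
#' `k* K^-1 y` and variance `sill - k*' K^-1 k*` (the process variance at the
#' new site, excluding the nugget). With `nugget = 0` the predictor
#' interpolates the data exactly with zero variance at the data sites. A
#' numerically non-positive-definite covariance triggers nugget inflation with
#' a warning.
#'
#' @param obs_lon,obs_lat,obs_values observations (values detrended, mean 0).
#' @param pred_lon,pred_lat prediction sites.
#' @param range_km,sill,nugget exponential-covariance parameters.
#' @return list with `mean` and `var` at the prediction sites.
#' @export
krige_exp <- function(obs_lon, obs_lat, obs_values, pred_lon, pred_lat,
                      range_km, sill, nugget = 0) {
  if (sill <= 0) {
    return(list(mean = rep(0, length(pred_lon)), var = rep(0, length(pred_lon))))
  }
  D <- gc_dist_matrix(obs_lon, obs_lat)
  K <- exp_cov(D, range_km, sill)
  diag(K) <- diag(K) + nugget
  ch <- NULL
  jit <- 0
  for (try in 0:6) {
    ch <- tryCatch(chol(K + diag(jit, nrow(K))), error = function(e) NULL)
    if (!is.null(ch)) break
    jit <- if (jit == 0) 1e-10 * sill else jit * 100
  }
  if (is.null(ch)) stop("covariance matrix not positive definite")
  if (jit > 0) warning(sprintf("covariance nearly singular: nugget inflated by %.3g", jit))
  Kstar <- exp_cov(gc_dist_matrix(obs_lon, obs_lat, pred_lon, pred_lat),
                   range_km, sill)              # n_obs x n_pred
  a <- backsolve(ch, backsolve(ch, obs_values, transpose = TRUE))
  mean <- drop(crossprod(Kstar, a))
  V <- backsolve(ch, Kstar, transpose = TRUE)
  var <- pmax(0, sill - colSums(V^2))
  list(mean = mean, var = var)
}

## ---- environmental interpolation ----------------------------------------------

#' Interpolate scattered environmental observations onto the grid
#'
#' Per depth stratum: a polynomial lon/lat trend surface (quadratic when the
#' stratum is well observed, linear when thin, constant otherwise) plus
#' spatially correlated smoothing of the trend residuals (exponential-covariance
#' kriging with maximum-likelihood parameters). A noiseless planar field is
#' recovered without error. Strata with a single observation give a constant
#' field (warning); empty strata stay missing. Leave-one-out RMSE per stratum
#' (at the stratum's fitted covariance parameters) is attached as a diagnostic.
#'
#' @param obs data.frame with `lon`, `lat`, `depth`, `value`.
#' @param variable name for the output field.
#' @param lon,lat target grid cell centres.
#' @param strata strata table from [make_strata()].
#' @return an [env_field()] with `attr(, "loo_rmse")`.
#' @export
interpolate_env <- function(obs, variable, lon, lat, strata) {
  vals <- array(NA_real_, c(length(lon), length(lat), nrow(strata)))
  grid <- expand.grid(lon = lon, lat = lat)
  obs$stratum <- stratum_of_depth(obs$depth, strata)
  loo <- rep(NA_real_, nrow(strata))
  fit_trend <- function(d) {
    if (nrow(d) >= 12) {
      lm(value ~ lon + lat + I(lon^2) + I(lat^2) + I(lon * lat), data = d)
    } else if (nrow(d) >= 4) {
      lm(value ~ lon + lat, data = d)
    } else lm(value ~ 1, data = d)
  }
  predict_one <- function(d, plon, plat, pars) {
    if (nrow(d) == 1) return(rep(d$value, length(plon)))
    trend <- fit_trend(d)
    resid <- d$value - predict(trend)
    pred <- predict(trend, newdata = data.frame(lon = plon, lat = plat))
    if (pars$sill > 0 && var(resid) > 0) {
      pred <- pred + krige_exp(d$lon, d$lat, resid, plon, plat,
                               pars$range_km, pars$sill, pars$nugget)$mean
    }
    unname(pred)
  }
  for (k in seq_len(nrow(strata))) {
    d <- obs[!is.na(obs$stratum) & obs$stratum == k, , drop = FALSE]
    if (nrow(d) == 0) next
    if (nrow(d) == 1) {
      warning(sprintf("stratum %d has a single %s observation: constant field", k, variable))
    }
    pars <- if (nrow(d) >= 5) {
      gp_ml(d$lon, d$lat, d$value - predict(fit_trend(d)))
    } else list(range_km = 1, sill = 0, nugget = 0)
    vals[, , k] <- predict_one(d, grid$lon, grid$lat, pars)
    if (nrow(d) >= 5) {
      errs <- vapply(seq_len(nrow(d)), function(i) {
        predict_one(d[-i, , drop = FALSE], d$lon[i], d$lat[i], pars) - d$value[i]
      }, 0)
      loo[k] <- sqrt(mean(errs^2))
    }
  }
  out <- env_field(variable, lon, lat, strata, vals)
  attr(out, "loo_rmse") <- loo
  out
}

## ---- isoscape -----------------------------------------------------------------

# Pull the env-field value (and variance) at given cells/strata.
env_at <- function(field, lon, lat, stratum) {
  i <- vapply(lon, function(x) which.min(abs(field$lon - x)), 0L)
  j <- vapply(lat, function(y) which.min(abs(field$lat - y)), 0L)
  idx <- cbind(i, j, stratum)
  list(value = field$values[idx],
       variance = if (is.null(field$variance)) rep(0, nrow(idx)) else field$variance[idx])
}

#' Fit a seawater delta-18O isoscape
#'
#' Two-stage empirical-Bayes universal kriging. Stage one regresses the
#' VPDB-converted observations on salinity, temperature and depth through an
#' additive penalized-spline model (cubic bases, smoothness by GCV); the share
#' of deviance it explains is reported. Stage two fits, per depth stratum, a
#' zero-mean Gaussian process with exponential covariance to the stage-one
#' residuals (range/sill/nugget by maximum likelihood; strata with fewer than
#' `min_gp_obs` points fall back to parameters pooled over all residuals).
#' Predictions on the grid add the kriged residual to the covariate fit; the
#' prediction variance adds the kriging variance to the squared covariate-fit
#' standard error. Cells whose nearest observation is beyond three correlation
#' ranges are flagged extrapolated.
#'
#' @param obs water observations: `lon`, `lat`, `depth`, `d18O`, `scale`,
#'   `temperature`, `salinity`, optionally `year`.
#' @param env_t,env_s temperature and salinity [env_field()]s defining the
#'   prediction grid and strata (temperature mean/variance feed geolocation).
#' @param year_window optional inclusive year filter applied before fitting.
#' @param min_gp_obs minimum residuals per stratum for a stratum-specific GP.
#' @return object of class `isoscape` with mean/sd arrays over cells x strata,
#'   the temperature mean/sd arrays, and fit diagnostics.
#' @export
fit_isoscape <- function(obs, env_t, env_s, year_window = NULL, min_gp_obs = 10) {
  if (!is.null(year_window) && !is.null(obs$year)) {
    obs <- obs[obs$year >= year_window[1] & obs$year <= year_window[2], , drop = FALSE]
  }
  if (nrow(obs) < 30) stop("need at least 30 water-isotope observations")
  obs <- convert_water_obs(obs)
  strata <- env_t$strata
  obs$stratum <- stratum_of_depth(obs$depth, strata)
  obs <- obs[!is.na(obs$stratum), , drop = FALSE]
  og_log("fit_isoscape", "%d observations across %d strata", nrow(obs),
         length(unique(obs$stratum)))

  # stage (i): additive covariate model with spline bases sized to the data
  kfor <- function(v, kmax = 7) max(3, min(kmax, length(unique(v)) - 1))
  terms <- c(
    if (length(unique(obs$salinity)) > 3)
      sprintf("s(salinity, bs='cr', k=%d)", kfor(obs$salinity)) else "salinity",
    if (length(unique(obs$temperature)) > 3)
      sprintf("s(temperature, bs='cr', k=%d)", kfor(obs$temperature)) else "temperature",
    if (length(unique(obs$depth)) > 3)
      sprintf("s(depth, bs='cr', k=%d)", kfor(obs$depth)) else "depth")
  form <- stats::as.formula(paste("d18O ~", paste(terms, collapse = " + ")))
  gamfit <- mgcv::gam(form, data = obs, method = "GCV.Cp")
  dev_expl <- summary(gamfit)$dev.expl
  obs$resid <- obs$d18O - as.numeric(predict(gamfit))

  # stage (ii): per-stratum residual GP (pooled fallback for thin strata)
  pooled <- gp_ml(obs$lon, obs$lat, obs$resid)
  gp_pars <- vector("list", nrow(strata))
  for (k in seq_len(nrow(strata))) {
    d <- obs[obs$stratum == k, , drop = FALSE]
    gp_pars[[k]] <- if (nrow(d) >= min_gp_obs) {
      gp_ml(d$lon, d$lat, d$resid)
    } else pooled
  }

  lon <- env_t$lon; lat <- env_t$lat
  grid <- expand.grid(lon = lon, lat = lat)
  dims <- c(length(lon), length(lat), nrow(strata))
  mean_arr <- array(NA_real_, dims)
  sd_arr <- array(NA_real_, dims)
  extrap <- array(FALSE, dims)
  for (k in seq_len(nrow(strata))) {
    newd <- data.frame(lon = grid$lon, lat = grid$lat,
                       salinity = as.vector(env_s$values[, , k]),
                       temperature = as.vector(env_t$values[, , k]),
                       depth = strata$mid[k])
    okcell <- stats::complete.cases(newd)
    pred <- predict(gamfit, newdata = newd[okcell, ], se.fit = TRUE)
    d <- obs[obs$stratum == k, , drop = FALSE]
    pars <- gp_pars[[k]]
    if (nrow(d) >= 2 && pars$sill > 0) {
      kr <- krige_exp(d$lon, d$lat, d$resid, newd$lon[okcell], newd$lat[okcell],
                      pars$range_km, pars$sill, pars$nugget)
    } else {
      kr <- list(mean = rep(0, sum(okcell)),
                 var = rep(pars$sill + pars$nugget, sum(okcell)))
    }
    m <- rep(NA_real_, nrow(newd)); s <- rep(NA_real_, nrow(newd))
    m[okcell] <- as.numeric(pred$fit) + kr$mean
    s[okcell] <- sqrt(pmax(0, pred$se.fit^2 + kr$var))
    mean_arr[, , k] <- m
    sd_arr[, , k] <- s
    if (nrow(d) > 0) {
      nearest <- apply(gc_dist_matrix(d$lon, d$lat, grid$lon, grid$lat), 2, min)
      extrap[, , k] <- nearest > 3 * pars$range_km
    } else extrap[, , k] <- TRUE
  }

  structure(list(lon = lon, lat = lat, strata = strata,
                 mean = mean_arr, sd = sd_arr,
                 temperature = env_t$values,
                 temperature_sd = if (is.null(env_t$variance)) array(0, dims)
                                  else sqrt(env_t$variance),
                 extrapolated = extrap,
                 diagnostics = list(
                   deviance_explained = dev_expl,
                   n_obs = nrow(obs),
                   gp = data.frame(
                     stratum = seq_len(nrow(strata)),
                     range_km = vapply(gp_pars, `[[`, 0, "range_km"),
                     sill = vapply(gp_pars, `[[`, 0, "sill"),
                     nugget = vapply(gp_pars, `[[`, 0, "nugget"))),
                 gam = gamfit),
            class = "isoscape")
}

#' @export
print.isoscape <- function(x, ...) {
  cat(sprintf("isoscape: %d x %d grid, %d strata; covariates explain %.1f%% of deviance\n",
              length(x$lon), length(x$lat), nrow(x$strata),
              100 * x$diagnostics$deviance_explained))
  invisible(x)
}
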