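# Von Bertalanffy growth model and the radius -> length -> age mapping used to
# convert ablation positions along an otolith transect into ages.

#' Construct a growth model
#'
#' Von Bertalanffy parameters plus a linear otolith-radius/fish-length map.
#' The study species' parameters are not bundled as silent defaults; supply the
#' published values for your stock (an example configuration ships in
#' `inst/extdata/example_config.json`).
#'
#' @param l_inf asymptotic length (cm), > 0.
#' @param k growth coefficient (1/year), > 0.
#' @param t0 theoretical age at length zero (years).
#' @param radius_slope otolith radius (um) per cm of fish length.
#' @param radius_intercept otolith radius (um) at length zero.
#' @return object of class `growth_model`.
#' @export
growth_model <- function(l_inf, k, t0 = 0, radius_slope = NULL,
                         radius_intercept = 0) {
  stopifnot(l_inf > 0, k > 0)
  structure(list(l_inf = l_inf, k = k, t0 = t0,
                 radius_slope = radius_slope,
                 radius_intercept = radius_intercept),
            class = "growth_model")
}

#' Age from length (inverse von Bertalanffy)
#'
#' \eqn{t = t_0 - \log(1 - L/L_\infty)/k}. Undefined at or above `l_inf`.
#'
#' @param length total length (cm), in (0, l_inf).
#' @param gm a [growth_model()].
#' @return age in years.
#' @export
age_from_length <- function(length, gm) {
  if (any(length <= 0)) stop("length must be > 0")
  if (any(length >= gm$l_inf)) stop("length >= l_inf: inverse growth model undefined")
  gm$t0 - log(1 - length / gm$l_inf) / gm$k
}

#' Length at age (von Bertalanffy)
#' @param age age in years.
#' @param gm a [growth_model()].
#' @return total length (cm).
#' @export
length_from_age <- function(age, gm) {
  gm$l_inf * (1 - exp(-gm$k * (age - gm$t0)))
}

#' Fish length from otolith radius (linear map)
#' @param radius otolith radius in micrometres.
#' @param gm a [growth_model()] with radius parameters set.
#' @return length in cm.
#' @export
length_from_radius <- function(radius, gm) {
  if (is.null(gm$radius_slope)) stop("growth model has no radius-length parameters")
  (radius - gm$radius_intercept) / gm$radius_slope
}

#' Otolith radius from fish length (linear map)
#' @param length length in cm.
#' @param gm a [growth_model()].
#' @return radius in micrometres.
#' @export
radius_from_length <- function(length, gm) {
  if (is.null(gm$radius_slope)) stop("growth model has no radius-length parameters")
  gm$radius_intercept + gm$radius_slope * length
}

#' Age map over ablation indices
#'
#' Returns a function `f(index) -> age (years)` assuming evenly spaced
#' ablations starting at the core: distance of ablation i is
#' `(i - 1) * spacing`. Age at an ablation is
#' `age_from_length(length_from_radius(distance))`; distances that map to
#' non-positive lengths (the core ablation) get age 0. The mapping is a plain
#' function so callers can substitute any other ablation-age model.
#'
#' @param gm a [growth_model()] with radius parameters.
#' @param spacing_um ablation spacing in micrometres (default 95).
#' @return function mapping ablation index to age in years.
#' @export
age_map_from_growth <- function(gm, spacing_um = 95) {
  force(gm); force(spacing_um)
  function(index) {
    d <- (index - 1) * spacing_um
    len <- pmin(length_from_radius(d, gm), gm$l_inf * (1 - 1e-9))
    ifelse(len <= 0, 0, gm$t0 - log(1 - len / gm$l_inf) / gm$k)
  }
}
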