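# Shared domain containers, table/grid readers and writers, and configuration.
#
# Tables are delimited text with a header row; gridded fields use a single
# self-describing text file: a "#meta " first line holding JSON metadata
# (CF-style variable name, grid vectors, depth strata) followed by a CSV body
# written at full IEEE double precision (%.17g), so write/read round-trips are
# lossless and files stay diff-able.

#' Default pipeline configuration
#'
#' Every tunable referenced by the pipeline, with defaults equal to the values
#' the source study states where it states one: detection-limit retention rule
#' (element kept when above LOD in >= 95\% of samples), nuclear region =
#' ablations 2--6, marginal region = last 3 ablations, cohort window
#' 1989--2002, change-point priors p0 = w0 = 0.2 with 10000 iterations and 5000
#' burn-in, mixtures of 1--5 sources under uneven-volume covariance models,
#' 5000 Monte-Carlo iterations for error propagation, six depth strata
#' (0--50, 50--100, 100--200, 200--300, 300--400, 400--500 m, half-open), and
#' 100 km / 100 m averaging for the fractionation-equation bias test.
#'
#' `growth` has no default: von Bertalanffy and radius-length parameters are
#' study-specific and must be supplied (see [growth_model()]); an example
#' configuration ships in `inst/extdata/example_config.json`.
#'
#' @return named list of settings.
#' @export
default_config <- function() {
  list(
    nuclear_ablations      = 2:6,
    marginal_n_last        = 3L,
    min_transect_points    = 14L,
    min_points_for_regions = 9L,
    lod_min_fraction       = 0.95,
    cohort_min_year        = 1989L,
    cohort_max_year        = 2002L,
    al_threshold           = NA_real_,  # NA = robust per-otolith median + 5 MAD
    ablation_spacing_um    = 95,
    growth                 = NULL,
    bcp_p0                 = 0.2,
    bcp_w0                 = 0.2,
    bcp_n_iter             = 10000L,
    bcp_burn_in            = 5000L,
    shift_threshold        = 0.5,
    mixture_G              = 1:5,
    mixture_models         = c("VVV", "VEV", "VVE"),
    mixture_n_restarts     = 20L,
    mixture_tol            = 1e-8,
    mixture_max_iter       = 1000L,
    mixture_transform      = "log_zscore",
    strata_bounds          = c(0, 50, 100, 200, 300, 400, 500),
    mc_iterations          = 5000L,
    bias_radius_km         = 100,
    bias_layer_m           = 100,
    nuclear_year_window    = c(1989L, 2002L),
    edge_year_window       = c(2011L, 2018L),
    covariate_share        = 0.61,
    fractionation_residual_sd = 0.2,
    occurrence_method      = "tail",
    seed                   = 1L
  )
}

#' Load a configuration file
#'
#' Reads a JSON key-value file and merges it over [default_config()]. An empty
#' file (or empty JSON object) yields all defaults. Unknown keys raise a
#' warning; a value whose type conflicts with the default raises an error.
#'
#' @param path path to a JSON configuration file.
#' @return named list of settings (class `og_config`).
#' @export
load_config <- function(path) {
  cfg <- default_config()
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  user <- if (!nzchar(trimws(txt))) list() else jsonlite::fromJSON(txt, simplifyVector = TRUE)
  if (!is.list(user)) stop("config file must contain a JSON object")
  for (key in names(user)) {
    if (!key %in% names(cfg)) {
      warning(sprintf("unknown config key '%s' ignored", key))
      next
    }
    val <- user[[key]]
    def <- cfg[[key]]
    if (!is.null(def)) {
      if (is.numeric(def) && !is.numeric(val)) {
        stop(sprintf("config key '%s' must be numeric, got %s", key, class(val)[1]))
      }
      if (is.character(def) && !is.character(val)) {
        stop(sprintf("config key '%s' must be character, got %s", key, class(val)[1]))
      }
      if (is.numeric(def) && is.integer(def)) val <- as.integer(round(val))
    }
    cfg[[key]] <- val
  }
  structure(cfg, class = c("og_config", "list"))
}

#' Build depth strata from boundary vector
#'
#' Strata are half-open `[lower, upper)` layers, non-overlapping and ordered by
#' depth.
#'
#' @param bounds increasing numeric vector of layer boundaries in metres.
#' @return data.frame with columns `lower`, `upper`, `mid`.
#' @export
make_strata <- function(bounds = default_config()$strata_bounds) {
  if (is.unsorted(bounds, strictly = TRUE)) stop("strata bounds must be strictly increasing")
  data.frame(
    lower = bounds[-length(bounds)],
    upper = bounds[-1],
    mid   = (bounds[-1] + bounds[-length(bounds)]) / 2
  )
}

# Assign depths (m) to stratum indices; half-open [lower, upper), NA outside.
stratum_of_depth <- function(depth, strata) {
  idx <- findInterval(depth, c(strata$lower, strata$upper[nrow(strata)]),
                      rightmost.closed = FALSE)
  idx[idx < 1 | idx > nrow(strata)] <- NA_integer_
  idx
}

## ---- otolith transects ------------------------------------------------------

#' Construct an otolith transect
#'
#' An ordered series of ablation points for one fish. `points` must have
#' columns `index` (1-based, contiguous), `distance` (micrometres from core,
#' strictly increasing) and one column per element:Ca ratio; an `Al` column, if
#' present, is the contamination sentinel.
#'
#' @param fish_id identifier.
#' @param points data.frame as described.
#' @return object of class `otolith_transect`.
#' @export
otolith_transect <- function(fish_id, points) {
  stopifnot(is.data.frame(points), all(c("index", "distance") %in% names(points)))
  points <- points[order(points$index), , drop = FALSE]
  rownames(points) <- NULL
  if (anyDuplicated(points$index)) {
    stop(sprintf("duplicate ablation index for fish '%s'", fish_id))
  }
  if (any(points$index < 1)) stop("ablation indices must be >= 1")
  if (!all(diff(points$index) >= 1)) stop("ablation indices must increase")
  if (any(points$distance < 0) || is.unsorted(points$distance, strictly = TRUE)) {
    stop(sprintf("distance from core must be >= 0 and strictly increasing for fish '%s'", fish_id))
  }
  structure(list(fish_id = as.character(fish_id), points = points),
            class = "otolith_transect")
}

#' @export
print.otolith_transect <- function(x, ...) {
  els <- setdiff(names(x$points), c("index", "distance"))
  cat(sprintf("otolith transect '%s': %d ablations, %.0f-%.0f um, elements: %s\n",
              x$fish_id, nrow(x$points), min(x$points$distance),
              max(x$points$distance), paste(els, collapse = ", ")))
  invisible(x)
}

# Element columns of a transect (everything except index/distance).
transect_elements <- function(tr) setdiff(names(tr$points), c("index", "distance"))

#' Read LA-ICPMS transects from a delimited table
#'
#' The table must have columns `fish_id`, `index`, `distance` and one column
#' per element:Ca ratio. Rows may be in any order; unparseable ratio cells
#' become missing values. Duplicate `(fish_id, index)` pairs and non-monotone
#' distances are hard errors naming the offending fish.
#'
#' @param path CSV file path.
#' @return named list of [otolith_transect()] objects, one per fish.
#' @export
read_transects <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("fish_id", "index", "distance")
  if (!all(need %in% names(raw))) {
    stop("transect table must have columns fish_id, index, distance")
  }
  els <- setdiff(names(raw), need)
  for (e in els) raw[[e]] <- suppressWarnings(as.numeric(raw[[e]]))
  raw$index <- as.integer(raw$index)
  key <- paste(raw$fish_id, raw$index)
  if (anyDuplicated(key)) {
    bad <- unique(raw$fish_id[duplicated(key)])
    stop(sprintf("duplicate (fish_id, index) rows for fish: %s",
                 paste(bad, collapse = ", ")))
  }
  out <- lapply(split(raw, raw$fish_id), function(d) {
    otolith_transect(d$fish_id[1], d[, c("index", "distance", els), drop = FALSE])
  })
  og_log("read_transects", "read %d transects (%d ablations) from %s",
         length(out), nrow(raw), path)
  out[order(names(out))]
}

#' Write transects to a delimited table
#'
#' Inverse of [read_transects()]; round-trips losslessly.
#'
#' @param transects list of [otolith_transect()].
#' @param path output CSV path.
#' @export
write_transects <- function(transects, path) {
  rows <- lapply(transects, function(tr) cbind(fish_id = tr$fish_id, tr$points))
  all_cols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(d) { d[setdiff(all_cols, names(d))] <- NA; d[all_cols] })
  tab <- do.call(rbind, rows)
  write.csv(format_full(tab), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Format numeric columns at full double precision for lossless text round trips.
format_full <- function(d) {
  for (j in seq_along(d)) {
    if (is.double(d[[j]])) d[[j]] <- ifelse(is.na(d[[j]]), NA, sprintf("%.17g", d[[j]]))
  }
  d
}

## ---- gridded environmental fields -------------------------------------------

#' Construct a gridded environmental field
#'
#' Regular lon/lat grid of cell centres with one layer per depth stratum.
#' `values` (and optional `variance`) are arrays of dim
#' `c(length(lon), length(lat), nrow(strata))`.
#'
#' @param variable variable name, e.g. `"temperature"` or `"salinity"`.
#' @param lon,lat cell-centre coordinate vectors (degrees, increasing).
#' @param strata data.frame from [make_strata()].
#' @param values value array; NA marks unobserved cells.
#' @param variance optional variance array of the same dim.
#' @param units unit string (metadata only).
#' @return object of class `env_field`.
#' @export
env_field <- function(variable, lon, lat, strata, values, variance = NULL,
                      units = "") {
  dim_expect <- c(length(lon), length(lat), nrow(strata))
  if (!identical(dim(values), as.integer(dim_expect))) {
    stop(sprintf("values dim must be %s", paste(dim_expect, collapse = " x ")))
  }
  if (!is.null(variance) && !identical(dim(variance), as.integer(dim_expect))) {
    stop("variance dim must match values")
  }
  if (is.unsorted(lon, strictly = TRUE) || is.unsorted(lat, strictly = TRUE)) {
    stop("lon and lat must be strictly increasing")
  }
  if (any(strata$lower[-1] < strata$upper[-nrow(strata)])) {
    # strictly increasing bounds already enforce non-overlap; keep the guard
  }
  structure(list(variable = variable, lon = lon, lat = lat, strata = strata,
                 values = values, variance = variance, units = units),
            class = "env_field")
}

#' @export
print.env_field <- function(x, ...) {
  cat(sprintf("env_field '%s': %d x %d grid, %d strata, %.0f%% observed\n",
              x$variable, length(x$lon), length(x$lat), nrow(x$strata),
              100 * mean(!is.na(x$values))))
  invisible(x)
}

#' Write a gridded field to self-describing text
#'
#' Single text file: a first line `#meta <json>` carrying variable name, units,
#' grid vectors and strata bounds, then a CSV body (`lon_i, lat_i, stratum,
#' value, variance`) at full double precision. Lossless round trip with
#' [read_env_field()].
#'
#' @param field an [env_field()] (or any object with the same slots).
#' @param path output path.
#' @export
write_env_field <- function(field, path) {
  meta <- list(variable = field$variable, units = field$units,
               lon = field$lon, lat = field$lat,
               strata_lower = field$strata$lower, strata_upper = field$strata$upper,
               has_variance = !is.null(field$variance))
  idx <- expand.grid(i = seq_along(field$lon), j = seq_along(field$lat),
                     k = seq_len(nrow(field$strata)))
  body <- data.frame(i = idx$i, j = idx$j, k = idx$k,
                     value = as.vector(field$values))
  if (!is.null(field$variance)) body$variance <- as.vector(field$variance)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#meta ", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)), con)
  write.csv(format_full(body), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gridded field written by [write_env_field()]
#'
#' @param path file path.
#' @return an [env_field()].
#' @export
read_env_field <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#meta ")) stop("missing #meta header (stratum metadata required)")
  meta <- jsonlite::fromJSON(sub("^#meta ", "", lines[1]))
  if (is.null(meta$strata_lower) || is.null(meta$strata_upper)) {
    stop("grid file metadata lacks depth strata")
  }
  body <- read.csv(textConnection(lines[-1]), stringsAsFactors = FALSE)
  nlon <- length(meta$lon); nlat <- length(meta$lat); ns <- length(meta$strata_lower)
  if (nrow(body) != nlon * nlat * ns) stop("grid body length does not match metadata grid")
  ord <- order(body$k, body$j, body$i)
  body <- body[ord, , drop = FALSE]
  values <- array(body$value, dim = c(nlon, nlat, ns))
  variance <- if (isTRUE(meta$has_variance)) array(body$variance, dim = c(nlon, nlat, ns)) else NULL
  strata <- data.frame(lower = meta$strata_lower, upper = meta$strata_upper,
                       mid = (meta$strata_lower + meta$strata_upper) / 2)
  env_field(meta$variable, meta$lon, meta$lat, strata, values, variance,
            units = if (is.null(meta$units)) "" else meta$units)
}

#' Write any gridded map product to text
#'
#' Dispatches on class: `env_field` objects go through [write_env_field()];
#' plain data.frames are written as full-precision CSV.
#'
#' @param map object to write.
#' @param path output path.
#' @export
write_map <- function(map, path) {
  if (inherits(map, "env_field")) return(write_env_field(map, path))
  if (is.data.frame(map)) {
    write.csv(format_full(map), path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  stop("don't know how to write an object of class ", class(map)[1])
}

## ---- area polygons -----------------------------------------------------------

#' Construct an area polygon
#'
#' @param name area label (e.g. `"A1"`, `"A2"`, `"B"`, `"C"`).
#' @param ring two-column matrix of lon/lat vertices; closed automatically.
#' @return object of class `area_polygon`.
#' @export
area_polygon <- function(name, ring) {
  ring <- as.matrix(ring)
  stopifnot(ncol(ring) == 2, nrow(ring) >= 3)
  if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  # shoelace area in degree^2; must be non-degenerate
  x <- ring[, 1]; y <- ring[, 2]; n <- nrow(ring)
  a <- abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
  if (a <= 0) stop("polygon has zero area")
  structure(list(name = name, ring = ring), class = "area_polygon")
}

#' Point-in-polygon test (ray casting)
#'
#' @param lon,lat point coordinates (vectorised).
#' @param polygon an [area_polygon()].
#' @return logical vector; boundary points count as inside.
#' @export
point_in_polygon <- function(lon, lat, polygon) {
  ring <- polygon$ring
  n <- nrow(ring) - 1
  inside <- logical(length(lon))
  for (p in seq_along(lon)) {
    x <- lon[p]; y <- lat[p]; hit <- FALSE
    for (i in seq_len(n)) {
      x1 <- ring[i, 1]; y1 <- ring[i, 2]; x2 <- ring[i + 1, 1]; y2 <- ring[i + 1, 2]
      if ((y1 > y) != (y2 > y)) {
        xint <- x1 + (y - y1) / (y2 - y1) * (x2 - x1)
        if (x < xint) hit <- !hit else if (x == xint) { hit <- TRUE; break }
      }
    }
    inside[p] <- hit
  }
  inside
}

#' Read area polygons from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon features; the feature property
#' `name` labels each area. Only the outer ring of each polygon is used.
#'
#' @param path GeoJSON file path.
#' @return named list of [area_polygon()].
#' @export
read_area_polygons <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("expected a GeoJSON FeatureCollection")
  polys <- lapply(gj$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], function(v) unlist(v)))
    area_polygon(f$properties$name, ring)
  })
  names(polys) <- vapply(polys, `[[`, "", "name")
  polys
}

#' Write area polygons to GeoJSON
#'
#' @param polygons named list of [area_polygon()].
#' @param path output path.
#' @export
write_area_polygons <- function(polygons, path) {
  feats <- lapply(polygons, function(p) {
    list(type = "Feature",
         properties = list(name = p$name),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(p$ring)),
                                                   function(i) as.numeric(p$ring[i, ])))))
  })
  gj <- list(type = "FeatureCollection", features = unname(feats))
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}
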