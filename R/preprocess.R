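# Sample filters, region extraction and ageing applied to raw transects and
# fish metadata before any inference.

#' Filter fish to a birth-cohort window
#'
#' Retains fish with `min_year <= birth_year <= max_year`. The default window
#' (1989--2002) restricts to cohorts young enough to limit interannual
#' variability in the study design this package implements.
#'
#' @param fish data.frame of fish records with a `birth_year` column.
#' @param min_year,max_year inclusive cohort bounds.
#' @return the retained subset (possibly empty, with a warning).
#' @export
cohort_filter <- function(fish, min_year = 1989, max_year = 2002) {
  if (is.null(fish$birth_year)) stop("fish records lack birth_year")
  keep <- fish$birth_year >= min_year & fish$birth_year <= max_year
  out <- fish[keep, , drop = FALSE]
  og_log("cohort_filter", "%d of %d fish retained (born %d-%d)",
         nrow(out), nrow(fish), min_year, max_year)
  if (nrow(out) == 0) warning("cohort filter removed every fish")
  out
}

#' Select elements above detection limits
#'
#' An element is retained iff the share of samples with value strictly above
#' its limit of detection is at least `min_fraction` (boundary inclusive: a
#' share of exactly 95\% retains).
#'
#' @param signatures data.frame with one column per candidate element.
#' @param lod_table named numeric vector of detection limits per element.
#' @param min_fraction minimum share of samples above LOD (default 0.95).
#' @param elements candidate element names; defaults to intersect of signature
#'   columns and `names(lod_table)` checked for completeness.
#' @return character vector of retained element names.
#' @export
select_elements <- function(signatures, lod_table, min_fraction = 0.95,
                            elements = NULL) {
  if (is.null(elements)) {
    elements <- intersect(names(signatures), names(signatures))
    elements <- setdiff(names(signatures),
                        c("fish_id", "region", "d18O", "d13C", "event", "Al"))
    elements <- elements[vapply(signatures[elements], is.numeric, TRUE)]
  }
  missing_lod <- setdiff(elements, names(lod_table))
  if (length(missing_lod)) {
    stop("no detection limit provided for element(s): ",
         paste(missing_lod, collapse = ", "))
  }
  share <- vapply(elements, function(e) {
    v <- signatures[[e]]
    mean(!is.na(v) & v > lod_table[[e]])
  }, 0)
  keep <- elements[share >= min_fraction]
  og_log("select_elements", "%d of %d elements above LOD in >= %.0f%% of samples: %s",
         length(keep), length(elements), 100 * min_fraction,
         paste(keep, collapse = ", "))
  keep
}

#' Remove Al-contaminated ablation points
#'
#' Points whose Al:Ca ratio exceeds a threshold are dropped. When
#' `al_threshold` is `NA` (the default configuration) a robust per-otolith
#' spike rule is used: median(Al) + 5 * MAD. A transect without an `Al` column
#' is returned unchanged with a warning.
#'
#' @param transect an [otolith_transect()].
#' @param al_threshold numeric threshold on Al:Ca, or `NA` for the robust rule.
#' @return the transect with contaminated points removed.
#' @export
exclude_contaminated <- function(transect, al_threshold = NA_real_) {
  pts <- transect$points
  if (!"Al" %in% names(pts)) {
    warning(sprintf("fish '%s': no Al data, contamination screen skipped",
                    transect$fish_id))
    return(transect)
  }
  al <- pts$Al
  thr <- if (is.na(al_threshold)) {
    median(al, na.rm = TRUE) + 5 * mad(al, na.rm = TRUE)
  } else al_threshold
  drop <- !is.na(al) & al > thr
  if (any(drop)) {
    og_log("exclude_contaminated", "fish '%s': %d of %d points removed (Al > %.3g)",
           transect$fish_id, sum(drop), nrow(pts), thr)
  }
  transect$points <- pts[!drop, , drop = FALSE]
  transect
}

#' Extract nuclear and marginal region signatures from a transect
#'
#' The nuclear signature is the unweighted mean of each element over the
#' ablations whose original index falls in `nuclear_ablations` (default 2--6;
#' ablation 1 is always excluded to minimise maternal effects). The marginal
#' signature is the mean over the last `marginal_n_last` surviving ablations.
#' Transects with fewer than `min_points` surviving points are dropped
#' (returns `NULL` with a log entry). Missing single elements propagate as
#' missing region values.
#'
#' @param transect an [otolith_transect()] (after contamination screening).
#' @param nuclear_ablations integer indices of the nuclear window.
#' @param marginal_n_last number of trailing ablations in the marginal window.
#' @param min_points minimum surviving points for a usable transect.
#' @return data.frame with two rows (`region` = nuclear, marginal) and one
#'   column per element, or `NULL` if the transect is unusable.
#' @export
extract_regions <- function(transect, nuclear_ablations = 2:6,
                            marginal_n_last = 3, min_points = 9) {
  pts <- transect$points
  if (nrow(pts) < min_points) {
    og_log("extract_regions", "fish '%s' dropped: %d surviving points < %d",
           transect$fish_id, nrow(pts), min_points)
    return(NULL)
  }
  els <- transect_elements(transect)
  nuc <- pts[pts$index %in% nuclear_ablations, els, drop = FALSE]
  mar <- pts[seq(nrow(pts) - marginal_n_last + 1, nrow(pts)), els, drop = FALSE]
  if (nrow(nuc) == 0) {
    og_log("extract_regions", "fish '%s' dropped: no surviving nuclear ablations",
           transect$fish_id)
    return(NULL)
  }
  mean_or_na <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = FALSE)
  out <- rbind(vapply(nuc, mean_or_na, 0), vapply(mar, mean_or_na, 0))
  out <- as.data.frame(out)
  data.frame(fish_id = transect$fish_id, region = c("nuclear", "marginal"), out,
             check.names = FALSE)
}

#' Region signatures for a set of transects
#'
#' Convenience wrapper: contamination screen + region extraction over a list of
#' transects, returning one long data.frame (fish dropped by the minimum-point
#' rule are logged and omitted).
#'
#' @inheritParams extract_regions
#' @param transects list of [otolith_transect()].
#' @param al_threshold see [exclude_contaminated()]; `NULL` skips the screen.
#' @return data.frame with columns `fish_id`, `region`, elements.
#' @export
extract_all_regions <- function(transects, nuclear_ablations = 2:6,
                                marginal_n_last = 3, min_points = 9,
                                al_threshold = NULL) {
  rows <- lapply(transects, function(tr) {
    if (!is.null(al_threshold)) tr <- exclude_contaminated(tr, al_threshold)
    extract_regions(tr, nuclear_ablations, marginal_n_last, min_points)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  og_log("extract_all_regions", "region signatures for %d of %d fish",
         length(rows), length(transects))
  out
}

#' Derive birth year and age at capture for fish records
#'
#' Ages each fish from its total length through the inverse von Bertalanffy
#' model and sets `birth_year = capture_year - round(age_at_capture)`.
#'
#' @param fish data.frame with `total_length` (cm) and `capture_date`
#'   (Date or ISO string).
#' @param gm a [growth_model()].
#' @return `fish` with `age_at_capture` and `birth_year` columns filled.
#' @export
age_fish <- function(fish, gm) {
  fish$age_at_capture <- age_from_length(fish$total_length, gm)
  cap_year <- as.integer(format(as.Date(fish$capture_date), "%Y"))
  fish$birth_year <- cap_year - round(fish$age_at_capture)
  fish
}
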