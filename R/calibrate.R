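#' Calibrate all event thresholds from a pre-industrial control run
#'
#' Builds a `threshold_set` holding, per cell, everything needed to classify
#' the four extreme event types against the control climate:
#' the day-of-year 90th-percentile temperature curve and the HWMId magnitude
#' quartiles; the control annual-HWMId distribution and its extreme level;
#' the pooled-month soil-moisture drought level; GEV parameters of annual
#' maximum outflow and the flood return level; the annual burned-area
#' wildfire level; and the dryness mask. Only the components whose forcing
#' fields are present in `control` are calibrated. The full supplied control
#' series is used for calibration.
#'
#' The upper-tail percentile `q` (default 97.5) is mirrored to `100 - q` for
#' the drought (lower) tail, and the flood return period is `100 / (100 - q)`
#' years (40 years at the default), so a single `q` drives the whole
#' sensitivity configuration.
#'
#' @param control A `sim_run` control simulation (see [generate_control()]).
#' @param q Upper-tail percentile in (50, 100).
#' @param doy_q,doy_window Day-of-year heatwave threshold percentile and
#'   window (days).
#' @param drought_min_run Minimum consecutive below-level months.
#' @param dryness_cutoff Discharge cutoff in mm/day.
#' @param min_flood_fraction Minimum flooded area, percent of cell area.
#' @param per_month_drought If `TRUE`, calibrate the drought level per
#'   calendar month instead of from all pooled control months.
#' @return An object of class `threshold_set`.
#' @export
calibrate_thresholds <- function(control, q = 97.5, doy_q = 90,
                                 doy_window = 31L, drought_min_run = 3L,
                                 dryness_cutoff = 0.1, min_flood_fraction = 1,
                                 per_month_drought = FALSE) {
  stopifnot(inherits(control, "sim_run"))
  if (q <= 50 || q >= 100)
    stop("q must lie in (50, 100)", call. = FALSE)
  f <- control$fields
  ts <- list(config = list(q = q, doy_q = doy_q, doy_window = doy_window,
                           drought_min_run = drought_min_run,
                           dryness_cutoff = dryness_cutoff,
                           min_flood_fraction = min_flood_fraction,
                           per_month_drought = per_month_drought,
                           control_years = control$n_years))
  if (!is.null(f$tasmax)) {
    ts$hw_doy <- calibrate_doy_percentile(f$tasmax, doy_q, doy_window)
    qr <- hwmid_reference_quartiles(f$tasmax)
    ts$hw_q25 <- qr$q25
    ts$hw_q75 <- qr$q75
    ts$control_hwmid <- hwmid_series(f$tasmax, ts$hw_doy, qr$q25, qr$q75)
  }
  if (!is.null(f$soil_moisture)) {
    ts$control_soil_moisture <- f$soil_moisture
  }
  if (!is.null(f$outflow)) {
    am <- daily_to_annual(f$outflow, max)
    ts$control_annmax_outflow <- am
    ts$gev <- fit_gev_annual_maxima(annual_maxima = am,
                                    return_period = 100 / (100 - q))
  }
  if (!is.null(f$burned_area)) {
    ts$control_burned_area <- f$burned_area
  }
  if (!is.null(f$discharge)) {
    ts$dryness_mask <- compute_dryness_mask(rowMeans(f$discharge),
                                            dryness_cutoff)
  }
  class(ts) <- "threshold_set"
  set_levels(ts, q)
}

# (Re)compute the percentile levels of a threshold_set at upper-tail q,
# reusing the stored control metric series; cheap, used by run_sensitivity.
set_levels <- function(ts, q) {
  p <- q / 100
  ts$config$q <- q
  if (!is.null(ts$control_hwmid))
    ts$hwmid_level <- row_quantile(ts$control_hwmid, p)
  if (!is.null(ts$control_soil_moisture)) {
    sm <- ts$control_soil_moisture
    if (isTRUE(ts$config$per_month_drought)) {
      ny <- ncol(sm) %/% 12L
      lev <- matrix(NA_real_, nrow(sm), 12L)
      for (m in seq_len(12L))
        lev[, m] <- row_quantile(sm[, m + 12L * (seq_len(ny) - 1L),
                                    drop = FALSE], 1 - p)
      ts$drought_level <- lev
    } else {
      ts$drought_level <- row_quantile(sm, 1 - p)
    }
  }
  if (!is.null(ts$gev)) {
    g <- ts$gev
    lev <- rep(NA_real_, nrow(g$params))
    ok <- g$usable & !is.na(g$params[, 1])
    lev[ok] <- qgev(p, g$params[ok, 1], g$params[ok, 2], g$params[ok, 3])
    ts$flood_level <- lev
    ts$flood_return_period <- 1 / (1 - p)
  }
  if (!is.null(ts$control_burned_area))
    ts$wildfire_level <- row_quantile(ts$control_burned_area, p)
  ts
}

#' @export
print.threshold_set <- function(x, ...) {
  have <- c(heatwave = !is.null(x$hwmid_level),
            drought = !is.null(x$drought_level),
            flood = !is.null(x$flood_level),
            wildfire = !is.null(x$wildfire_level))
  cat(sprintf(
    "threshold_set: q = %g, calibrated on %s control years; events: %s\n",
    x$config$q, x$config$control_years %||% "?",
    paste(names(have)[have], collapse = ", ")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

hazard_types <- c("heatwave", "drought", "flood", "wildfire")

#' Classify extreme event years for a simulation run
#'
#' Applies a calibrated [calibrate_thresholds()] `threshold_set` to a run's
#' forcing fields and returns, for each cell and year, whether each event
#' type occurred. Drought and flood classification apply the dryness mask;
#' flood additionally requires at least `min_flood_fraction` percent of the
#' cell to be flooded that year (when a `flooded_fraction` field is
#' available). When a grid with a land mask is supplied, ocean cells are
#' never flagged.
#'
#' @param run A `sim_run`.
#' @param thresholds A `threshold_set`.
#' @param types Event types to classify; defaults to every type whose
#'   forcing field and calibration are available.
#' @param grid Optional [haz_grid()] whose land mask is applied.
#' @return An object of class `event_matrix`: a list with `occ` (named list
#'   of logical `ncell x nyear` matrices), `years` (calendar years) and
#'   `combination_id`.
#' @export
detect_events <- function(run, thresholds, types = NULL, grid = NULL) {
  stopifnot(inherits(run, "sim_run"), inherits(thresholds, "threshold_set"))
  f <- run$fields
  avail <- c(
    heatwave = !is.null(f$tasmax) && !is.null(thresholds$hwmid_level),
    drought = !is.null(f$soil_moisture) && !is.null(thresholds$drought_level),
    flood = !is.null(f$outflow) && !is.null(thresholds$flood_level),
    wildfire = !is.null(f$burned_area) && !is.null(thresholds$wildfire_level))
  if (is.null(types)) types <- names(avail)[avail]
  if (!all(types %in% names(avail)[avail]))
    stop("requested event types lack forcing fields or calibration",
         call. = FALSE)
  dry <- thresholds$dryness_mask
  occ <- list()
  if ("heatwave" %in% types) {
    hw <- hwmid_series(f$tasmax, thresholds$hw_doy,
                       thresholds$hw_q25, thresholds$hw_q75)
    occ$heatwave <- !is.na(hw) & hw > thresholds$hwmid_level
  }
  if ("drought" %in% types) {
    lev <- thresholds$drought_level
    if (is.matrix(lev)) { # per-calendar-month levels
      ny <- ncol(f$soil_moisture) %/% 12L
      lev_series <- lev[, rep(seq_len(12L), ny), drop = FALSE]
      below <- f$soil_moisture < lev_series
      dr <- detect_drought_years(ifelse(below, -1, 1), 0,
                                 thresholds$config$drought_min_run)
    } else {
      dr <- detect_drought_years(f$soil_moisture, lev,
                                 thresholds$config$drought_min_run)
    }
    if (!is.null(dry)) dr <- dr & dry
    occ$drought <- dr
  }
  if ("flood" %in% types) {
    am <- daily_to_annual(f$outflow, max)
    occ$flood <- classify_flood_years(
      am, thresholds$flood_level, f$flooded_fraction, dry,
      thresholds$config$min_flood_fraction)
  }
  if ("wildfire" %in% types) {
    occ$wildfire <- f$burned_area > thresholds$wildfire_level
  }
  if (!is.null(grid)) {
    land <- as.vector(grid$land_mask)
    occ <- lapply(occ, function(m) { m[!land, ] <- FALSE; m })
  }
  structure(list(occ = occ,
                 years = run$start_year + seq_len(run$n_years) - 1L,
                 combination_id = run$combination_id %||%
                   paste(run$climate_model_id, run$impact_model_id, sep = "_")),
            class = "event_matrix")
}

#' @export
print.event_matrix <- function(x, ...) {
  cat(sprintf("event_matrix [%s]: %d cells x %d years; types: %s\n",
              x$combination_id, nrow(x$occ[[1]]), length(x$years),
              paste(names(x$occ), collapse = ", ")))
  invisible(x)
}

#' Percentile sensitivity analysis
#'
#' Re-runs calibration levels and event classification across a set of
#' upper-tail percentiles (mirrored to the lower tail for droughts and
#' mapped to the matching return period for floods). Event counts are
#' non-increasing in `q` because the flagged sets are nested.
#'
#' @param control A control `sim_run` (calibration input).
#' @param run The run to classify.
#' @param q_values Upper-tail percentiles.
#' @param thresholds Optionally, a pre-calibrated `threshold_set` for
#'   `control` to avoid recalibrating the expensive components.
#' @param ... Passed to [calibrate_thresholds()].
#' @return Named list of [detect_events()] results, one per percentile.
#' @export
run_sensitivity <- function(control, run, q_values = c(95, 97.5, 99),
                            thresholds = NULL, ...) {
  if (is.null(thresholds))
    thresholds <- calibrate_thresholds(control, q = q_values[1], ...)
  out <- lapply(q_values, function(q)
    detect_events(run, set_levels(thresholds, q)))
  names(out) <- paste0("q", q_values)
  out
}
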