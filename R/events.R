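# Temporal reduction helpers -------------------------------------------------

# Reduce an ncell x (block * nyear) matrix to ncell x nyear. `max` and `mean`
# take fast paths (max.col / rowMeans); any other function falls back to
# apply().  All daily fields use 365-day no-leap years.
block_reduce <- function(x, block, fun = max) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  nt <- ncol(x)
  if (nt %% block != 0)
    stop("series length is not a multiple of the block size", call. = FALSE)
  ny <- nt %/% block
  out <- matrix(NA_real_, nrow(x), ny)
  for (y in seq_len(ny)) {
    slice <- x[, ((y - 1) * block + 1):(y * block), drop = FALSE]
    out[, y] <- if (identical(fun, max)) {
      slice[cbind(seq_len(nrow(slice)), max.col(slice, ties.method = "first"))]
    } else if (identical(fun, mean)) {
      rowMeans(slice)
    } else {
      apply(slice, 1, fun)
    }
  }
  out
}

daily_to_annual <- function(x, fun = max) block_reduce(x, 365L, fun)
monthly_to_annual <- function(x, fun = mean) block_reduce(x, 12L, fun)

# row-wise type-7 quantile (Rcpp); accepts a vector as a one-row matrix
row_quantile <- function(x, p) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  .cpp_row_quantile(x, p)
}

# Run detection ---------------------------------------------------------------

#' Maximal runs of TRUE values
#'
#' Finds all maximal runs of consecutive `TRUE` values of at least
#' `min_len`; runs are non-overlapping by construction.
#'
#' @param x Logical vector.
#' @param min_len Minimum run length.
#' @return Data frame with columns `start` and `length`.
#' @export
detect_runs <- function(x, min_len = 3L) {
  stopifnot(is.logical(x), min_len >= 1)
  r <- rle(as.logical(x))
  ends <- cumsum(r$lengths)
  keep <- r$values & !is.na(r$values) & r$lengths >= min_len
  data.frame(start = (ends - r$lengths + 1L)[keep], length = r$lengths[keep])
}

#' Heatwave periods within one year
#'
#' A heatwave period is a run of at least three consecutive days on which
#' daily maximum temperature exceeds the day-of-year threshold (the 90th
#' percentile of control temperatures in a 31-day window). Periods are not
#' stitched across year boundaries.
#'
#' @param tasmax_year Numeric vector of 365 daily maximum temperatures.
#' @param threshold_curve Numeric vector of 365 day-of-year thresholds.
#' @param min_len Minimum period length in days.
#' @return Data frame with columns `start` (day of year) and `length`.
#' @export
detect_heatwave_periods <- function(tasmax_year, threshold_curve, min_len = 3L) {
  stopifnot(length(tasmax_year) == 365L, length(threshold_curve) == 365L)
  detect_runs(tasmax_year > threshold_curve, min_len)
}

# Day-of-year threshold calibration -------------------------------------------

#' Calibrate a day-of-year percentile threshold curve
#'
#' For each cell and each day of the year, the threshold is the empirical
#' q-th percentile of all control values whose day of year falls within a
#' centred window (default 31 days, i.e. 15 days either side), wrapping
#' across the December-January boundary, pooled over all control years.
#' Control series of at least 30 years are recommended for a stable curve.
#'
#' @param control_tasmax Numeric matrix `ncell x (365 * nyears)` of daily
#'   control temperatures, or a single daily series.
#' @param q Percentile in (0, 100); default 90.
#' @param window Odd window width in days.
#' @return `ncell x 365` threshold matrix (a vector for vector input).
#' @export
calibrate_doy_percentile <- function(control_tasmax, q = 90, window = 31L) {
  if (q <= 0 || q >= 100)
    stop("percentile q must lie strictly between 0 and 100", call. = FALSE)
  if (window %% 2 == 0 || window < 1)
    stop("window must be odd and positive", call. = FALSE)
  vec <- is.vector(control_tasmax)
  if (vec) control_tasmax <- matrix(control_tasmax, nrow = 1)
  out <- .cpp_doy_quantile(control_tasmax, q / 100, as.integer(window))
  if (vec) out[1, ] else out
}

# HWMId -----------------------------------------------------------------------

#' Annual heatwave magnitude index (HWMId)
#'
#' For each day `d` inside a heatwave period with temperature `T_d`, the
#' daily magnitude is `(T_d - Q25) / (Q75 - Q25)` when `T_d > Q25` and 0
#' otherwise, where `Q25` and `Q75` are the 25th and 75th percentiles of the
#' control run's annual maximum temperature series. A period's magnitude is
#' the sum of its daily magnitudes and the annual index is the maximum
#' period magnitude (0 in years without a heatwave period). The index grows
#' with both the severity and the persistence of heat extremes.
#'
#' @param tasmax_year Numeric vector of 365 daily maximum temperatures.
#' @param threshold_curve 365-value day-of-year threshold
#'   (see [calibrate_doy_percentile()]).
#' @param magnitude_quartiles Numeric length-2 vector `c(Q25, Q75)` from the
#'   control annual-maximum series.
#' @param min_len Minimum heatwave period length in days.
#' @return Non-negative scalar.
#' @export
hwmid_annual <- function(tasmax_year, threshold_curve, magnitude_quartiles,
                         min_len = 3L) {
  q25 <- magnitude_quartiles[1]; q75 <- magnitude_quartiles[2]
  if (q75 <= q25)
    stop("degenerate magnitude reference: Q75 must exceed Q25", call. = FALSE)
  periods <- detect_heatwave_periods(tasmax_year, threshold_curve, min_len)
  if (!nrow(periods)) return(0)
  md <- ifelse(tasmax_year > q25, (tasmax_year - q25) / (q75 - q25), 0)
  mags <- mapply(function(s, l) sum(md[s:(s + l - 1L)]),
                 periods$start, periods$length)
  max(mags)
}

#' Annual HWMId series for many cells
#'
#' Vectorised evaluation of [hwmid_annual()] for an `ncell x (365 * nyears)`
#' temperature matrix. Heatwave periods are confined to calendar years.
#' Cells with a degenerate magnitude reference (`Q75 <= Q25`) are returned
#' as `NA` with a warning.
#'
#' @param tasmax Matrix `ncell x (365 * nyears)`.
#' @param threshold_curves Matrix `ncell x 365`.
#' @param q25,q75 Per-cell magnitude quartiles.
#' @param min_len Minimum heatwave period length in days.
#' @return Matrix `ncell x nyears` of annual HWMId values.
#' @export
hwmid_series <- function(tasmax, threshold_curves, q25, q75, min_len = 3L) {
  if (is.vector(tasmax)) tasmax <- matrix(tasmax, nrow = 1)
  if (is.vector(threshold_curves))
    threshold_curves <- matrix(threshold_curves, nrow = 1)
  ncell <- nrow(tasmax)
  ny <- ncol(tasmax) %/% 365L
  stopifnot(ncol(tasmax) == ny * 365L, ncol(threshold_curves) == 365L,
            length(q25) == ncell, length(q75) == ncell)
  out <- matrix(0, ncell, ny)
  iqr <- q75 - q25
  bad <- !is.na(iqr) & iqr <= 0
  if (any(bad)) {
    warning(sprintf("%d cell(s) with degenerate magnitude reference set to NA",
                    sum(bad)), call. = FALSE)
    out[bad, ] <- NA_real_
  }
  doy <- rep(seq_len(365L), ny)
  for (i in which(!bad & !is.na(iqr))) {
    x <- tasmax[i, ]
    ex <- x > threshold_curves[i, doy]
    md <- ifelse(x > q25[i], (x - q25[i]) / iqr[i], 0)
    # pad a FALSE day after each year so runs cannot cross year boundaries
    exp_ <- rbind(matrix(ex, 365L, ny), FALSE)
    mdp <- rbind(matrix(md, 365L, ny), 0)
    r <- rle(as.vector(exp_))
    ends <- cumsum(r$lengths)
    ok <- r$values & r$lengths >= min_len
    if (!any(ok)) next
    s <- (ends - r$lengths + 1L)[ok]
    e <- ends[ok]
    cs <- c(0, cumsum(as.vector(mdp)))
    mags <- cs[e + 1L] - cs[s]
    yrs <- (s - 1L) %/% 366L + 1L
    mx <- tapply(mags, yrs, max)
    out[i, as.integer(names(mx))] <- mx
  }
  out
}

# magnitude quartiles of the control annual-maximum temperature series
hwmid_reference_quartiles <- function(control_tasmax) {
  am <- daily_to_annual(control_tasmax, max)
  list(q25 = row_quantile(am, 0.25), q75 = row_quantile(am, 0.75))
}

# Generic percentile classification -------------------------------------------

#' Classify years as extreme against a control distribution
#'
#' A year is flagged when its annual metric strictly exceeds (upper tail) or
#' falls strictly below (lower tail) the q-th percentile of the control
#' series for the same cell. Ties never flag.
#'
#' @param annual_metric `ncell x nyear` matrix (or vector) of the candidate
#'   annual metric.
#' @param control_metric `ncell x nyear_control` matrix (or vector) of the
#'   control series; at least 40 control years are recommended.
#' @param q Percentile in (0, 100): e.g. 97.5 with `tail = "upper"` for
#'   heatwaves/wildfires, 2.5 with `tail = "lower"` for droughts.
#' @param tail `"upper"` or `"lower"`.
#' @return Logical matrix of the same shape as `annual_metric`.
#' @export
classify_extreme_years <- function(annual_metric, control_metric, q = 97.5,
                                   tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  if (q <= 0 || q >= 100)
    stop("percentile q must lie strictly between 0 and 100", call. = FALSE)
  vec <- is.vector(annual_metric)
  if (vec) annual_metric <- matrix(annual_metric, nrow = 1)
  if (is.vector(control_metric)) control_metric <- matrix(control_metric, nrow = 1)
  if (ncol(control_metric) == 0)
    stop("empty control series", call. = FALSE)
  stopifnot(nrow(control_metric) == nrow(annual_metric))
  level <- row_quantile(control_metric, q / 100)
  out <- if (tail == "upper") annual_metric > level else annual_metric < level
  if (vec) out[1, ] else out
}

# Drought ---------------------------------------------------------------------

#' Detect drought years from monthly soil moisture
#'
#' A year is a drought year when soil moisture stays strictly below the
#' calibrated level (default the 2.5th percentile of all pooled control
#' months) for at least `min_run` consecutive months within the calendar
#' year; runs spanning the December-January boundary count toward neither
#' year unless at least `min_run` of their months fall inside one year.
#'
#' @param soil_moisture `ncell x (12 * nyears)` monthly matrix (or a single
#'   monthly series).
#' @param level Per-cell drought level (soil-moisture value).
#' @param min_run Minimum consecutive below-level months.
#' @return Logical `ncell x nyears` matrix (vector for vector input).
#' @export
detect_drought_years <- function(soil_moisture, level, min_run = 3L) {
  vec <- is.vector(soil_moisture)
  if (vec) soil_moisture <- matrix(soil_moisture, nrow = 1)
  ncell <- nrow(soil_moisture)
  ny <- ncol(soil_moisture) %/% 12L
  stopifnot(ncol(soil_moisture) == ny * 12L, length(level) %in% c(1L, ncell))
  level <- rep_len(level, ncell)
  out <- matrix(FALSE, ncell, ny)
  for (i in seq_len(ncell)) {
    below <- soil_moisture[i, ] < level[i]
    bp <- rbind(matrix(below, 12L, ny), FALSE) # break runs at year ends
    r <- rle(as.vector(bp))
    ends <- cumsum(r$lengths)
    ok <- r$values & r$lengths >= min_run
    if (!any(ok)) next
    yrs <- ((ends - r$lengths + 1L)[ok] - 1L) %/% 13L + 1L
    out[i, unique(yrs)] <- TRUE
  }
  if (vec) out[1, ] else out
}

#' Dryness mask from annual mean discharge
#'
#' Cells whose annual mean discharge is below the cutoff (default 0.1 mm per
#' day) are excluded from drought and flood classification. The boundary
#' value itself is retained (strict "below").
#'
#' @param discharge Per-cell annual mean discharge (mm/day), non-negative.
#' @param cutoff Exclusion cutoff in mm/day.
#' @return Logical vector, `TRUE` for retained cells.
#' @export
compute_dryness_mask <- function(discharge, cutoff = 0.1) {
  if (any(discharge < 0, na.rm = TRUE))
    stop("discharge must be non-negative", call. = FALSE)
  !(discharge < cutoff)
}
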