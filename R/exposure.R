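#' Event frequency over a 30-year window
#'
#' Counts flagged years per cell and event type in the window of `width`
#' years centred on `center` (the window covers `center - width/2` to
#' `center + width/2 - 1`; the 30-year baseline centred on 2000 spans
#' 1985-2014) and divides by the width. Counts are stored alongside the
#' width so downstream threshold comparisons can use exact fraction
#' arithmetic.
#'
#' @param events An [detect_events()] `event_matrix`.
#' @param center Central calendar year of the window.
#' @param width Window width in years.
#' @return An object of class `freq_field` with elements `counts` (named
#'   list of per-cell integer vectors), `width`, `center`, `types`,
#'   `combination_id`.
#' @export
window_frequency <- function(events, center, width = 30L) {
  stopifnot(inherits(events, "event_matrix"))
  yrs <- (center - width %/% 2):(center + width - width %/% 2 - 1L)
  if (!all(yrs %in% events$years))
    stop(sprintf("window %d-%d extends outside the available years %d-%d",
                 min(yrs), max(yrs), min(events$years), max(events$years)),
         call. = FALSE)
  idx <- match(yrs, events$years)
  counts <- lapply(events$occ, function(m)
    as.integer(rowSums(m[, idx, drop = FALSE])))
  structure(list(counts = counts, width = as.integer(width),
                 center = center, types = names(counts),
                 combination_id = events$combination_id),
            class = "freq_field")
}

#' Per-cell frequencies of a frequency field
#' @param ff A `freq_field`.
#' @param type Event type; default all types as a matrix `ncell x ntype`.
#' @return Numeric vector (one type) or matrix of frequencies in `[0, 1]`.
#' @export
frequencies <- function(ff, type = NULL) {
  stopifnot(inherits(ff, "freq_field"))
  if (!is.null(type)) {
    if (!type %in% ff$types) stop("unknown event type: ", type, call. = FALSE)
    return(ff$counts[[type]] / ff$width)
  }
  out <- sapply(ff$counts, function(cnt) cnt / ff$width)
  if (is.null(dim(out))) # single-cell grid: keep the cell x type shape
    out <- matrix(out, nrow = 1, dimnames = list(NULL, ff$types))
  out
}

#' @export
print.freq_field <- function(x, ...) {
  cat(sprintf("freq_field [%s] window %d +/- %d: %s\n",
              x$combination_id %||% "?", x$center, x$width %/% 2,
              paste(x$types, collapse = ", ")))
  invisible(x)
}

#' Change in event frequency between two windows
#'
#' @param future,baseline `freq_field` objects on the same grid with the
#'   same event types and width.
#' @return Matrix `ncell x ntype` of `future - baseline` frequency deltas in
#'   `[-1, 1]`.
#' @export
frequency_change <- function(future, baseline) {
  stopifnot(inherits(future, "freq_field"), inherits(baseline, "freq_field"))
  if (!identical(future$types, baseline$types) ||
      future$width != baseline$width ||
      length(future$counts[[1]]) != length(baseline$counts[[1]]))
    stop("frequency fields do not match (types, width or grid)", call. = FALSE)
  frequencies(future) - frequencies(baseline)
}

#' Ensemble mean, minimum and maximum
#'
#' Elementwise arithmetic mean, minimum and maximum across climate
#' model-impact model combinations; the inputs may be numeric vectors,
#' matrices, or `freq_field` objects (which are reduced per event type).
#' Order of combinations is immaterial, and min <= mean <= max elementwise.
#'
#' @param x List with one element per combination.
#' @return List with elements `mean`, `min`, `max`.
#' @export
ensemble_stats <- function(x) {
  if (!length(x)) stop("empty ensemble", call. = FALSE)
  if (inherits(x[[1]], "freq_field")) {
    mats <- lapply(x, frequencies)
  } else {
    mats <- x
  }
  arr <- simplify2array(mats)
  nd <- length(dim(arr))
  if (nd <= 1L || length(mats) == 1L) {
    arr <- simplify2array(lapply(mats, as.vector))
    if (is.null(dim(arr))) arr <- matrix(arr, nrow = 1)
    return(list(mean = rowMeans(arr),
                min = do.call(pmin, lapply(mats, as.vector)),
                max = do.call(pmax, lapply(mats, as.vector))))
  }
  list(mean = apply(arr, seq_len(nd - 1L), mean),
       min = apply(arr, seq_len(nd - 1L), min),
       max = apply(arr, seq_len(nd - 1L), max))
}

# Exact frequency-threshold comparison: a count of k flagged years out of
# `width` qualifies at `threshold` (per year) iff k >= threshold * width,
# evaluated with a conservative epsilon so 10/30 qualifies at 0.33
# regardless of float representation.
mh_qualifies <- function(counts, width, threshold) {
  counts >= threshold * width - 1e-9
}

#' Multi-hazard event-type count per cell
#'
#' Number of event types whose window frequency meets the qualification
#' threshold (default 0.33 per year, i.e. an event at least every third year
#' on average; 10 flagged years out of 30 qualifies). Thresholds between
#' 0.2 and 0.5 are supported for sensitivity analysis.
#'
#' @param ff A `freq_field` containing the event types to count.
#' @param threshold Qualification frequency, events per year.
#' @return Integer vector, one count in `0..ntype` per cell.
#' @export
multi_hazard_count <- function(ff, threshold = 0.33) {
  stopifnot(inherits(ff, "freq_field"))
  qual <- vapply(ff$counts, function(cnt)
    mh_qualifies(cnt, ff$width, threshold),
    logical(length(ff$counts[[1]])))
  if (is.null(dim(qual))) qual <- matrix(qual, nrow = 1)
  as.integer(rowSums(qual))
}

# area * overlap weights of a mask restricted to land cells, as a sparse
# (index, weight) pair on the flattened grid
mask_weights <- function(mask, grid, areas = NULL) {
  if (is.null(areas)) areas <- area_weights(grid)
  cl <- mask$cells
  on_land <- grid$land_mask[cbind(cl$row, cl$col)]
  cl <- cl[on_land, , drop = FALSE]
  idx <- cell_index(grid, cl$row, cl$col)
  w <- areas[cbind(cl$row, cl$col)] * cl$overlap
  list(idx = idx, w = w)
}

#' Exposure of one entity to one event type
#'
#' The proportion of an entity's geographic range (or ecoregion) exposed,
#' computed as the frequency-weighted, area-weighted, overlap-weighted mean
#' over grid cells: `sum(f_i a_i o_i) / sum(a_i o_i)` with `f_i` the window
#' event frequency, `a_i` the spherical cell area and `o_i` the overlap
#' fraction. Weighting by overlap avoids overestimating exposure for
#' small-ranged entities; only land cells contribute.
#'
#' @param freq Per-cell frequency vector on the flattened grid (see
#'   [frequencies()]), or any per-cell indicator in `[0, 1]`.
#' @param mask A [range_mask()].
#' @param grid A [haz_grid()].
#' @param areas Optional precomputed [area_weights()] matrix.
#' @return Exposure proportion in `[0, 1]`.
#' @export
entity_exposure <- function(freq, mask, grid, areas = NULL) {
  mw <- mask_weights(mask, grid, areas)
  denom <- sum(mw$w)
  if (denom <= 0)
    stop("entity has zero overlap-weighted land area (excluded entity)",
         call. = FALSE)
  sum(freq[mw$idx] * mw$w) / denom
}

#' Exposure of one entity to multiple event types
#'
#' Like [entity_exposure()] but with the per-cell indicator "at least
#' `min_types` event types qualify at `threshold`" in place of the
#' frequency, so the result is the proportion of the entity's area exposed
#' to `min_types` or more different extreme event types.
#'
#' @inheritParams entity_exposure
#' @param ff A `freq_field` with the event types to count.
#' @param min_types Minimum number of qualifying event types.
#' @param threshold Qualification frequency, events per year.
#' @return Exposure proportion in `[0, 1]`.
#' @export
entity_multi_exposure <- function(ff, mask, grid, areas = NULL,
                                  min_types = 2L, threshold = 0.33) {
  ind <- as.numeric(multi_hazard_count(ff, threshold) >= min_types)
  entity_exposure(ind, mask, grid, areas)
}

#' Count entities above an exposure cutoff
#'
#' @param exposures Data frame with at least an `exposure` column; grouping
#'   columns default to `taxon` when present, else `entity_kind`.
#' @param cutoff Exposure cutoff in `[0, 1]`; entities with
#'   `exposure >= cutoff` are counted.
#' @param by Grouping column name(s).
#' @return Data frame of group counts (column `n`).
#' @export
count_entities_above <- function(exposures, cutoff,
                                 by = intersect(c("taxon", "entity_kind"),
                                                names(exposures))[1]) {
  stopifnot("exposure" %in% names(exposures))
  sel <- exposures[exposures$exposure >= cutoff, , drop = FALSE]
  if (is.na(by) || is.null(by)) return(data.frame(n = nrow(sel)))
  counts <- table(factor(sel[[by]], levels = unique(exposures[[by]])))
  out <- data.frame(group = names(counts), n = as.integer(counts),
                    stringsAsFactors = FALSE)
  names(out)[1] <- by
  out
}
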