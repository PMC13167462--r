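#' Construct a range mask from a cell-fraction table
#'
#' A range mask records, for one entity (a species or an ecoregion), the
#' fraction of each grid cell covered by that entity's geometry. Masks are
#' stored sparsely: only cells with nonzero overlap are kept.
#'
#' @param grid A [haz_grid()].
#' @param cells Data frame with columns `row`, `col` (1-based grid indices)
#'   and `overlap` (fraction in `[0, 1]`).
#' @param entity_id Identifier for the entity.
#' @param entity_kind `"species"` or `"ecoregion"`.
#' @param taxon One of `"amphibian"`, `"bird"`, `"mammal"`, `"reptile"` or
#'   `"none"` (ecoregions).
#' @return An object of class `range_mask`.
#' @export
range_mask <- function(grid, cells, entity_id, entity_kind = "species",
                       taxon = "none") {
  entity_kind <- match.arg(entity_kind, c("species", "ecoregion"))
  taxon <- match.arg(taxon, c("amphibian", "bird", "mammal", "reptile", "none"))
  cells <- as.data.frame(cells)
  stopifnot(all(c("row", "col", "overlap") %in% names(cells)))
  nlat <- length(grid$lat_centers); nlon <- length(grid$lon_centers)
  if (nrow(cells)) {
    if (any(cells$row < 1 | cells$row > nlat | cells$col < 1 | cells$col > nlon))
      stop("cell indices outside the grid", call. = FALSE)
    if (any(!is.finite(cells$overlap)) ||
        any(cells$overlap < -1e-9) || any(cells$overlap > 1 + 1e-9))
      stop("overlap fractions must lie in [0, 1]", call. = FALSE)
    cells$overlap <- pmin(pmax(cells$overlap, 0), 1)
    cells <- cells[cells$overlap > 0, , drop = FALSE]
  }
  structure(
    list(entity_id = entity_id, entity_kind = entity_kind, taxon = taxon,
         cells = cells[c("row", "col", "overlap")]),
    class = "range_mask"
  )
}

#' @export
print.range_mask <- function(x, ...) {
  cat(sprintf("range_mask '%s' (%s/%s): %d cells, total overlap %.3f\n",
              x$entity_id, x$entity_kind, x$taxon, nrow(x$cells),
              sum(x$cells$overlap)))
  invisible(x)
}

# Sutherland-Hodgman clip of a polygon against an axis-aligned rectangle.
# Returns the clipped vertex lists; the clip region is convex so the result
# is a single polygon (possibly empty).
clip_polygon_rect <- function(px, py, xmin, xmax, ymin, ymax) {
  clip_edge <- function(px, py, inside, intersect) {
    n <- length(px)
    if (n == 0L) return(list(x = numeric(0), y = numeric(0)))
    outx <- numeric(0); outy <- numeric(0)
    ins <- inside(px, py)
    for (i in seq_len(n)) {
      j <- if (i == 1L) n else i - 1L
      if (ins[i]) {
        if (!ins[j]) {
          p <- intersect(px[j], py[j], px[i], py[i])
          outx <- c(outx, p[1]); outy <- c(outy, p[2])
        }
        outx <- c(outx, px[i]); outy <- c(outy, py[i])
      } else if (ins[j]) {
        p <- intersect(px[j], py[j], px[i], py[i])
        outx <- c(outx, p[1]); outy <- c(outy, p[2])
      }
    }
    list(x = outx, y = outy)
  }
  ix <- function(x1, y1, x2, y2, xc) c(xc, y1 + (y2 - y1) * (xc - x1) / (x2 - x1))
  iy <- function(x1, y1, x2, y2, yc) c(x1 + (x2 - x1) * (yc - y1) / (y2 - y1), yc)
  p <- clip_edge(px, py, function(x, y) x >= xmin,
                 function(...) ix(..., xc = xmin))
  p <- clip_edge(p$x, p$y, function(x, y) x <= xmax,
                 function(...) ix(..., xc = xmax))
  p <- clip_edge(p$x, p$y, function(x, y) y >= ymin,
                 function(...) iy(..., yc = ymin))
  clip_edge(p$x, p$y, function(x, y) y <= ymax,
            function(...) iy(..., yc = ymax))
}

# shoelace formula; vertices in order, not necessarily closed
polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3L) return(0)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Rasterize a polygon into per-cell overlap fractions
#'
#' Computes, for every grid cell intersecting the polygon's bounding box, the
#' fraction of the cell covered by the polygon via exact analytic
#' polygon-rectangle clipping (Sutherland-Hodgman) in longitude-latitude
#' coordinates. Fractions are areas in degree space divided by
#' `resolution^2`; because a cell is small, the planar fraction equals the
#' spherical fraction to high accuracy. Geometries crossing the antimeridian
#' are not supported.
#'
#' @param geometry A two-column matrix or data frame of polygon vertices
#'   `(lon, lat)` in order (closed or open ring), or `NULL`/zero rows for an
#'   empty geometry (which yields an empty mask).
#' @param grid A [haz_grid()].
#' @inheritParams range_mask
#' @return A [range_mask()]; cells with zero intersection are absent.
#' @export
rasterize_range <- function(geometry, grid, entity_id = "entity",
                            entity_kind = "species", taxon = "none") {
  empty <- data.frame(row = integer(0), col = integer(0), overlap = numeric(0))
  if (is.null(geometry) || NROW(geometry) == 0L)
    return(range_mask(grid, empty, entity_id, entity_kind, taxon))
  geometry <- as.matrix(geometry)
  if (ncol(geometry) != 2L || any(!is.finite(geometry)))
    stop("invalid geometry: need a finite two-column (lon, lat) vertex matrix",
         call. = FALSE)
  px <- geometry[, 1L]; py <- geometry[, 2L]
  # drop an explicit closing vertex
  n <- length(px)
  if (n > 1L && px[1L] == px[n] && py[1L] == py[n]) {
    px <- px[-n]; py <- py[-n]; n <- n - 1L
  }
  if (n < 3L)
    stop("invalid geometry: fewer than three distinct vertices", call. = FALSE)
  res <- grid$resolution
  lat <- grid$lat_centers; lon <- grid$lon_centers
  rows <- which(lat + res / 2 > min(py) & lat - res / 2 < max(py))
  cols <- which(lon + res / 2 > min(px) & lon - res / 2 < max(px))
  out <- empty
  for (ci in cols) {
    xmin <- lon[ci] - res / 2; xmax <- lon[ci] + res / 2
    for (ri in rows) {
      ymin <- lat[ri] - res / 2; ymax <- lat[ri] + res / 2
      cl <- clip_polygon_rect(px, py, xmin, xmax, ymin, ymax)
      a <- polygon_area(cl$x, cl$y)
      if (a > 0) {
        frac <- min(a / res^2, 1)
        out <- rbind(out, data.frame(row = ri, col = ci, overlap = frac))
      }
    }
  }
  range_mask(grid, out, entity_id, entity_kind, taxon)
}

# total overlap restricted to land cells
land_overlap <- function(mask, grid) {
  if (!nrow(mask$cells)) return(0)
  on_land <- grid$land_mask[cbind(mask$cells$row, mask$cells$col)]
  sum(mask$cells$overlap[on_land])
}

#' Exclude ranges with no footprint on the land grid
#'
#' Ranges whose total overlap with land cells is zero (for example species
#' restricted to small islands that the grid does not resolve) carry no
#' exposure information and are excluded. Re-filtering the kept set is
#' idempotent.
#'
#' @param ranges List of [range_mask()] objects built against `grid`.
#' @param grid A [haz_grid()].
#' @return A list with elements `kept` and `excluded` (lists of masks) and
#'   `summary`, a data frame of initial/excluded/kept counts per taxon.
#' @export
filter_unrepresented <- function(ranges, grid) {
  keep <- vapply(ranges, function(m) land_overlap(m, grid) > 0, logical(1))
  taxa <- vapply(ranges, function(m) m$taxon, character(1))
  lv <- unique(taxa)
  summary <- data.frame(
    taxon = lv,
    initial = as.integer(table(factor(taxa, lv))),
    excluded = as.integer(table(factor(taxa[!keep], lv))),
    stringsAsFactors = FALSE
  )
  summary$kept <- summary$initial - summary$excluded
  list(kept = ranges[keep], excluded = ranges[!keep], summary = summary)
}

#' Tally range exclusions per taxon
#'
#' Bookkeeping helper turning per-taxon initial range counts and excluded
#' (unrepresented) counts into kept counts and a grand total.
#'
#' @param initial Named integer vector of initial range counts per taxon.
#' @param excluded Named integer vector of excluded counts per taxon; names
#'   must match `initial`.
#' @return Data frame with columns `taxon`, `initial`, `excluded`, `kept`,
#'   plus an attribute `total_kept`.
#' @export
range_filter_summary <- function(initial, excluded) {
  stopifnot(!is.null(names(initial)), setequal(names(initial), names(excluded)))
  excluded <- excluded[names(initial)]
  if (any(excluded > initial) || any(excluded < 0))
    stop("excluded counts must lie in [0, initial]", call. = FALSE)
  out <- data.frame(taxon = names(initial),
                    initial = as.integer(initial),
                    excluded = as.integer(excluded),
                    kept = as.integer(initial - excluded),
                    stringsAsFactors = FALSE)
  attr(out, "total_kept") <- sum(out$kept)
  out
}

#' Species richness map
#'
#' Per-cell count of entities whose range mask has nonzero overlap with the
#' cell.
#'
#' @param masks List of [range_mask()] objects on a common grid.
#' @param grid A [haz_grid()].
#' @return Integer matrix `nlat x nlon`.
#' @export
richness_map <- function(masks, grid) {
  out <- matrix(0L, length(grid$lat_centers), length(grid$lon_centers))
  for (m in masks) {
    idx <- cbind(m$cells$row, m$cells$col)
    if (nrow(idx)) out[idx] <- out[idx] + 1L
  }
  out
}
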