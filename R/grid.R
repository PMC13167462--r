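#' Define a regular latitude-longitude analysis grid
#'
#' Constructs the cell-centre-registered grid on which all gridded fields,
#' event classifications and exposure statistics are defined. Cells span
#' `[centre - resolution/2, centre + resolution/2)` in both axes (half-open),
#' so adjacent cells never overlap and the antimeridian is never crossed by a
#' cell (geometries wrapping the antimeridian are not supported).
#'
#' @param lat0 Latitude of the southernmost cell centre (degrees).
#' @param lon0 Longitude of the westernmost cell centre (degrees).
#' @param nlat,nlon Number of rows (latitude) and columns (longitude).
#' @param resolution Cell size in degrees; the default 0.5 matches the
#'   resolution of harmonised global impact-model output.
#' @param land_mask Logical matrix `nlat x nlon`, `TRUE` for land cells.
#'   Defaults to all-land. Rows index latitude (south to north), columns
#'   longitude (west to east).
#' @return An object of class `haz_grid` with elements `lat_centers`,
#'   `lon_centers`, `resolution` and `land_mask`.
#' @examples
#' g <- haz_grid(lat0 = 30.25, lon0 = 10.25, nlat = 4, nlon = 4)
#' g
#' @export
haz_grid <- function(lat0 = -89.75, lon0 = -179.75, nlat = 360, nlon = 720,
                     resolution = 0.5, land_mask = NULL) {
  stopifnot(is.numeric(resolution), length(resolution) == 1L, resolution > 0,
            nlat >= 1, nlon >= 1)
  lat <- lat0 + (seq_len(nlat) - 1L) * resolution
  lon <- lon0 + (seq_len(nlon) - 1L) * resolution
  if (any(lat < -90 | lat > 90))
    stop("latitude centres must lie in [-90, 90]", call. = FALSE)
  if (any(lon < -180 | lon >= 180))
    stop("longitude centres must lie in [-180, 180)", call. = FALSE)
  if (abs(lat[1L]) > 90 - resolution / 2 + 1e-12 ||
      abs(lat[nlat]) > 90 - resolution / 2 + 1e-12)
    stop("cells must not extend beyond the poles", call. = FALSE)
  if (is.null(land_mask)) {
    land_mask <- matrix(TRUE, nlat, nlon)
  } else {
    land_mask <- as.matrix(land_mask)
    if (!is.logical(land_mask) ||
        !all(dim(land_mask) == c(nlat, nlon)))
      stop("land_mask must be a logical nlat x nlon matrix", call. = FALSE)
  }
  structure(
    list(lat_centers = lat, lon_centers = lon, resolution = resolution,
         land_mask = land_mask),
    class = "haz_grid"
  )
}

#' @export
print.haz_grid <- function(x, ...) {
  cat(sprintf(
    "haz_grid: %d x %d cells at %g deg, lat [%g, %g], lon [%g, %g], %d land cells\n",
    length(x$lat_centers), length(x$lon_centers), x$resolution,
    min(x$lat_centers), max(x$lat_centers),
    min(x$lon_centers), max(x$lon_centers), sum(x$land_mask)))
  invisible(x)
}

#' Number of cells in a grid
#' @param grid A [haz_grid()].
#' @return Integer cell count (`nlat * nlon`).
#' @export
n_cells <- function(grid) {
  length(grid$lat_centers) * length(grid$lon_centers)
}

# Flattened cell indexing follows R matrix column-major order:
# index = (col - 1) * nlat + row.  All per-cell field matrices use this order.
cell_index <- function(grid, row, col) {
  (col - 1L) * length(grid$lat_centers) + row
}

# latitude of every flattened cell, recycled down columns
cell_latitudes <- function(grid) {
  rep(grid$lat_centers, times = length(grid$lon_centers))
}

#' Spherical area of a grid cell band
#'
#' Exact area of a `resolution x resolution` cell centred at `latitude` on a
#' sphere of radius 6,371 km: `R^2 * dlambda * (sin(phi2) - sin(phi1))` with
#' `phi1, phi2` the cell's bounding latitudes in radians and `dlambda` the
#' longitudinal width in radians. The area depends on latitude only, is exact
#' (no small-angle approximation), and reduces to the familiar
#' `cos(latitude)` proportionality because
#' `sin(phi2) - sin(phi1) = 2 cos(phi_c) sin(dphi/2)`.
#'
#' @param latitude Cell-centre latitude(s), degrees.
#' @param resolution Cell size in degrees.
#' @return Cell area(s) in km^2.
#' @examples
#' cell_area(0) / cell_area(60)  # exactly 2
#' @export
cell_area <- function(latitude, resolution = 0.5) {
  stopifnot(resolution > 0)
  if (any(abs(latitude) > 90 - resolution / 2 + 1e-12))
    stop("latitude outside the valid band |lat| <= 90 - resolution/2",
         call. = FALSE)
  R <- 6371 # km, mean Earth radius
  phi1 <- (latitude - resolution / 2) * pi / 180
  phi2 <- (latitude + resolution / 2) * pi / 180
  dlam <- resolution * pi / 180
  R^2 * dlam * (sin(phi2) - sin(phi1))
}

#' Per-cell area weights for a grid
#'
#' @param grid A [haz_grid()].
#' @return Numeric matrix `nlat x nlon` of cell areas (km^2); constant along
#'   rows since area depends on latitude only.
#' @export
area_weights <- function(grid) {
  a <- cell_area(grid$lat_centers, grid$resolution)
  matrix(a, nrow = length(grid$lat_centers), ncol = length(grid$lon_centers))
}
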