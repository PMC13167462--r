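# Gridded fields, range-mask tables and configs are serialized as plain
# text: CSV with a commented metadata header for gridded fields, plain CSV
# for entity tables, YAML for configs.  Values are written with 17
# significant digits so numeric round trips are exact.

fmt_num <- function(x) {
  out <- formatC(x, format = "g", digits = 17)
  out[is.na(x)] <- "NA"
  out
}

#' Write a gridded field to a CSV file with metadata header
#'
#' @param field Numeric matrix `nlat x nlon` (or a flattened per-cell vector
#'   together with `grid`).
#' @param path Output path.
#' @param grid A [haz_grid()] describing the field's grid.
#' @param name Variable name recorded in the header.
#' @param units Units string recorded in the header.
#' @param meta Optional named list of extra scalar metadata.
#' @return `path`, invisibly.
#' @export
write_gridded <- function(field, path, grid, name = "field", units = "1",
                          meta = list()) {
  nlat <- length(grid$lat_centers); nlon <- length(grid$lon_centers)
  if (is.vector(field)) field <- matrix(field, nlat, nlon)
  stopifnot(identical(dim(field), c(nlat, nlon)))
  hdr <- c("#hazexposure_gridded v1",
           sprintf("#name: %s", name),
           sprintf("#units: %s", units),
           sprintf("#nlat: %d", nlat),
           sprintf("#nlon: %d", nlon),
           sprintf("#lat0: %s", fmt_num(grid$lat_centers[1])),
           sprintf("#lon0: %s", fmt_num(grid$lon_centers[1])),
           sprintf("#resolution: %s", fmt_num(grid$resolution)),
           vapply(names(meta), function(k)
             sprintf("#%s: %s", k, as.character(meta[[k]])), character(1)))
  idx <- which(!is.na(field) | is.na(field), arr.ind = TRUE) # all cells
  lines <- c(hdr, "row,col,value",
             paste(idx[, 1], idx[, 2], fmt_num(field[idx]), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gridded field written by [write_gridded()]
#'
#' @param path Input path.
#' @param grid Optional [haz_grid()]; when given, the file's grid header is
#'   validated against it.
#' @return List with `values` (numeric `nlat x nlon` matrix), `name`,
#'   `units`, `meta` (named character list) and `grid_spec`.
#' @export
read_gridded <- function(path, grid = NULL) {
  lines <- readLines(path)
  if (!length(lines) || lines[1] != "#hazexposure_gridded v1")
    stop(sprintf("parse error in '%s': not a hazexposure gridded file", path),
         call. = FALSE)
  hdr <- grep("^#", lines, value = TRUE)[-1]
  kv <- regmatches(hdr, regexec("^#([^:]+): ?(.*)$", hdr))
  meta <- stats::setNames(vapply(kv, `[`, character(1), 3),
                          vapply(kv, `[`, character(1), 2))
  need <- c("name", "units", "nlat", "nlon", "lat0", "lon0", "resolution")
  if (!all(need %in% names(meta)))
    stop(sprintf("parse error in '%s': missing header field(s) %s", path,
                 paste(setdiff(need, names(meta)), collapse = ", ")),
         call. = FALSE)
  nlat <- as.integer(meta[["nlat"]]); nlon <- as.integer(meta[["nlon"]])
  body <- utils::read.csv(text = lines[!grepl("^#", lines)])
  if (!all(c("row", "col", "value") %in% names(body)))
    stop(sprintf("parse error in '%s': missing data columns", path),
         call. = FALSE)
  if (!is.null(grid)) {
    ok <- nlat == length(grid$lat_centers) && nlon == length(grid$lon_centers) &&
      isTRUE(all.equal(as.numeric(meta[["lat0"]]), grid$lat_centers[1])) &&
      isTRUE(all.equal(as.numeric(meta[["lon0"]]), grid$lon_centers[1])) &&
      isTRUE(all.equal(as.numeric(meta[["resolution"]]), grid$resolution))
    if (!ok)
      stop(sprintf("grid mismatch: '%s' was written on a different grid", path),
           call. = FALSE)
  }
  values <- matrix(NA_real_, nlat, nlon)
  values[cbind(body$row, body$col)] <- body$value
  extra <- meta[setdiff(names(meta), need)]
  list(values = values, name = meta[["name"]], units = meta[["units"]],
       meta = as.list(extra),
       grid_spec = list(nlat = nlat, nlon = nlon,
                        lat0 = as.numeric(meta[["lat0"]]),
                        lon0 = as.numeric(meta[["lon0"]]),
                        resolution = as.numeric(meta[["resolution"]])))
}

#' Write range masks to a CSV table
#'
#' Columns: `entity_id`, `entity_kind`, `taxon`, `cell_row`, `cell_col`,
#' `overlap`.
#'
#' @param masks List of [range_mask()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_range_masks <- function(masks, path) {
  rows <- lapply(masks, function(m) {
    if (!nrow(m$cells))
      return(data.frame(entity_id = m$entity_id, entity_kind = m$entity_kind,
                        taxon = m$taxon, cell_row = NA_integer_,
                        cell_col = NA_integer_, overlap = NA_real_))
    data.frame(entity_id = m$entity_id, entity_kind = m$entity_kind,
               taxon = m$taxon, cell_row = m$cells$row,
               cell_col = m$cells$col, overlap = m$cells$overlap)
  })
  df <- do.call(rbind, rows)
  df$overlap <- fmt_num(df$overlap)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read range masks from a CSV table
#'
#' @param path Input path (format of [write_range_masks()]).
#' @param grid A [haz_grid()] the masks are defined on.
#' @return List of [range_mask()] objects.
#' @export
read_range_masks <- function(path, grid) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("entity_id", "entity_kind", "taxon", "cell_row", "cell_col",
            "overlap")
  if (!all(need %in% names(df)))
    stop(sprintf("parse error in '%s': missing column(s) %s", path,
                 paste(setdiff(need, names(df)), collapse = ", ")),
         call. = FALSE)
  ids <- unique(df$entity_id)
  lapply(ids, function(id) {
    sub <- df[df$entity_id == id, , drop = FALSE]
    cells <- sub[!is.na(sub$cell_row),
                 c("cell_row", "cell_col", "overlap"), drop = FALSE]
    names(cells) <- c("row", "col", "overlap")
    range_mask(grid, cells, entity_id = id, entity_kind = sub$entity_kind[1],
               taxon = sub$taxon[1])
  })
}

#' Write an exposure table to CSV
#'
#' @param exposures Data frame of exposure records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exposure_table <- function(exposures, path) {
  utils::write.csv(exposures, path, row.names = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Desk-scale defaults: a 20 x 20 cell grid at 0.5 degrees, a 100-year
#' control run, a 1985-2100 scenario, a 5 x 3 pseudo model ensemble, 200
#' synthetic species and 12 ecoregions; percentile 97.5, multi-hazard
#' threshold 0.33 per year, 30-year windows with baseline centred on 2000
#' and future windows centred on 2030/2050/2085.
#'
#' @return Nested configuration list accepted by [run_pipeline()].
#' @export
default_config <- function() {
  list(
    seed = 1,
    grid = list(lat0 = 30.25, lon0 = 10.25, nlat = 20, nlon = 20,
                resolution = 0.5, land_fraction = 0.7),
    events = c("heatwave", "drought", "flood", "wildfire"),
    q = 97.5,
    mh_threshold = 0.33,
    min_types = 2,
    window_width = 30,
    baseline_center = 2000,
    centers = c(2030, 2050, 2085),
    control_years = 100,
    scenario = list(tag = "ssp370", start_year = 1985, end_year = 2100,
                    trend = list(warming_rate = 0.4, drying_rate = 0.02,
                                 flow_scale_rate = 0.05,
                                 burn_scale_rate = 0.1, start_year = 2015)),
    ensemble = list(n_climate = 5, n_impact = 3),
    species = list(n = 200, n_offland = 3, size_min = 1, size_max = 60),
    ecoregions = list(n = 12),
    exposure_cutoff = 0.5
  )
}

validate_config <- function(config) {
  stopifnot(is.list(config))
  cfg <- utils::modifyList(default_config(), config)
  if (cfg$q <= 50 || cfg$q >= 100)
    stop("config: q must lie in (50, 100)", call. = FALSE)
  if (cfg$mh_threshold <= 0 || cfg$mh_threshold > 1)
    stop("config: mh_threshold must lie in (0, 1]", call. = FALSE)
  with(cfg, {
    stopifnot(control_years >= 30, window_width >= 1,
              ensemble$n_climate >= 1, ensemble$n_impact >= 1,
              scenario$end_year > scenario$start_year)
  })
  ny_scen <- cfg$scenario$end_year - cfg$scenario$start_year + 1
  half <- cfg$window_width %/% 2
  for (ctr in c(cfg$baseline_center, cfg$centers)) {
    if (ctr - half < cfg$scenario$start_year ||
        ctr + cfg$window_width - half - 1 > cfg$scenario$end_year)
      stop(sprintf("config: window centred on %d extends outside the scenario years", ctr),
           call. = FALSE)
  }
  cfg$scenario$n_years <- ny_scen
  cfg
}

#' Read and validate a pipeline configuration from YAML
#'
#' Missing entries fall back to [default_config()].
#'
#' @param path Path to a YAML file.
#' @return Validated configuration list.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}
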