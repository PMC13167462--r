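# Deterministic 31-bit sub-seed from a base seed and a list of labels
# (polynomial rolling hash mod 2^31 - 1). One independent substream per
# (variable, combination), so regenerating one variable never shifts the
# noise of another.
derive_seed <- function(base_seed, ...) {
  s <- paste(c(base_seed, ...), collapse = "|")
  h <- 17
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Stationary AR(1) field, ncell x n, marginal sd `sd`, lag-1 autocorrelation
# `phi`; column 1 drawn from the stationary distribution.
ar1_field <- function(ncell, n, phi, sd) {
  x <- matrix(0, ncell, n)
  x[, 1] <- stats::rnorm(ncell, 0, sd)
  if (n > 1) {
    eps <- matrix(stats::rnorm(ncell * (n - 1), 0, sd * sqrt(1 - phi^2)),
                  ncell, n - 1)
    for (t in 2:n) x[, t] <- phi * x[, t - 1] + eps[, t - 1]
  }
  x
}

#' Default parameters of the synthetic forcing generator
#'
#' Controls the statistical structure of the generated fields. Daily maximum
#' temperature is a latitude-dependent mean plus a seasonal sine plus AR(1)
#' noise (lag-1 autocorrelation 0.7, producing realistic multi-day heat
#' spells); monthly soil moisture is a bounded logistic transform of an AR(1)
#' process (autocorrelation 0.5, so dry spells persist for months); daily
#' outflow is lognormal with seasonal modulation and autocorrelated log
#' noise; annual burned area is a gamma-distributed cell fraction; annual
#' mean discharge is constant per cell from a wet/dry map; and the annual
#' flooded-area fraction is beta-distributed.
#'
#' @param tasmax_base Mean temperature at the equator, degrees C.
#' @param tasmax_lat_gradient Cooling per degree of absolute latitude.
#' @param tasmax_seasonal_amp,tasmax_seasonal_lat Seasonal amplitude
#'   intercept and per-degree-latitude increase, degrees C.
#' @param tasmax_ar1,tasmax_sd Daily noise autocorrelation and marginal sd.
#' @param sm_ar1,sm_sd Monthly soil-moisture latent AR(1) parameters.
#' @param outflow_log_mean,outflow_seasonal_amp,outflow_ar1,outflow_sd
#'   Log-scale outflow parameters.
#' @param burn_shape,burn_mean Gamma shape and mean of annual burned
#'   fraction.
#' @param flood_frac_shape1,flood_frac_shape2 Beta parameters of the annual
#'   flooded-area fraction.
#' @param discharge_wet,discharge_dry,dry_fraction Wet/dry annual mean
#'   discharge (mm/day) and the fraction of dry cells.
#' @return Named list of generator settings.
#' @export
forcing_params <- function(tasmax_base = 28, tasmax_lat_gradient = 0.4,
                           tasmax_seasonal_amp = 3, tasmax_seasonal_lat = 0.15,
                           tasmax_ar1 = 0.7, tasmax_sd = 3,
                           sm_ar1 = 0.5, sm_sd = 1,
                           outflow_log_mean = 1, outflow_seasonal_amp = 0.5,
                           outflow_ar1 = 0.5, outflow_sd = 0.6,
                           burn_shape = 1.2, burn_mean = 0.02,
                           flood_frac_shape1 = 2, flood_frac_shape2 = 18,
                           discharge_wet = 1, discharge_dry = 0.05,
                           dry_fraction = 0.1) {
  as.list(environment())
}

#' Scenario trend specification
#'
#' Deterministic trend components added to the stationary control process
#' from `start_year` onwards; an all-zero specification reproduces the
#' control statistics exactly (bit-identically under the same seed).
#'
#' @param warming_rate Degrees C per decade added to daily maximum
#'   temperature.
#' @param drying_rate Fractional soil-moisture decline per decade
#'   (multiplicative `1 - rate * decades`, floored at 0).
#' @param flow_scale_rate Multiplicative outflow trend per decade.
#' @param burn_scale_rate Multiplicative burned-area trend per decade.
#' @param start_year Calendar year from which the trends apply.
#' @return Object of class `trend_spec`.
#' @export
trend_spec <- function(warming_rate = 0, drying_rate = 0,
                       flow_scale_rate = 0, burn_scale_rate = 0,
                       start_year = 2015) {
  stopifnot(is.finite(warming_rate), is.finite(drying_rate),
            is.finite(flow_scale_rate), is.finite(burn_scale_rate))
  structure(as.list(environment()), class = "trend_spec")
}

all_forcing_variables <- c("tasmax", "soil_moisture", "outflow",
                           "burned_area", "discharge", "flooded_fraction")

# decades since trend start for a per-step time axis (years as fractions)
trend_decades <- function(year_frac, trend) {
  if (is.null(trend)) return(0)
  pmax(0, (year_frac - trend$start_year) / 10)
}

# Shared generator behind generate_control()/generate_scenario().  One
# seeded substream per variable; trends are deterministic additions on top
# of the identical stationary noise.
generate_run <- function(grid, n_years, seed, params = forcing_params(),
                         trend = NULL, start_year = 1850,
                         run_kind = "control", scenario_tag = "picontrol",
                         climate_model_id = "gcm1", impact_model_id = "gim1",
                         variables = all_forcing_variables) {
  nc <- n_cells(grid)
  lat <- cell_latitudes(grid)
  nd <- 365L * n_years
  nm <- 12L * n_years
  doy <- rep(seq_len(365L), n_years)
  day_year_frac <- start_year + (seq_len(nd) - 1) / 365
  month_year_frac <- start_year + (seq_len(nm) - 0.5) / 12
  ann_year_frac <- start_year + seq_len(n_years) - 0.5
  fields <- list()

  if ("tasmax" %in% variables) {
    set.seed(derive_seed(seed, "tasmax"))
    peak <- ifelse(lat >= 0, 196, 15) # mid-July / mid-January
    amp <- params$tasmax_seasonal_amp + params$tasmax_seasonal_lat * abs(lat)
    base <- params$tasmax_base - params$tasmax_lat_gradient * abs(lat)
    # seasonal cycle per cell: amp_i * cos(2*pi*(doy - peak_i)/365)
    season <- amp * cos(2 * pi * (matrix(doy, nc, nd, byrow = TRUE) - peak) / 365)
    x <- base + season + ar1_field(nc, nd, params$tasmax_ar1, params$tasmax_sd)
    if (!is.null(trend) && trend$warming_rate != 0)
      x <- x + trend$warming_rate *
        matrix(trend_decades(day_year_frac, trend), nc, nd, byrow = TRUE)
    fields$tasmax <- x
  }
  if ("soil_moisture" %in% variables) {
    set.seed(derive_seed(seed, "soil_moisture"))
    m <- stats::plogis(ar1_field(nc, nm, params$sm_ar1, params$sm_sd))
    if (!is.null(trend) && trend$drying_rate != 0) {
      fac <- pmax(0, 1 - trend$drying_rate *
                    trend_decades(month_year_frac, trend))
      m <- m * matrix(fac, nc, nm, byrow = TRUE)
    }
    fields$soil_moisture <- m
  }
  if ("outflow" %in% variables) {
    set.seed(derive_seed(seed, "outflow"))
    season <- params$outflow_seasonal_amp * sin(2 * pi * doy / 365)
    logq <- params$outflow_log_mean +
      matrix(season, nc, nd, byrow = TRUE) +
      ar1_field(nc, nd, params$outflow_ar1, params$outflow_sd)
    x <- exp(logq)
    if (!is.null(trend) && trend$flow_scale_rate != 0)
      x <- x * matrix(1 + trend$flow_scale_rate *
                        trend_decades(day_year_frac, trend), nc, nd,
                      byrow = TRUE)
    fields$outflow <- x
  }
  if ("burned_area" %in% variables) {
    set.seed(derive_seed(seed, "burned_area"))
    b <- matrix(stats::rgamma(nc * n_years, shape = params$burn_shape,
                              scale = params$burn_mean / params$burn_shape),
                nc, n_years)
    if (!is.null(trend) && trend$burn_scale_rate != 0)
      b <- b * matrix(1 + trend$burn_scale_rate *
                        trend_decades(ann_year_frac, trend), nc, n_years,
                      byrow = TRUE)
    fields$burned_area <- pmin(b, 1)
  }
  if ("discharge" %in% variables) {
    set.seed(derive_seed(seed, "discharge"))
    dry <- stats::runif(nc) < params$dry_fraction
    q <- ifelse(dry, params$discharge_dry, params$discharge_wet)
    fields$discharge <- matrix(q, nc, n_years)
  }
  if ("flooded_fraction" %in% variables) {
    set.seed(derive_seed(seed, "flooded_fraction"))
    fields$flooded_fraction <- matrix(
      stats::rbeta(nc * n_years, params$flood_frac_shape1,
                   params$flood_frac_shape2), nc, n_years)
  }

  structure(list(run_kind = run_kind, scenario_tag = scenario_tag,
                 climate_model_id = climate_model_id,
                 impact_model_id = impact_model_id,
                 combination_id = paste(climate_model_id, impact_model_id,
                                        sep = "_"),
                 calendar = "365_day", start_year = start_year,
                 n_years = n_years, seed = seed, fields = fields),
            class = "sim_run")
}

#' @export
print.sim_run <- function(x, ...) {
  cat(sprintf("sim_run [%s/%s] %s %d-%d (%d years): %s\n",
              x$climate_model_id, x$impact_model_id, x$scenario_tag,
              x$start_year, x$start_year + x$n_years - 1L, x$n_years,
              paste(names(x$fields), collapse = ", ")))
  invisible(x)
}

#' Generate a stationary pre-industrial control run
#'
#' Produces a seeded, trend-free simulation with the statistical structure
#' described in [forcing_params()]. Identical arguments give bit-identical
#' output.
#'
#' @param grid A [haz_grid()].
#' @param n_years Number of 365-day years (at least 30).
#' @param seed Integer seed.
#' @param params Generator settings from [forcing_params()].
#' @param start_year Calendar year of the first simulated year.
#' @param variables Which forcing fields to generate.
#' @return A `sim_run` with `run_kind = "control"`.
#' @export
generate_control <- function(grid, n_years, seed, params = forcing_params(),
                             start_year = 1850,
                             variables = all_forcing_variables) {
  if (n_years < 30)
    stop("control runs need at least 30 years", call. = FALSE)
  generate_run(grid, n_years, seed, params, trend = NULL,
               start_year = start_year, run_kind = "control",
               scenario_tag = "picontrol", variables = variables)
}

#' Generate a scenario run with injected trends
#'
#' Same stochastic process as [generate_control()] plus the deterministic
#' trend components of a [trend_spec()]; with an all-zero trend and the same
#' seed the output is bit-identical to the control process.
#'
#' @inheritParams generate_control
#' @param trend A [trend_spec()].
#' @param scenario_tag Label, e.g. `"ssp126"`, `"ssp370"`, `"ssp585"`.
#' @param start_year Calendar year of the first simulated year.
#' @return A `sim_run` with `run_kind = "scenario"`.
#' @export
generate_scenario <- function(grid, n_years, seed, trend = trend_spec(),
                              params = forcing_params(), start_year = 1985,
                              scenario_tag = "ssp370",
                              variables = all_forcing_variables) {
  stopifnot(inherits(trend, "trend_spec"))
  generate_run(grid, n_years, seed, params, trend = trend,
               start_year = start_year, run_kind = "scenario",
               scenario_tag = scenario_tag, variables = variables)
}

#' Enumerate a pseudo model ensemble
#'
#' Labels and per-combination seeds for `n_climate x n_impact` climate
#' model-impact model combinations. Seeds are derived deterministically from
#' `base_seed` and are pairwise distinct, so combinations can be generated
#' independently (and discarded after use when memory matters).
#'
#' @param n_climate,n_impact Ensemble dimensions (each at least 1).
#' @param base_seed Integer seed.
#' @return Data frame with columns `climate_model_id`, `impact_model_id`,
#'   `combination_id`, `seed`.
#' @export
ensemble_combinations <- function(n_climate, n_impact, base_seed) {
  stopifnot(n_climate >= 1, n_impact >= 1)
  g <- expand.grid(climate_model_id = sprintf("gcm%02d", seq_len(n_climate)),
                   impact_model_id = sprintf("gim%02d", seq_len(n_impact)),
                   stringsAsFactors = FALSE)
  g$combination_id <- paste(g$climate_model_id, g$impact_model_id, sep = "_")
  g$seed <- vapply(g$combination_id,
                   function(id) derive_seed(base_seed, id), integer(1))
  if (anyDuplicated(g$seed))
    g$seed <- g$seed + seq_len(nrow(g)) # exceedingly unlikely; keep distinct
  g
}

# Slightly perturb noise/seasonality settings per combination so ensemble
# members differ in structure, not just in noise realisation.
perturb_params <- function(params, seed) {
  set.seed(derive_seed(seed, "perturb"))
  keys <- c("tasmax_sd", "tasmax_seasonal_amp", "tasmax_ar1",
            "sm_sd", "outflow_sd", "burn_mean")
  for (k in keys) params[[k]] <- params[[k]] * stats::runif(1, 0.9, 1.1)
  params$tasmax_ar1 <- min(params$tasmax_ar1, 0.95)
  params
}

#' Generate a full pseudo ensemble of control and scenario runs
#'
#' Materialises every climate model-impact model combination with its own
#' perturbed generator settings, control run and scenario run. Intended for
#' desk-scale grids; for larger problems iterate over
#' [ensemble_combinations()] and generate each member on demand.
#'
#' @inheritParams generate_control
#' @param n_climate,n_impact Ensemble dimensions.
#' @param base_seed Integer seed.
#' @param n_years_control Control run length.
#' @param n_years_scenario Scenario run length.
#' @param scenario_start Calendar year of the first scenario year.
#' @param trend A [trend_spec()] applied to every member's scenario.
#' @return List of members, each with `combination_id`, `control` and
#'   `scenario`.
#' @export
generate_model_ensemble <- function(grid, n_climate = 5, n_impact = 3,
                                    base_seed = 1, n_years_control = 100,
                                    n_years_scenario = 116,
                                    scenario_start = 1985,
                                    trend = trend_spec(),
                                    params = forcing_params(),
                                    variables = all_forcing_variables) {
  combos <- ensemble_combinations(n_climate, n_impact, base_seed)
  lapply(seq_len(nrow(combos)), function(i) {
    cp <- perturb_params(params, combos$seed[i])
    list(combination_id = combos$combination_id[i],
         climate_model_id = combos$climate_model_id[i],
         impact_model_id = combos$impact_model_id[i],
         seed = combos$seed[i],
         control = generate_run(grid, n_years_control, combos$seed[i], cp,
                                run_kind = "control",
                                scenario_tag = "picontrol",
                                climate_model_id = combos$climate_model_id[i],
                                impact_model_id = combos$impact_model_id[i],
                                variables = variables),
         scenario = generate_run(grid, n_years_scenario, combos$seed[i], cp,
                                 trend = trend, start_year = scenario_start,
                                 run_kind = "scenario",
                                 scenario_tag = "scenario",
                                 climate_model_id = combos$climate_model_id[i],
                                 impact_model_id = combos$impact_model_id[i],
                                 variables = variables))
  })
}

#' Generate a synthetic land mask
#'
#' Thresholds a smooth random field (a sum of Gaussian bumps) so that
#' approximately `land_fraction` of cells are land, emulating contiguous
#' continents surrounded by ocean.
#'
#' @param grid A [haz_grid()].
#' @param land_fraction Target land fraction in (0, 1).
#' @param seed Integer seed.
#' @param n_bumps Number of Gaussian bumps.
#' @return Logical `nlat x nlon` matrix.
#' @export
synthetic_land_mask <- function(grid, land_fraction = 0.7, seed = 1,
                                n_bumps = 5) {
  stopifnot(land_fraction > 0, land_fraction < 1)
  set.seed(derive_seed(seed, "land_mask"))
  nlat <- length(grid$lat_centers); nlon <- length(grid$lon_centers)
  lat <- matrix(grid$lat_centers, nlat, nlon)
  lon <- matrix(grid$lon_centers, nlat, nlon, byrow = TRUE)
  field <- matrix(0, nlat, nlon)
  ext_lat <- diff(range(grid$lat_centers)) + grid$resolution
  ext_lon <- diff(range(grid$lon_centers)) + grid$resolution
  for (b in seq_len(n_bumps)) {
    c_lat <- stats::runif(1, min(grid$lat_centers), max(grid$lat_centers))
    c_lon <- stats::runif(1, min(grid$lon_centers), max(grid$lon_centers))
    w <- stats::runif(1, 0.15, 0.45) * max(ext_lat, ext_lon)
    field <- field + exp(-((lat - c_lat)^2 + (lon - c_lon)^2) / (2 * w^2))
  }
  field >= stats::quantile(field, 1 - land_fraction, type = 7)
}

# grow a contiguous random blob of `size` cells on `allowed` (logical matrix)
grow_blob <- function(allowed, start_row, start_col, size) {
  nlat <- nrow(allowed); nlon <- ncol(allowed)
  sel <- matrix(FALSE, nlat, nlon)
  sel[start_row, start_col] <- TRUE
  cells <- matrix(c(start_row, start_col), 1, 2)
  while (nrow(cells) < size) {
    nb <- do.call(rbind, apply(cells, 1, function(rc) {
      rbind(c(rc[1] - 1, rc[2]), c(rc[1] + 1, rc[2]),
            c(rc[1], rc[2] - 1), c(rc[1], rc[2] + 1))
    }, simplify = FALSE))
    ok <- nb[, 1] >= 1 & nb[, 1] <= nlat & nb[, 2] >= 1 & nb[, 2] <= nlon
    nb <- nb[ok, , drop = FALSE]
    ok <- allowed[nb] & !sel[nb]
    nb <- unique(nb[ok, , drop = FALSE])
    if (!nrow(nb)) break # blob boxed in; stop short
    pick <- nb[sample.int(nrow(nb), 1), , drop = FALSE]
    sel[pick] <- TRUE
    cells <- rbind(cells, pick)
  }
  cells
}

#' Generate synthetic species range masks
#'
#' Contiguous random blobs on the land mask with per-cell overlap fractions;
#' exactly `n_offland` additional ranges are placed entirely on ocean cells
#' to exercise the island-exclusion filter (these emulate small-island
#' species the grid does not resolve).
#'
#' @param grid A [haz_grid()] with a land mask.
#' @param n_species Number of on-land species ranges.
#' @param seed Integer seed.
#' @param size_dist List with `min` and `max` range size (cells); sizes are
#'   drawn log-uniformly.
#' @param n_offland Number of ranges placed entirely off land.
#' @return List of [range_mask()] objects with taxa assigned at random.
#' @export
generate_ranges <- function(grid, n_species = 200, seed = 1,
                            size_dist = list(min = 1, max = 60),
                            n_offland = 0) {
  set.seed(derive_seed(seed, "ranges"))
  land <- grid$land_mask
  if (n_offland > 0 && !any(!land))
    stop("grid has no ocean cells for off-land ranges", call. = FALSE)
  taxa <- c("amphibian", "bird", "mammal", "reptile")
  make_one <- function(id, allowed, taxon) {
    starts <- which(allowed, arr.ind = TRUE)
    st <- starts[sample.int(nrow(starts), 1), ]
    size <- max(1L, round(exp(stats::runif(1, log(size_dist$min),
                                           log(size_dist$max)))))
    cells <- grow_blob(allowed, st[1], st[2], size)
    range_mask(grid, data.frame(row = cells[, 1], col = cells[, 2],
                                overlap = stats::runif(nrow(cells), 0.3, 1)),
               entity_id = id, entity_kind = "species", taxon = taxon)
  }
  on_land <- lapply(seq_len(n_species), function(i)
    make_one(sprintf("sp_%04d", i), land, sample(taxa, 1)))
  off <- lapply(seq_len(n_offland), function(i)
    make_one(sprintf("island_sp_%03d", i), !land, sample(taxa, 1)))
  c(on_land, off)
}

#' Generate a synthetic ecoregion partition
#'
#' Partitions the land cells into `n_regions` contiguous-ish regions by
#' nearest-seed (Voronoi-like) assignment under great-circle distance. Every
#' land cell belongs to exactly one region with overlap 1, so per-cell
#' overlaps across regions sum to 1 on land.
#'
#' @param grid A [haz_grid()] with a land mask.
#' @param n_regions Number of regions (at most the number of land cells).
#' @param seed Integer seed.
#' @return List of [range_mask()] objects with `entity_kind = "ecoregion"`.
#' @export
generate_ecoregions <- function(grid, n_regions = 12, seed = 1) {
  set.seed(derive_seed(seed, "ecoregions"))
  land <- which(grid$land_mask, arr.ind = TRUE)
  if (n_regions > nrow(land))
    stop("n_regions exceeds the number of land cells", call. = FALSE)
  seeds <- land[sample.int(nrow(land), n_regions), , drop = FALSE]
  lat1 <- grid$lat_centers[land[, 1]] * pi / 180
  lon1 <- grid$lon_centers[land[, 2]] * pi / 180
  lat2 <- grid$lat_centers[seeds[, 1]] * pi / 180
  lon2 <- grid$lon_centers[seeds[, 2]] * pi / 180
  # haversine great-circle distance, land cells x seeds
  d <- outer(seq_along(lat1), seq_along(lat2), function(i, j) {
    dlat <- lat1[i] - lat2[j]; dlon <- lon1[i] - lon2[j]
    a <- sin(dlat / 2)^2 + cos(lat1[i]) * cos(lat2[j]) * sin(dlon / 2)^2
    2 * asin(pmin(1, sqrt(a)))
  })
  assign <- max.col(-d, ties.method = "first")
  lapply(seq_len(n_regions), function(r) {
    cells <- land[assign == r, , drop = FALSE]
    range_mask(grid, data.frame(row = cells[, 1], col = cells[, 2],
                                overlap = rep(1, nrow(cells))),
               entity_id = sprintf("eco_%03d", r), entity_kind = "ecoregion",
               taxon = "none")
  })
}
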