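fields_for_events <- function(events) {
  map <- list(heatwave = "tasmax",
              drought = c("soil_moisture", "discharge"),
              flood = c("outflow", "discharge", "flooded_fraction"),
              wildfire = "burned_area")
  unique(unlist(map[events]))
}

stage_msg <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(paste0("[hazexposure] ", fmt), ...))
}

#' Run the full synthetic exposure pipeline
#'
#' Chains synthesis, calibration, detection and exposure aggregation:
#' generates the grid, land mask, species ranges and ecoregions; then, for
#' every climate model-impact model combination, generates a control and a
#' scenario run, calibrates event thresholds on the control, classifies
#' extreme event years in the scenario, and reduces them to 30-year-window
#' frequencies; finally computes per-entity exposure (per event type and
#' multi-hazard) for every window, takes ensemble mean/min/max across
#' combinations, and summarises entity counts above the exposure cutoff.
#' Deterministic given the config seed. Combinations are generated one at a
#' time and discarded so memory stays bounded.
#'
#' @param config Configuration list (see [default_config()]); missing
#'   entries are filled with defaults.
#' @param out_dir Optional output directory; when given, the exposure table,
#'   ensemble-mean frequency maps, range masks, summary and provenance
#'   record are written there.
#' @param quiet Suppress stage messages.
#' @return List with `grid`, `species` (kept masks), `excluded_species`,
#'   `ecoregions`, `frequency` (per-combination list of `freq_field`s by
#'   window), `exposure` (data frame with ensemble statistics), `summary`,
#'   and `provenance`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         quiet = FALSE) {
  cfg <- validate_config(config)
  t0 <- Sys.time()

  # --- grid, ranges, ecoregions
  g0 <- haz_grid(cfg$grid$lat0, cfg$grid$lon0, cfg$grid$nlat, cfg$grid$nlon,
                 cfg$grid$resolution)
  land <- synthetic_land_mask(g0, cfg$grid$land_fraction, cfg$seed)
  grid <- haz_grid(cfg$grid$lat0, cfg$grid$lon0, cfg$grid$nlat, cfg$grid$nlon,
                   cfg$grid$resolution, land_mask = land)
  areas <- area_weights(grid)
  stage_msg(quiet, "grid %dx%d, %d land cells, seed %d",
            cfg$grid$nlat, cfg$grid$nlon, sum(land), cfg$seed)

  ranges <- generate_ranges(grid, cfg$species$n, cfg$seed,
                            size_dist = list(min = cfg$species$size_min,
                                             max = cfg$species$size_max),
                            n_offland = cfg$species$n_offland)
  flt <- filter_unrepresented(ranges, grid)
  species <- flt$kept
  ecoregions <- generate_ecoregions(grid, cfg$ecoregions$n, cfg$seed)
  entities <- c(species, ecoregions)
  stage_msg(quiet, "%d species kept (%d excluded off-land), %d ecoregions",
            length(species), length(flt$excluded), length(ecoregions))

  ent_meta <- data.frame(
    entity_id = vapply(entities, `[[`, character(1), "entity_id"),
    entity_kind = vapply(entities, `[[`, character(1), "entity_kind"),
    taxon = vapply(entities, `[[`, character(1), "taxon"),
    stringsAsFactors = FALSE)
  ent_w <- lapply(entities, mask_weights, grid = grid, areas = areas)
  ent_denom <- vapply(ent_w, function(w) sum(w$w), numeric(1))

  # --- per-combination detection and window frequencies
  combos <- ensemble_combinations(cfg$ensemble$n_climate,
                                  cfg$ensemble$n_impact, cfg$seed)
  trend <- do.call(trend_spec, cfg$scenario$trend)
  vars <- fields_for_events(cfg$events)
  centers <- c(cfg$baseline_center, cfg$centers)
  freq_by_combo <- vector("list", nrow(combos))
  names(freq_by_combo) <- combos$combination_id
  for (i in seq_len(nrow(combos))) {
    tci <- Sys.time()
    cp <- perturb_params(forcing_params(), combos$seed[i])
    control <- generate_run(grid, cfg$control_years, combos$seed[i], cp,
                            run_kind = "control", scenario_tag = "picontrol",
                            climate_model_id = combos$climate_model_id[i],
                            impact_model_id = combos$impact_model_id[i],
                            variables = vars)
    thresholds <- calibrate_thresholds(control, q = cfg$q)
    scen <- generate_run(grid, cfg$scenario$n_years, combos$seed[i], cp,
                         trend = trend, start_year = cfg$scenario$start_year,
                         run_kind = "scenario",
                         scenario_tag = cfg$scenario$tag,
                         climate_model_id = combos$climate_model_id[i],
                         impact_model_id = combos$impact_model_id[i],
                         variables = vars)
    ev <- detect_events(scen, thresholds, types = cfg$events, grid = grid)
    freq_by_combo[[i]] <- lapply(centers, function(ctr)
      window_frequency(ev, ctr, cfg$window_width))
    names(freq_by_combo[[i]]) <- as.character(centers)
    stage_msg(quiet, "combination %s: %d event types classified (%.1f s)",
              combos$combination_id[i], length(cfg$events),
              as.numeric(difftime(Sys.time(), tci, units = "secs")))
  }

  # --- per-combination exposures, then ensemble statistics
  n_ent <- length(entities)
  types <- c(cfg$events, "multihazard")
  expo <- array(NA_real_,
                c(n_ent, length(centers), length(types), nrow(combos)),
                dimnames = list(ent_meta$entity_id, as.character(centers),
                                types, combos$combination_id))
  for (k in seq_len(nrow(combos))) {
    for (w in seq_along(centers)) {
      ff <- freq_by_combo[[k]][[w]]
      fr <- frequencies(ff)
      mh <- as.numeric(multi_hazard_count(ff, cfg$mh_threshold) >=
                         cfg$min_types)
      for (e in seq_len(n_ent)) {
        mw <- ent_w[[e]]
        expo[e, w, , k] <- c(colSums(fr[mw$idx, , drop = FALSE] * mw$w),
                             sum(mh[mw$idx] * mw$w)) / ent_denom[e]
      }
    }
  }
  stage_msg(quiet, "exposure computed for %d entities x %d windows x %d types x %d combinations",
            n_ent, length(centers), length(types), nrow(combos))

  ens_mean <- apply(expo, 1:3, mean)
  ens_min <- apply(expo, 1:3, min)
  ens_max <- apply(expo, 1:3, max)
  rows <- expand.grid(entity = seq_len(n_ent), window = seq_along(centers),
                      type = seq_along(types))
  exposure <- data.frame(
    entity_id = ent_meta$entity_id[rows$entity],
    entity_kind = ent_meta$entity_kind[rows$entity],
    taxon = ent_meta$taxon[rows$entity],
    scenario = cfg$scenario$tag,
    window_center = centers[rows$window],
    event_type = types[rows$type],
    exposure = ens_mean[cbind(rows$entity, rows$window, rows$type)],
    ens_min = ens_min[cbind(rows$entity, rows$window, rows$type)],
    ens_max = ens_max[cbind(rows$entity, rows$window, rows$type)],
    stringsAsFactors = FALSE)
  base_idx <- match(cfg$baseline_center, centers)
  baseline <- ens_mean[cbind(rows$entity, rep(base_idx, nrow(rows)),
                             rows$type)]
  exposure$change <- exposure$exposure - baseline

  # --- summary
  summ <- stats::aggregate(
    cbind(exposure, ens_min, ens_max) ~ window_center + event_type + entity_kind,
    data = exposure, FUN = mean)
  counts <- do.call(rbind, lapply(centers, function(ctr) {
    do.call(rbind, lapply(types, function(tp) {
      sub <- exposure[exposure$window_center == ctr &
                        exposure$event_type == tp, ]
      cnt <- count_entities_above(sub, cfg$exposure_cutoff, by = "entity_kind")
      cnt$window_center <- ctr; cnt$event_type <- tp
      cnt
    }))
  }))
  summary <- list(mean_exposure = summ,
                  entities_above_cutoff = counts,
                  cutoff = cfg$exposure_cutoff)

  provenance <- list(
    package = "hazexposure",
    version = as.character(utils::packageVersion("hazexposure")),
    r_version = R.version.string,
    seed = cfg$seed,
    combination_seeds = stats::setNames(combos$seed, combos$combination_id),
    config = cfg,
    config_hash = config_hash(cfg),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  result <- list(grid = grid, species = species,
                 excluded_species = flt$excluded, ecoregions = ecoregions,
                 frequency = freq_by_combo, exposure = exposure,
                 summary = summary, provenance = provenance)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_exposure_table(exposure, file.path(out_dir, "exposure.csv"))
    write_range_masks(c(species, ecoregions),
                      file.path(out_dir, "range_masks.csv"))
    for (w in seq_along(centers)) {
      ens <- ensemble_stats(lapply(freq_by_combo, `[[`, w))
      for (tp in cfg$events)
        write_gridded(ens$mean[, tp], grid = grid,
                      path = file.path(out_dir,
                                       sprintf("freq_mean_%s_%d.csv", tp,
                                               centers[w])),
                      name = sprintf("%s_frequency", tp), units = "1/yr",
                      meta = list(window_center = centers[w],
                                  window_width = cfg$window_width))
    }
    utils::write.csv(counts, file.path(out_dir, "entities_above_cutoff.csv"),
                     row.names = FALSE)
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    stage_msg(quiet, "artifacts written to %s", out_dir)
  }
  result
}

# md5 of the canonical YAML rendering of the config (tools::md5sum works on
# files, so render to a tempfile)
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(cfg, tf)
  unname(tools::md5sum(tf))
}
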