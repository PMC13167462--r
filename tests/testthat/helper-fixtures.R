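# Small grids and runs shared across tests; everything is generated in code.

small_grid <- function(nlat = 6, nlon = 6, land_fraction = 0.6, seed = 1) {
  g0 <- haz_grid(30.25, 10.25, nlat, nlon)
  haz_grid(30.25, 10.25, nlat, nlon,
           land_mask = synthetic_land_mask(g0, land_fraction, seed))
}

# event_matrix built directly from per-type flag matrices (cells x years)
fake_events <- function(occ, start_year = 1985, combination_id = "test") {
  structure(list(occ = occ,
                 years = start_year + seq_len(ncol(occ[[1]])) - 1L,
                 combination_id = combination_id),
            class = "event_matrix")
}

# freq_field built directly from counts
fake_freq <- function(counts, width = 30L, center = 2000) {
  structure(list(counts = counts, width = as.integer(width), center = center,
                 types = names(counts), combination_id = "test"),
            class = "freq_field")
}
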