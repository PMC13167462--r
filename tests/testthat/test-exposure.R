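test_that("window frequencies divide flagged years by the window width", {
  occ <- matrix(FALSE, 2, 40)
  occ[1, seq(1, 30, by = 2)] <- TRUE # 15 of the first 30 years
  ev <- fake_events(list(heatwave = occ), start_year = 1985)
  ff <- window_frequency(ev, 2000, 30)
  expect_equal(frequencies(ff, "heatwave"), c(0.5, 0.0))
  occ2 <- matrix(TRUE, 1, 30)
  ev2 <- fake_events(list(heatwave = occ2), start_year = 1985)
  expect_equal(frequencies(window_frequency(ev2, 2000), "heatwave"), 1.0)
  expect_error(window_frequency(ev, 2020, 30), "outside")
})

test_that("frequency change is the future-minus-baseline difference", {
  base <- fake_freq(list(heatwave = c(0L, 3L)), center = 2000)
  fut <- fake_freq(list(heatwave = c(15L, 3L)), center = 2050)
  d <- frequency_change(fut, base)
  expect_equal(d[, "heatwave"], c(0.5, 0))
  expect_equal(frequency_change(base, base)[, "heatwave"], c(0, 0))
  lo <- fake_freq(list(heatwave = c(0L, 0L)))
  hi <- fake_freq(list(heatwave = c(30L, 30L)))
  expect_equal(frequency_change(lo, hi)[, "heatwave"], c(-1, -1))
  bad <- fake_freq(list(wildfire = c(1L, 2L)))
  expect_error(frequency_change(fut, bad), "match")
})

test_that("ensemble statistics are elementwise and order-invariant", {
  x <- list(0.2, 0.4, 0.9)
  es <- ensemble_stats(x)
  expect_equal(unname(c(es$mean, es$min, es$max)), c(0.5, 0.2, 0.9))
  one <- ensemble_stats(list(c(a = 0.3, b = 0.7)))
  expect_equal(one$mean, one$min)
  expect_equal(one$mean, one$max)
  perm <- ensemble_stats(rev(x))
  expect_equal(perm, es)
  expect_error(ensemble_stats(list()), "empty")
})

test_that("multi-hazard counts use exact fraction comparisons", {
  cnt <- list(heatwave = 15L, wildfire = 11L, drought = 7L, flood = 0L)
  ff <- fake_freq(cnt, width = 30) # freqs 0.50, 0.3667, 0.2333, 0.00
  expect_equal(multi_hazard_count(ff, 0.33), 2L)
  expect_equal(multi_hazard_count(ff, 0.2), 3L)
  expect_equal(multi_hazard_count(ff, 0.5), 1L)
  # 10 of 30 years (0.3333...) meets the 0.33 threshold exactly
  ff10 <- fake_freq(list(heatwave = 10L), width = 30)
  expect_equal(multi_hazard_count(ff10, 0.33), 1L)
  # non-increasing in the threshold; non-decreasing in any frequency
  for (th in c(0.2, 0.3, 0.4, 0.5))
    expect_gte(multi_hazard_count(ff, th), multi_hazard_count(ff, th + 0.01))
  ffup <- fake_freq(list(heatwave = 13L, wildfire = 11L, drought = 3L,
                         flood = 0L), width = 30)
  expect_gte(multi_hazard_count(ffup, 0.33), multi_hazard_count(ff, 0.33))
})

test_that("entity exposure is the area- and overlap-weighted frequency", {
  g <- haz_grid(30.25, 10.25, 4, 4)
  nc <- n_cells(g)
  # single-cell range with overlap 1: exposure equals the cell frequency
  m1 <- range_mask(g, data.frame(row = 2, col = 3, overlap = 1), "one")
  f <- rep(0, nc); f[(3 - 1) * 4 + 2] <- 0.37 # column-major flattened index
  expect_equal(entity_exposure(f, m1, g), 0.37)
  # two equal-area cells (same latitude), frequencies 0 and 1 -> 0.5
  m2 <- range_mask(g, data.frame(row = c(2, 2), col = c(1, 2),
                                 overlap = c(1, 1)), "two")
  f2 <- rep(0, nc); f2[(2 - 1) * 4 + 2] <- 1
  expect_equal(entity_exposure(f2, m2, g), 0.5)
  # 4-cell case with unequal areas and overlaps: hand-computed weighted sum
  rows <- c(1, 2, 3, 4); cols <- c(1, 1, 2, 3)
  ov <- c(0.2, 1, 0.5, 0.8)
  fr <- c(0.1, 0.4, 0.9, 0)
  m4 <- range_mask(g, data.frame(row = rows, col = cols, overlap = ov), "four")
  f4 <- rep(0, nc); f4[(cols - 1) * 4 + rows] <- fr
  a <- cell_area(g$lat_centers[rows], 0.5)
  expect_equal(entity_exposure(f4, m4, g), sum(fr * a * ov) / sum(a * ov))
  # bounded by the min and max in-range frequency
  expect_gte(entity_exposure(f4, m4, g), min(fr))
  expect_lte(entity_exposure(f4, m4, g), max(fr))
  # splitting one cell's overlap into two co-located entries is invariant
  msplit <- range_mask(g, data.frame(row = c(rows, 2), col = c(cols, 1),
                                     overlap = c(0.2, 0.6, 0.5, 0.8, 0.4)),
                       "split")
  expect_equal(entity_exposure(f4, msplit, g), entity_exposure(f4, m4, g))
  # empty / off-land range errors
  land <- matrix(TRUE, 4, 4); land[2, 3] <- FALSE
  gl <- haz_grid(30.25, 10.25, 4, 4, land_mask = land)
  expect_error(entity_exposure(f, m1, gl), "zero overlap")
})

test_that("multi-hazard exposure counts qualifying cells and nests in k", {
  g <- haz_grid(30.25, 10.25, 2, 2)
  counts <- list(heatwave = c(12L, 12L, 0L, 12L),
                 wildfire = c(11L, 0L, 0L, 12L),
                 drought = c(0L, 0L, 0L, 10L),
                 flood = c(0L, 0L, 0L, 0L))
  ff <- fake_freq(counts, width = 30)
  all4 <- range_mask(g, data.frame(row = c(1, 2, 1, 2), col = c(1, 1, 2, 2),
                                   overlap = rep(1, 4)), "all")
  got <- vapply(1:3, function(k)
    entity_multi_exposure(ff, all4, g, min_types = k), numeric(1))
  expect_true(all(diff(got) <= 1e-12)) # k = 1 >= k = 2 >= k = 3
  # cells qualifying at >= 2 types: cells 1 and 4 only
  mh <- multi_hazard_count(ff, 0.33)
  expect_equal(mh, c(2L, 1L, 0L, 3L))
  only1 <- range_mask(g, data.frame(row = 1, col = 1, overlap = 1), "c1")
  expect_equal(entity_multi_exposure(ff, only1, g, min_types = 2), 1.0)
  only3 <- range_mask(g, data.frame(row = 1, col = 2, overlap = 1), "c3")
  expect_equal(entity_multi_exposure(ff, only3, g, min_types = 2), 0.0)
})

test_that("entity counts above a cutoff match a brute-force filter", {
  set.seed(5)
  df <- data.frame(entity_id = sprintf("s%02d", 1:50),
                   taxon = sample(c("bird", "mammal"), 50, replace = TRUE),
                   exposure = runif(50))
  got <- count_entities_above(df, 0.5, by = "taxon")
  for (tx in unique(df$taxon)) {
    expect_equal(got$n[got$taxon == tx],
                 sum(df$exposure >= 0.5 & df$taxon == tx))
  }
  expect_equal(sum(count_entities_above(df, 0)$n), 50L)
  expect_equal(sum(count_entities_above(df, 1)$n),
               sum(df$exposure >= 1))
})

test_that("ecoregion exposures reconstruct the global land mean", {
  g <- small_grid(8, 8, land_fraction = 0.6, seed = 2)
  eco <- generate_ecoregions(g, 5, 17)
  set.seed(6)
  f <- runif(n_cells(g))
  aw <- area_weights(g)
  num <- den <- 0
  for (m in eco) {
    e <- entity_exposure(f, m, g)
    w <- sum(aw[cbind(m$cells$row, m$cells$col)] * m$cells$overlap)
    num <- num + e * w
    den <- den + w
  }
  land_mean <- sum(f[as.vector(g$land_mask)] * aw[g$land_mask]) /
    sum(aw[g$land_mask])
  expect_equal(num / den, land_mean, tolerance = 1e-12)
})
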