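test_that("control generation is deterministic and physically bounded", {
  g <- small_grid(4, 4)
  a <- generate_control(g, 30, 42)
  b <- generate_control(g, 30, 42)
  expect_identical(a, b)
  expect_true(all(a$fields$soil_moisture >= 0 & a$fields$soil_moisture <= 1))
  expect_true(all(a$fields$burned_area >= 0 & a$fields$burned_area <= 1))
  expect_true(all(a$fields$outflow > 0))
  expect_true(all(a$fields$discharge >= 0))
  expect_true(all(a$fields$flooded_fraction >= 0 &
                    a$fields$flooded_fraction <= 1))
  expect_error(generate_control(g, 20, 1), "at least 30")
})

test_that("control runs are stationary: fitted trend CI covers zero", {
  g <- haz_grid(30.25, 10.25, 2, 2)
  ctl <- generate_control(g, 500, 11, variables = "tasmax")
  ann <- colMeans(matrix(colMeans(ctl$fields$tasmax), 365, 500))
  fit <- summary(stats::lm(ann ~ seq_along(ann)))$coefficients
  slope <- fit[2, 1]; se <- fit[2, 2]
  expect_lt(abs(slope), 1.96 * se)
})

test_that("zero-trend scenarios reproduce the control process exactly", {
  g <- small_grid(3, 3)
  ctl <- generate_control(g, 40, 5)
  scen <- generate_scenario(g, 40, 5, trend_spec(), start_year = 1985)
  expect_identical(scen$fields, ctl$fields)
})

test_that("an imposed warming trend appears at the expected magnitude", {
  g <- haz_grid(30.25, 10.25, 2, 2)
  tr <- trend_spec(warming_rate = 0.5, start_year = 2000)
  scen <- generate_scenario(g, 80, 9, tr, start_year = 2000,
                            variables = "tasmax")
  x <- colMeans(scen$fields$tasmax)
  first <- mean(x[1:3650])
  last <- mean(x[(79 * 365 - 3649):(79 * 365 + 365)])
  # decade-mean trend midpoints sit 71 years apart: expect 0.5 * 7.1 = 3.55
  expect_equal(last - first, 3.55, tolerance = 0.15)
})

test_that("pseudo-ensembles have distinct seeds and ordered statistics", {
  combos <- ensemble_combinations(5, 3, 123)
  expect_equal(nrow(combos), 15L)
  expect_equal(anyDuplicated(combos$seed), 0L)
  expect_equal(nrow(ensemble_combinations(1, 1, 7)), 1L)

  g <- small_grid(3, 3)
  ens <- generate_model_ensemble(g, 2, 2, 3, n_years_control = 30,
                                 n_years_scenario = 30,
                                 variables = "burned_area")
  expect_equal(length(ens), 4L)
  stat <- lapply(ens, function(m) rowMeans(m$control$fields$burned_area))
  es <- ensemble_stats(stat)
  expect_true(all(es$min <= es$mean + 1e-12))
  expect_true(all(es$mean <= es$max + 1e-12))
})

test_that("synthetic ranges exercise the island-exclusion path", {
  g <- small_grid(8, 8, land_fraction = 0.5)
  rg <- generate_ranges(g, 20, 13, n_offland = 3)
  expect_equal(length(rg), 23L)
  flt <- filter_unrepresented(rg, g)
  expect_equal(length(flt$excluded), 3L)
  expect_identical(rg, generate_ranges(g, 20, 13, n_offland = 3))
  # single-cell species: overlap in (0, 1]
  one <- generate_ranges(g, 5, 2, size_dist = list(min = 1, max = 1))
  for (m in one) {
    expect_equal(nrow(m$cells), 1L)
    expect_gt(m$cells$overlap, 0)
    expect_lte(m$cells$overlap, 1)
  }
})

test_that("ecoregions partition the land cells", {
  g <- small_grid(8, 8, land_fraction = 0.6)
  eco <- generate_ecoregions(g, 5, 21)
  cover <- matrix(0, 8, 8)
  for (m in eco) cover[cbind(m$cells$row, m$cells$col)] <-
      cover[cbind(m$cells$row, m$cells$col)] + m$cells$overlap
  expect_equal(cover[g$land_mask], rep(1, sum(g$land_mask)))
  expect_equal(cover[!g$land_mask], rep(0, sum(!g$land_mask)))
  # areas conserved under the partition
  aw <- area_weights(g)
  region_area <- sum(vapply(eco, function(m)
    sum(aw[cbind(m$cells$row, m$cells$col)] * m$cells$overlap), numeric(1)))
  expect_equal(region_area, sum(aw[g$land_mask]))
  # one region is the land mask itself
  single <- generate_ecoregions(g, 1, 3)
  expect_equal(nrow(single[[1]]$cells), sum(g$land_mask))
  expect_error(generate_ecoregions(g, sum(g$land_mask) + 1, 1), "exceeds")
})
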