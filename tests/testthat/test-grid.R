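test_that("cell areas follow spherical geometry", {
  # cos-latitude rule is exact for the spherical band formula
  expect_equal(cell_area(0) / cell_area(60), 2.0)
  expect_equal(cell_area(30), cell_area(-30))
  # strictly decreasing in |latitude|
  lats <- seq(0.25, 89.25, by = 0.5)
  expect_true(all(diff(cell_area(lats)) < 0))
  expect_error(cell_area(90), "valid band")
  expect_error(cell_area(-89.999, resolution = 0.5), "valid band")
})

test_that("full-sphere cell areas sum to the analytic sphere area", {
  g <- haz_grid(lat0 = -89, lon0 = -179, nlat = 90, nlon = 180,
                resolution = 2)
  total <- sum(area_weights(g))
  expect_equal(total, 4 * pi * 6371^2, tolerance = 1e-3)
})

test_that("grid construction validates its invariants", {
  g <- haz_grid(30.25, 10.25, 4, 8, 0.5)
  expect_s3_class(g, "haz_grid")
  expect_equal(n_cells(g), 32)
  expect_true(all(diff(g$lat_centers) > 0))
  expect_error(haz_grid(89.75, 0.25, 10, 10, 0.5), "poles|\\[-90")
  expect_error(haz_grid(0.25, 179.95, 2, 2, 0.5), "\\[-180")
  expect_error(haz_grid(0.25, 0.25, 2, 2, 0.5,
                        land_mask = matrix(TRUE, 3, 2)), "land_mask")
  expect_error(haz_grid(0.25, 0.25, 2, 2, resolution = -1))
})
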