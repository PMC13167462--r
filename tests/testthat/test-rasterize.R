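# grid with cells [10, 10.5) x [30, 30.5) etc.; centres at 30.25/10.25 + k/2
rgrid <- function() haz_grid(30.25, 10.25, 4, 4)

test_that("axis-aligned rectangles rasterize to exact fractions", {
  g <- rgrid()
  # rectangle exactly covering the cell at row 2, col 2
  rect <- cbind(c(10.5, 11, 11, 10.5), c(30.5, 30.5, 31, 31))
  m <- rasterize_range(rect, g, entity_id = "full")
  expect_equal(nrow(m$cells), 1L)
  expect_equal(m$cells$row, 2L)
  expect_equal(m$cells$col, 2L)
  expect_equal(m$cells$overlap, 1.0)

  # western half of that cell
  half <- cbind(c(10.5, 10.75, 10.75, 10.5), c(30.5, 30.5, 31, 31))
  mh <- rasterize_range(half, g)
  expect_equal(mh$cells$overlap, 0.5)
  expect_equal(mh$cells[c("row", "col")], data.frame(row = 2L, col = 2L),
               ignore_attr = TRUE)
})

test_that("an L-shaped polygon matches a point-sampling area oracle", {
  g <- rgrid()
  # L across cells (1,1), (1,2), (2,1), entering each only partially
  L <- cbind(c(10.1, 10.9, 10.9, 10.4, 10.4, 10.1),
             c(30.1, 30.1, 30.35, 30.35, 30.9, 30.9))
  m <- rasterize_range(L, g, entity_id = "L")
  expect_true(all(m$cells$overlap >= 0 & m$cells$overlap <= 1))
  for (k in seq_len(nrow(m$cells))) {
    r <- m$cells$row[k]; cc <- m$cells$col[k]
    xmin <- g$lon_centers[cc] - 0.25; ymin <- g$lat_centers[r] - 0.25
    oracle <- sample_fraction(L, xmin, xmin + 0.5, ymin, ymin + 0.5)
    expect_equal(m$cells$overlap[k], oracle, tolerance = 0.01)
  }
  # total overlap-weighted area equals the polygon area (shoelace, degrees)
  poly_area <- 0.8 * 0.25 + 0.3 * 0.55
  expect_equal(sum(m$cells$overlap) * 0.5^2, poly_area, tolerance = 1e-9)
})

test_that("degenerate and invalid geometries are handled", {
  g <- rgrid()
  expect_equal(nrow(rasterize_range(NULL, g)$cells), 0L)
  expect_equal(nrow(rasterize_range(matrix(numeric(0), 0, 2), g)$cells), 0L)
  expect_error(rasterize_range(cbind(c(1, NA, 2), c(1, 2, 3)), g), "invalid")
  expect_error(rasterize_range(cbind(c(1, 2), c(1, 2)), g), "invalid")
})

test_that("island filtering partitions ranges and is idempotent", {
  land <- matrix(FALSE, 4, 4); land[1:2, 1:2] <- TRUE
  g <- haz_grid(30.25, 10.25, 4, 4, land_mask = land)
  on_land <- range_mask(g, data.frame(row = 1, col = 1, overlap = 0.01),
                        "sp1", taxon = "bird")
  off_land <- range_mask(g, data.frame(row = 4, col = 4, overlap = 0.9),
                         "sp2", taxon = "bird")
  empty <- range_mask(g, data.frame(row = integer(0), col = integer(0),
                                    overlap = numeric(0)),
                      "sp3", taxon = "mammal")
  flt <- filter_unrepresented(list(on_land, off_land, empty), g)
  expect_equal(vapply(flt$kept, `[[`, character(1), "entity_id"), "sp1")
  expect_setequal(vapply(flt$excluded, `[[`, character(1), "entity_id"),
                  c("sp2", "sp3"))
  expect_equal(length(flt$kept) + length(flt$excluded), 3L)
  # idempotent on the kept set
  again <- filter_unrepresented(flt$kept, g)
  expect_equal(length(again$excluded), 0L)
  expect_equal(sum(flt$summary$excluded), 2L)
})

test_that("richness map counts overlapping ranges additively", {
  g <- rgrid()
  m1 <- range_mask(g, data.frame(row = 1, col = 1, overlap = 0.4), "a")
  m2 <- range_mask(g, data.frame(row = c(1, 2), col = c(1, 2),
                                 overlap = c(1, 1)), "b")
  expect_equal(richness_map(list(), g), matrix(0L, 4, 4))
  r <- richness_map(list(m1, m2), g)
  expect_equal(r[1, 1], 2L)
  expect_equal(r[2, 2], 1L)
  expect_equal(sum(r), 3L)
})
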