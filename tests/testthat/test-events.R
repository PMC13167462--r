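test_that("day-of-year thresholds match a direct percentile oracle", {
  # constant series: threshold equals the constant on every day
  const <- rep(20, 365 * 30)
  expect_equal(calibrate_doy_percentile(const, 90, 31), rep(20, 365))

  # windowed pooling equals quantile(type = 7) over the pooled window values
  set.seed(4)
  ny <- 20
  x <- 10 * sin(2 * pi * rep(seq_len(365), ny) / 365) +
    rnorm(365 * ny, sd = 2)
  thr <- calibrate_doy_percentile(x, 90, 31)
  m <- matrix(x, 365, ny)
  for (d in c(1, 17, 180, 365)) {
    rows <- ((d - 16):(d + 14) %% 365) + 1
    oracle <- unname(quantile(as.vector(m[rows, ]), 0.9, type = 7))
    expect_equal(thr[d], oracle, tolerance = 1e-12)
  }

  # degenerate window of 1 day: exact per-calendar-day percentile
  thr1 <- calibrate_doy_percentile(x, 90, 1)
  expect_equal(thr1[42], unname(quantile(m[42, ], 0.9, type = 7)))

  expect_error(calibrate_doy_percentile(x, 0), "between 0 and 100")
  expect_error(calibrate_doy_percentile(x, 90, 30), "odd")
})

test_that("heatwave periods are maximal runs of at least three days", {
  thr <- rep(25, 365)
  x <- rep(20, 365)
  x[100:102] <- 30
  p <- detect_heatwave_periods(x, thr)
  expect_equal(p, data.frame(start = 100L, length = 3L))

  x2 <- rep(20, 365); x2[200:201] <- 30
  expect_equal(nrow(detect_heatwave_periods(x2, thr)), 0L)

  # pattern TTTFTTT: two periods of length 3
  x3 <- rep(20, 365); x3[10:12] <- 30; x3[14:16] <- 30
  p3 <- detect_heatwave_periods(x3, thr)
  expect_equal(p3$start, c(10L, 14L))
  expect_equal(p3$length, c(3L, 3L))
  expect_equal(p3, brute_runs(x3 > thr, 3L), ignore_attr = TRUE)
})

test_that("HWMId accumulates normalized magnitudes over heatwave periods", {
  thr <- rep(25, 365)
  q <- c(28, 32) # Q25, Q75 of the control annual maxima; IQR = 4
  none <- rep(20, 365)
  expect_equal(hwmid_annual(none, thr, q), 0)

  # hand-built 5-day heatwave: magnitudes (30,29,33,31,27.5) ->
  # (0.5, 0.25, 1.25, 0.75, 0): day 5 is below Q25 and contributes zero
  x <- rep(20, 365)
  x[100:104] <- c(30, 29, 33, 31, 27.5)
  expect_equal(hwmid_annual(x, thr, q), 0.5 + 0.25 + 1.25 + 0.75 + 0)

  # extending a period never decreases the annual value
  x2 <- x; x2[105] <- 29
  expect_gte(hwmid_annual(x2, thr, q), hwmid_annual(x, thr, q))

  expect_error(hwmid_annual(x, thr, c(30, 30)), "degenerate")
})

test_that("vectorised HWMId equals the scalar implementation per cell-year", {
  set.seed(7)
  ncell <- 5; ny <- 6
  tas <- matrix(rnorm(ncell * 365 * ny, 24, 4), ncell)
  thr <- matrix(rnorm(ncell * 365, 27, 0.5), ncell)
  q25 <- rep(28, ncell); q75 <- rep(33, ncell)
  hw <- hwmid_series(tas, thr, q25, q75)
  for (i in seq_len(ncell)) {
    for (y in seq_len(ny)) {
      yr <- tas[i, ((y - 1) * 365 + 1):(y * 365)]
      expect_equal(hw[i, y], hwmid_annual(yr, thr[i, ], c(q25[i], q75[i])))
    }
  }
  # degenerate reference cells flag as NA with a warning
  expect_warning(hwd <- hwmid_series(tas, thr, q25, q25), "degenerate")
  expect_true(all(is.na(hwd)))
})

test_that("extreme-year classification uses strict tail exceedance", {
  ctl <- c(0, 0, 0, 0, 0)
  expect_false(any(classify_extreme_years(0, ctl, 97.5, "upper")))
  expect_true(classify_extreme_years(1e-9, ctl, 97.5, "upper"))
  set.seed(1)
  ctl2 <- rnorm(100)
  expect_true(classify_extreme_years(max(ctl2) + 1, ctl2, 97.5, "upper"))
  expect_true(classify_extreme_years(min(ctl2) - 1, ctl2, 2.5, "lower"))
  expect_false(classify_extreme_years(median(ctl2), ctl2, 2.5, "lower"))
  expect_error(classify_extreme_years(1, numeric(0)), "empty control")
})

test_that("drought years require a sufficient within-year dry spell", {
  lev <- 0.2
  yr <- rep(0.5, 12)
  yr[4:6] <- 0.1
  expect_true(detect_drought_years(yr, lev))
  # two 2-month spells separated by a wet month do not qualify
  yr2 <- rep(0.5, 12); yr2[c(3, 4, 6, 7)] <- 0.1
  expect_false(detect_drought_years(yr2, lev))
  # 50-year random monthly series agrees with the brute-force scanner
  set.seed(12)
  sm <- runif(50 * 12)
  expect_equal(detect_drought_years(sm, 0.3), brute_drought_flags(sm, 0.3))
  # December-January spells count toward neither year unless 3 months fall
  # within one calendar year
  yr3 <- rep(0.5, 24); yr3[11:14] <- 0.1 # Nov,Dec | Jan,Feb
  expect_equal(detect_drought_years(yr3, lev), c(FALSE, FALSE))
})

test_that("the dryness mask retains cells at or above the cutoff", {
  expect_equal(compute_dryness_mask(c(0.05, 0.1, 1.0)),
               c(FALSE, TRUE, TRUE))
  expect_error(compute_dryness_mask(-0.1), "non-negative")
})

test_that("flood years need outflow above level, wet cells and flooded area", {
  lev <- 10
  out <- matrix(c(12, 8, 15), 1)
  frac <- matrix(c(0.05, 0.5, 0.005), 1)
  flags <- classify_flood_years(out, lev, frac, dryness_mask = TRUE)
  expect_equal(as.vector(flags), c(TRUE, FALSE, FALSE))
  # without the flooded-area condition the third year floods
  expect_equal(as.vector(classify_flood_years(out, lev)),
               c(TRUE, FALSE, TRUE))
  # dryness-masked cell never floods
  expect_false(any(classify_flood_years(out, lev, frac, dryness_mask = FALSE)))
  expect_error(classify_flood_years(out, lev, frac * 100), "\\[0, 1\\]")
})

test_that("calibrated detection responds to percentile choice per cell", {
  g <- small_grid(4, 4)
  ctl <- generate_control(g, 60, 31)
  scen <- generate_scenario(g, 50, 31,
                            trend_spec(warming_rate = 0.5, drying_rate = 0.05,
                                       burn_scale_rate = 0.2,
                                       start_year = 1985),
                            start_year = 1985)
  ts <- calibrate_thresholds(ctl)
  sens <- run_sensitivity(ctl, scen, thresholds = ts)
  for (tp in c("heatwave", "drought", "flood", "wildfire")) {
    n95 <- rowSums(sens$q95$occ[[tp]])
    n975 <- rowSums(sens$q97.5$occ[[tp]])
    n99 <- rowSums(sens$q99$occ[[tp]])
    expect_true(all(n95 >= n975), info = tp)
    expect_true(all(n975 >= n99), info = tp)
  }
  # drought flags at the looser (5th) level are a superset of the 2.5th
  expect_true(all(sens$q97.5$occ$drought <= sens$q95$occ$drought))
})
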