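test_that("GEV distribution functions are mutually consistent", {
  # quantile/CDF inversion across shapes, including Gumbel
  for (shape in c(-0.3, 0, 0.2)) {
    p <- c(0.05, 0.5, 0.975)
    q <- qgev(p, loc = 2, scale = 1.5, shape = shape)
    expect_equal(pgev(q, 2, 1.5, shape), p)
  }
  # closed-form Gumbel quantile
  expect_equal(qgev(0.975, 0, 1, 0), -log(-log(0.975)))
  # density integrates to ~1 (Gumbel)
  expect_equal(integrate(dgev, -10, 30, loc = 0, scale = 1, shape = 0)$value,
               1, tolerance = 1e-5)
  expect_equal(return_period_prob(40), 0.975)
})

test_that("GEV fitting recovers known parameters from simulation", {
  set.seed(99)
  x <- rgev(5000, loc = 10, scale = 2, shape = 0.2)
  fit <- fit_gev(x)
  expect_equal(unname(fit["loc"]), 10, tolerance = 0.05)
  expect_equal(unname(fit["scale"]), 2, tolerance = 0.05)
  expect_lt(abs(unname(fit["shape"]) - 0.2), 0.05)
  expect_error(fit_gev(rep(3, 100)), "degenerate")
})

test_that("return-level classification approximates the empirical percentile", {
  # for a large stationary control, classifying by the GEV 40-year level is
  # nearly identical to classifying by the empirical 97.5th percentile of
  # the annual maxima
  set.seed(3)
  am <- matrix(exp(rnorm(5000, 1, 0.8)), 1)
  fit <- fit_gev_annual_maxima(annual_maxima = am, return_period = 40)
  expect_equal(fit$prob, 0.975)
  by_gev <- as.vector(am > fit$level)
  by_emp <- as.vector(classify_extreme_years(am, am, 97.5, "upper"))
  expect_gte(mean(by_gev == by_emp), 0.99)
})

test_that("per-cell annual-maxima fitting flags degenerate cells", {
  set.seed(8)
  daily <- rbind(exp(rnorm(365 * 60, 1, 0.5)), rep(2, 365 * 60))
  fit <- fit_gev_annual_maxima(daily, return_period = 40)
  expect_true(fit$usable[1])
  expect_false(fit$usable[2])
  expect_true(is.na(fit$level[2]))
  expect_gt(fit$level[1], max(qgev(0.9, fit$params[1, 1], fit$params[1, 2],
                                   fit$params[1, 3])))
})
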