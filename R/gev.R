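#' Generalized extreme value distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the GEV distribution with location `loc`, scale `scale` and shape
#' `shape`. The shape sign convention follows the block-maxima literature:
#' `shape > 0` is heavy-tailed (Frechet), `shape = 0` Gumbel, `shape < 0`
#' bounded (Weibull). Annual maxima of daily river outflow are modelled with
#' this family, and a T-year return level is the quantile at non-exceedance
#' probability `1 - 1/T`.
#'
#' @param x,q Quantiles.
#' @param p Probabilities.
#' @param n Number of draws.
#' @param loc,scale,shape Parameters; `scale > 0`.
#' @return `dgev` the density, `pgev` the CDF, `qgev` the quantile function,
#'   `rgev` random draws.
#' @name gev
NULL

gev_recycle <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  lapply(args, rep_len, n)
}

#' @rdname gev
#' @export
dgev <- function(x, loc = 0, scale = 1, shape = 0) {
  stopifnot(all(scale > 0))
  a <- gev_recycle(x = x, loc = loc, scale = scale, shape = shape)
  z <- (a$x - a$loc) / a$scale
  out <- numeric(length(z))
  g <- abs(a$shape) < 1e-9
  t0 <- exp(-z[g])
  out[g] <- t0 * exp(-t0) / a$scale[g]
  arg <- 1 + a$shape[!g] * z[!g]
  ok <- arg > 0
  t1 <- arg[ok]^(-1 / a$shape[!g][ok])
  v <- numeric(sum(!g)) # zero off-support
  v[ok] <- t1^(a$shape[!g][ok] + 1) * exp(-t1) / a$scale[!g][ok]
  out[!g] <- v
  out
}

#' @rdname gev
#' @export
pgev <- function(q, loc = 0, scale = 1, shape = 0) {
  stopifnot(all(scale > 0))
  a <- gev_recycle(q = q, loc = loc, scale = scale, shape = shape)
  z <- (a$q - a$loc) / a$scale
  out <- numeric(length(z))
  g <- abs(a$shape) < 1e-9
  out[g] <- exp(-exp(-z[g]))
  sh <- a$shape[!g]
  arg <- 1 + sh * z[!g]
  out[!g] <- ifelse(arg > 0, exp(-pmax(arg, 0)^(-1 / sh)),
                    ifelse(sh > 0, 0, 1))
  out
}

#' @rdname gev
#' @export
qgev <- function(p, loc = 0, scale = 1, shape = 0) {
  stopifnot(all(p > 0 & p < 1), all(scale > 0))
  a <- gev_recycle(p = p, loc = loc, scale = scale, shape = shape)
  out <- numeric(length(a$p))
  g <- abs(a$shape) < 1e-9
  out[g] <- a$loc[g] - a$scale[g] * log(-log(a$p[g]))
  out[!g] <- a$loc[!g] +
    a$scale[!g] * ((-log(a$p[!g]))^(-a$shape[!g]) - 1) / a$shape[!g]
  out
}

#' @rdname gev
#' @export
rgev <- function(n, loc = 0, scale = 1, shape = 0) {
  qgev(stats::runif(n), loc, scale, shape)
}

#' Non-exceedance probability of a T-year return period
#'
#' A T-year event has annual exceedance probability `1/T`, so its threshold
#' is the `(1 - 1/T)` quantile of the annual-maximum distribution; a 40-year
#' return period maps to the 97.5th percentile.
#'
#' @param return_period Return period in years, `> 1`.
#' @return Non-exceedance probability `1 - 1/return_period`.
#' @export
return_period_prob <- function(return_period) {
  stopifnot(all(return_period > 1))
  1 - 1 / return_period
}

# Sample probability-weighted moments b0, b1, b2 (Hosking)
pwm3 <- function(x) {
  x <- sort(x)
  n <- length(x)
  j <- seq_len(n)
  b0 <- mean(x)
  b1 <- sum((j - 1) / (n - 1) * x) / n
  b2 <- sum((j - 1) * (j - 2) / ((n - 1) * (n - 2)) * x) / n
  c(b0, b1, b2)
}

# L-moment estimator of GEV parameters (Hosking's approximation for the
# shape); returns c(loc, scale, shape) in the Frechet-positive convention.
gev_lmom <- function(x) {
  b <- pwm3(x)
  c2 <- (2 * b[2] - b[1]) / (3 * b[3] - b[1]) - log(2) / log(3)
  k <- 7.8590 * c2 + 2.9554 * c2^2 # Hosking's k = -shape
  if (abs(k) < 1e-8) {
    scale <- (2 * b[2] - b[1]) / log(2)
    loc <- b[1] - 0.5772156649015329 * scale
    return(c(loc = loc, scale = scale, shape = 0))
  }
  g <- gamma(1 + k)
  scale <- (2 * b[2] - b[1]) * k / (g * (1 - 2^(-k)))
  loc <- b[1] + scale * (g - 1) / k
  c(loc = loc, scale = scale, shape = -k)
}

gev_nll <- function(par, x, shape_bound = 0.5) {
  loc <- par[1]; scale <- par[2]; shape <- par[3]
  if (scale <= 0 || abs(shape) >= shape_bound) return(1e10)
  z <- (x - loc) / scale
  if (abs(shape) < 1e-9) {
    return(length(x) * log(scale) + sum(z) + sum(exp(-z)))
  }
  arg <- 1 + shape * z
  if (any(arg <= 0)) return(1e10)
  length(x) * log(scale) + (1 + 1 / shape) * sum(log(arg)) + sum(arg^(-1 / shape))
}

#' Fit a GEV distribution to a sample of block maxima
#'
#' Maximum-likelihood fit with L-moment estimates as starting values. The
#' shape parameter is constrained to `(-0.5, 0.5)` for numerical stability;
#' if the likelihood optimisation fails to converge the (clamped) L-moment
#' estimate is returned with a warning.
#'
#' @param x Numeric vector of block maxima (finite; length >= 10).
#' @param shape_bound Half-width of the admissible shape interval.
#' @return Named vector `c(loc, scale, shape)` with attribute `method`
#'   (`"mle"` or `"lmom"`).
#' @export
fit_gev <- function(x, shape_bound = 0.5) {
  x <- as.numeric(x)
  stopifnot(all(is.finite(x)), length(x) >= 10)
  if (stats::sd(x) == 0)
    stop("degenerate sample: constant block maxima", call. = FALSE)
  start <- gev_lmom(x)
  start[3] <- min(max(start[3], -shape_bound + 0.02), shape_bound - 0.02)
  if (start[2] <= 0) start[2] <- stats::sd(x)
  fit <- tryCatch(
    stats::optim(start, gev_nll, x = x, shape_bound = shape_bound,
                 method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit) || fit$convergence != 0 || !is.finite(fit$value) ||
      fit$value >= 1e9) {
    warning("GEV likelihood fit did not converge; using L-moment estimate",
            call. = FALSE)
    out <- start
    attr(out, "method") <- "lmom"
  } else {
    out <- fit$par
    attr(out, "method") <- "mle"
  }
  names(out) <- c("loc", "scale", "shape")
  out
}

#' Calibrate flood return levels from control outflow
#'
#' Fits a GEV distribution to the annual maxima of daily outflow from a
#' pre-industrial control run, per cell, and evaluates the return level at
#' the configured return period (default 40 years, i.e. the 97.5th
#' percentile of the annual-maximum distribution).
#'
#' @param control_outflow Numeric matrix `ncell x (365 * nyears)` of daily
#'   outflow, a single daily series, or (via `annual_maxima`) precomputed
#'   maxima.
#' @param return_period Return period in years.
#' @param annual_maxima Optional `ncell x nyears` matrix (or vector) of
#'   annual maxima, bypassing the daily-to-annual reduction.
#' @return List with `params` (`ncell x 3` matrix), `level` (return level
#'   per cell), `prob` (the non-exceedance probability used), `method`
#'   (per-cell fit method) and `usable` (FALSE where maxima were degenerate).
#' @export
fit_gev_annual_maxima <- function(control_outflow = NULL, return_period = 40,
                                  annual_maxima = NULL) {
  if (is.null(annual_maxima)) {
    stopifnot(!is.null(control_outflow))
    if (is.vector(control_outflow))
      control_outflow <- matrix(control_outflow, nrow = 1)
    annual_maxima <- daily_to_annual(control_outflow, max)
  }
  if (is.vector(annual_maxima)) annual_maxima <- matrix(annual_maxima, nrow = 1)
  p <- return_period_prob(return_period)
  ncell <- nrow(annual_maxima)
  params <- matrix(NA_real_, ncell, 3,
                   dimnames = list(NULL, c("loc", "scale", "shape")))
  level <- rep(NA_real_, ncell)
  method <- rep(NA_character_, ncell)
  usable <- rep(TRUE, ncell)
  for (i in seq_len(ncell)) {
    x <- annual_maxima[i, ]
    if (stats::sd(x) == 0) {
      usable[i] <- FALSE
      next
    }
    fit <- fit_gev(x)
    params[i, ] <- fit
    method[i] <- attr(fit, "method")
    level[i] <- qgev(p, fit[1], fit[2], fit[3])
  }
  list(params = params, level = level, prob = p, method = method,
       usable = usable)
}

#' Classify flood years from annual maximum outflow
#'
#' A cell-year is a flood year when its annual maximum outflow strictly
#' exceeds the calibrated return level, at least `min_fraction` percent of
#' the cell area is flooded that year, and the cell passes the dryness mask.
#'
#' @param annual_max_outflow `ncell x nyear` matrix (or vector for one cell).
#' @param flood_return_level Per-cell return level from
#'   [fit_gev_annual_maxima()].
#' @param flooded_fraction Optional `ncell x nyear` matrix of the flooded
#'   area fraction in `[0, 1]`; `NULL` means no flooded-area exclusion.
#' @param dryness_mask Optional logical per-cell vector, `TRUE` where the
#'   cell is retained (see [compute_dryness_mask()]).
#' @param min_fraction Minimum flooded area, percent of cell area.
#' @return Logical `ncell x nyear` matrix.
#' @export
classify_flood_years <- function(annual_max_outflow, flood_return_level,
                                 flooded_fraction = NULL, dryness_mask = NULL,
                                 min_fraction = 1) {
  if (is.vector(annual_max_outflow))
    annual_max_outflow <- matrix(annual_max_outflow, nrow = 1)
  flagged <- annual_max_outflow > flood_return_level
  flagged[is.na(flagged)] <- FALSE
  if (!is.null(flooded_fraction)) {
    stopifnot(all(dim(flooded_fraction) == dim(annual_max_outflow)))
    if (any(flooded_fraction < 0 | flooded_fraction > 1, na.rm = TRUE))
      stop("flooded_fraction must lie in [0, 1]", call. = FALSE)
    flagged <- flagged & (flooded_fraction >= min_fraction / 100)
  }
  if (!is.null(dryness_mask)) flagged <- flagged & dryness_mask
  flagged
}
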