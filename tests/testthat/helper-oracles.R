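# Independent brute-force oracles, deliberately written without rle() or any
# code shared with the package internals.

# all maximal runs of TRUE of length >= min_len, by explicit scanning
brute_runs <- function(x, min_len = 3L) {
  starts <- integer(0); lens <- integer(0)
  i <- 1L; n <- length(x)
  while (i <= n) {
    if (isTRUE(x[i])) {
      j <- i
      while (j < n && isTRUE(x[j + 1L])) j <- j + 1L
      if (j - i + 1L >= min_len) {
        starts <- c(starts, i); lens <- c(lens, j - i + 1L)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  data.frame(start = starts, length = lens)
}

# does any within-year run of below-level months reach min_run?
brute_drought_flags <- function(monthly, level, min_run = 3L) {
  ny <- length(monthly) %/% 12L
  vapply(seq_len(ny), function(y) {
    m <- monthly[((y - 1L) * 12L + 1L):(y * 12L)]
    nrow(brute_runs(m < level, min_run)) > 0L
  }, logical(1))
}

# fraction of a rectangle [xmin,xmax]x[ymin,ymax] covered by a polygon,
# by dense point sampling with mgcv's point-in-polygon test
sample_fraction <- function(poly, xmin, xmax, ymin, ymax, n = 200) {
  xs <- seq(xmin, xmax, length.out = n + 1)[-1] - (xmax - xmin) / (2 * n)
  ys <- seq(ymin, ymax, length.out = n + 1)[-1] - (ymax - ymin) / (2 * n)
  pts <- as.matrix(expand.grid(xs, ys))
  bnd <- rbind(poly, poly[1, ])
  mean(mgcv::in.out(bnd, pts))
}
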