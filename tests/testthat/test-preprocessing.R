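test_that("binning follows the floor convention, max-tie rule and precursor removal", {
  p <- bin_params(1.0005079, 0.40)
  s <- spectrum("s", 800, 2, 187.0, 10)
  b <- bin_peaks(s, p)
  expect_identical(b$peak_bins, 187L)

  # two peaks in one bin keep the maximum intensity
  s2 <- spectrum("s", 800, 2, c(187.0, 187.3), c(10, 30))
  b2 <- bin_peaks(s2, p)
  expect_identical(b2$peak_values, 30)

  # peaks within the precursor removal window are discarded
  s3 <- spectrum("s", 500.0, 2, c(499.0, 300.0), c(10, 10))
  b3 <- bin_peaks(s3, p, precursor_window_removal = 1.5)
  expect_identical(length(b3$peak_bins), 1L)

  # empty spectrum: all-zero single-bin result
  s4 <- spectrum("s", 500, 2, numeric(0), numeric(0))
  b4 <- bin_peaks(s4, p)
  expect_identical(b4$values, 0)
  expect_identical(b4$n_bins, 1L)

  # grid is sized to reach flank_radius past the last peak
  expect_identical(b$n_bins, 187L + 75L + 1L)
})

test_that("regional normalization scales each region's max to target", {
  p <- bin_params()
  # single nonzero bin becomes exactly the target
  b <- structure(list(values = c(0, 0, 16, 0, 0), n_bins = 5L, params = p,
                      peak_bins = 2L, peak_values = 16),
                 class = "binned_spectrum")
  nm <- region_normalize(b, n_regions = 1L, target = 50)
  expect_equal(nm$values[3], 50)
  expect_identical(sum(nm$values != 0), 1L)

  # all-zero input passes through with no division error
  z <- structure(list(values = numeric(5), n_bins = 5L, params = p,
                      peak_bins = integer(0), peak_values = numeric(0)),
                 class = "binned_spectrum")
  expect_identical(region_normalize(z)$values, numeric(5))

  # two regions with maxima 9 and 4 (sqrt: 3 and 2) each scale to 50;
  # within-region ratios preserved
  b2 <- structure(list(values = c(9, 1, 4, 1), n_bins = 4L, params = p,
                       peak_bins = 0:3, peak_values = c(9, 1, 4, 1)),
                  class = "binned_spectrum")
  nm2 <- region_normalize(b2, n_regions = 2L, target = 50, min_relative = 0)
  expect_equal(nm2$values, c(50, 50 / 3, 50, 25))

  # sub-5%-of-global-max values are zeroed
  b3 <- structure(list(values = c(10000, 1, 0, 0), n_bins = 4L, params = p,
                       peak_bins = 0:1, peak_values = c(10000, 1)),
                  class = "binned_spectrum")
  nm3 <- region_normalize(b3, n_regions = 1L)
  expect_identical(nm3$values[2], 0)
})

test_that("dense transform matches its definition on hand cases", {
  p <- bin_params()
  mk <- function(values) structure(
    list(values = values, n_bins = length(values), params = p,
         peak_bins = which(values > 0) - 1L,
         peak_values = values[values > 0]),
    class = "binned_spectrum")

  # all-zero in, all-zero out
  expect_identical(dense_xcorr_transform(mk(numeric(300)))$values,
                   numeric(300))

  # single peak of 50 at bin 200 (0-based), F = 75
  v <- numeric(400); v[201] <- 50
  out <- dense_xcorr_transform(mk(v), 75L)$values
  expect_equal(out[201], 50)
  inwin <- setdiff(126:276, 201)  # bins 125..275 0-based
  expect_equal(unique(round(out[inwin], 12)), round(-50 / 150, 12))
  expect_identical(max(abs(out[c(1:125, 277:400)])), 0)

  # constant input: zero on all interior bins
  cst <- mk(rep(3, 500))
  outc <- dense_xcorr_transform(cst, 75L)$values
  interior <- 76:(500 - 75)  # 1-based bins with full windows
  expect_equal(max(abs(outc[interior])), 0, tolerance = 1e-12)
})

test_that("dense transform equals the naive bin-by-bin oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(200:2000, 1)
    y <- numeric(n)
    idx <- sample(n, sample(5:60, 1))
    y[idx] <- runif(length(idx), 1, 50)
    F <- sample(c(5L, 25L, 75L), 1)
    b <- structure(list(values = y, n_bins = n, params = bin_params(),
                        peak_bins = sort(idx) - 1L,
                        peak_values = y[sort(idx)]),
                   class = "binned_spectrum")
    expect_equal(dense_xcorr_transform(b, F)$values,
                 naive_xcorr_transform(y, F), tolerance = 1e-12)
  }
})

test_that("sparse transform structure: breakpoints, empty input, lookup", {
  # empty peak collection
  sp0 <- sparse_xcorr_transform(integer(0), numeric(0), 1000L, 75L)
  expect_identical(sp0$bp_starts, 0L)
  expect_identical(sp0$bp_values, 0)
  expect_identical(sp0$breakpoint_updates, 0L)
  expect_identical(map_to_dense(sp0)$values, numeric(1000))

  # breakpoint count bound: <= 2k + 1; counter <= 2k
  for (seed in 1:10) {
    set.seed(seed)
    k <- sample(1:80, 1)
    bins <- sort(sample(0:4999, k))
    vals <- runif(k, 1, 50)
    sp <- sparse_xcorr_transform(bins, vals, 5000L, 75L)
    expect_lte(length(sp$bp_starts), 2L * k + 1L)
    expect_lte(sp$breakpoint_updates, 2L * k)
    expect_identical(sp$bp_starts[1], 0L)
    expect_true(all(diff(sp$bp_starts) > 0))
  }

  # isolated peak: lookup at the peak is exactly its intensity
  sp1 <- sparse_xcorr_transform(500L, 42, 2000L, 75L)
  expect_equal(xcorr_lookup(sp1, 500L), 42)
  # far from any peak: exactly zero
  expect_identical(xcorr_lookup(sp1, 1500L), 0)
  expect_error(xcorr_lookup(sp1, 2000L), "out of range")
})

test_that("sparse and dense paths agree bin-for-bin on random spectra", {
  widths <- list(c(1.0005079, 0.40), c(0.02, 0.0))
  n_cases <- 150L
  worst <- 0
  for (seed in seq_len(n_cases)) {
    w <- widths[[(seed %% 2L) + 1L]]
    s <- random_raw_spectrum(seed, n_peaks = sample(10:120, 1))
    b <- bin_peaks(s, bin_params(w[1], w[2]))
    nm <- region_normalize(b)
    d <- dense_xcorr_transform(nm, 75L)
    sp <- sparse_xcorr_transform(nm$peak_bins, nm$peak_values, nm$n_bins, 75L)
    md <- map_to_dense(sp)
    worst <- max(worst, max(abs(d$values - md$values)))
    # spot-check point lookups too
    probe <- sample(0:(nm$n_bins - 1L), 20L)
    expect_equal(xcorr_lookup(sp, probe), d$values[probe + 1L],
                 tolerance = 1e-9)
  }
  expect_lt(worst, 1e-9)
})

test_that("sparse work is independent of the grid size", {
  set.seed(99)
  bins <- sort(sample(0:1999, 50))
  vals <- runif(50, 1, 50)
  sp_small <- sparse_xcorr_transform(bins, vals, 2000L, 75L)
  sp_big <- sparse_xcorr_transform(bins, vals, 100000L, 75L)
  expect_identical(sp_big$breakpoint_updates, sp_small$breakpoint_updates)
})

test_that("both transforms are linear operators and preserve zero", {
  p <- bin_params()
  set.seed(7)
  n <- 1500L
  x <- numeric(n); z <- numeric(n)
  x[sample(n, 40)] <- runif(40, 1, 50)
  z[sample(n, 40)] <- runif(40, 1, 50)
  mk <- function(v) structure(
    list(values = v, n_bins = n, params = p,
         peak_bins = which(v != 0) - 1L, peak_values = v[v != 0]),
    class = "binned_spectrum")
  a <- 2.5; b <- -0.75
  lhs <- dense_xcorr_transform(mk(a * x + b * z), 75L)$values
  rhs <- a * dense_xcorr_transform(mk(x), 75L)$values +
         b * dense_xcorr_transform(mk(z), 75L)$values
  expect_equal(lhs, rhs, tolerance = 1e-9)

  comb <- a * x + b * z
  spc <- sparse_xcorr_transform(which(comb != 0) - 1L, comb[comb != 0], n, 75L)
  expect_equal(map_to_dense(spc)$values, lhs, tolerance = 1e-9)
})
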