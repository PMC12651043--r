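make_gaussian_spectrum <- function(centers, heights, widths = 10,
                                   grid = seq(250, 700, by = 0.1)) {
  widths <- rep_len(widths, length(centers))
  a <- numeric(length(grid))
  for (i in seq_along(centers))
    a <- a + heights[i] * exp(-0.5 * ((grid - centers[i]) / widths[i])^2)
  absorption_spectrum(grid, a)
}

test_that("anchor extraction: exact grid hits, interpolation, constants", {
  s <- absorption_spectrum(seq(400, 600, by = 0.1),
                           rep(0.8, length(seq(400, 600, by = 0.1))))
  expect_equal(unname(anchors_from_spectrum(s)), c(0.8, 0.8, 0.8))

  # exact hit at 577.0
  grid <- seq(490, 590, by = 0.1)
  a <- seq_along(grid) * 0.001
  s2 <- absorption_spectrum(grid, a)
  expect_equal(anchors_from_spectrum(s2)[["A577"]], a[which(grid == 577)])

  # midpoint interpolation between bracketing points
  s3 <- absorption_spectrum(c(490, 500.5, 568.9, 576.9, 577.1, 590),
                            c(0.1, 0.2, 0.3, 0.40, 0.44, 0.5))
  expect_equal(anchors_from_spectrum(s3)[["A577"]], 0.42)

  # anchors outside grid
  s4 <- absorption_spectrum(seq(200, 400, 0.5), rep(1, 401))
  expect_error(anchors_from_spectrum(s4), "does not cover")
})

test_that("nearest-neighbour anchor mode snaps to the closest grid point", {
  s <- absorption_spectrum(c(499.96, 500.07, 568.9, 569.04, 576.9, 577.04),
                           c(1, 2, 3, 4, 5, 6))
  got <- anchors_from_spectrum(s, method = "nearest")
  expect_equal(unname(got), c(6, 4, 1))
})

test_that("OD normalization rescales to the target and is idempotent", {
  s <- make_gaussian_spectrum(c(414, 576), c(1.6, 0.4))
  n <- normalize_to_od(s, target = 0.8)
  win <- n$wavelength >= 380 & n$wavelength <= 440
  expect_equal(max(n$absorbance[win]), 0.8, tolerance = 1e-12)
  expect_equal(n$absorbance, s$absorbance / 2, tolerance = 1e-12)

  twice <- normalize_to_od(n, target = 0.8)
  expect_equal(twice$absorbance, n$absorbance, tolerance = 1e-12)

  # already at target: unchanged
  expect_equal(normalize_to_od(n, 0.8)$absorbance, n$absorbance)

  # fixed-wavelength reference policy
  nf <- normalize_to_od(s, target = 0.8, reference = 414)
  expect_equal(stats::approx(nf$wavelength, nf$absorbance, 414)$y, 0.8,
               tolerance = 1e-6)

  flat0 <- absorption_spectrum(seq(300, 600, 1), rep(0, 301))
  expect_error(normalize_to_od(flat0), "non-positive")
})

test_that("band metrics find constructed peaks and flag degenerate windows", {
  s <- make_gaussian_spectrum(414, 1.2)
  bm <- extract_band_metrics(s)
  expect_equal(bm$peak_nm[bm$band == "soret"], 414, tolerance = 0.11)
  expect_false(bm$boundary[bm$band == "soret"])

  # two Q-band Gaussians: brute-force argmax over the dense grid as oracle
  s2 <- make_gaussian_spectrum(c(542, 576), c(0.5, 0.6), widths = 8)
  bm2 <- extract_band_metrics(s2)
  for (band in c("q542", "q576")) {
    win <- bm2[bm2$band == band, c("window_lo", "window_hi")]
    idx <- which(s2$wavelength >= win[[1]] & s2$wavelength <= win[[2]])
    oracle_peak <- s2$wavelength[idx[which.max(s2$absorbance[idx])]]
    expect_equal(bm2$peak_nm[bm2$band == band], oracle_peak, tolerance = 0.11)
  }
  expect_equal(bm2$peak_nm[bm2$band == "q542"], 542, tolerance = 0.11)
  expect_equal(bm2$peak_nm[bm2$band == "q576"], 576, tolerance = 0.11)

  flat <- absorption_spectrum(seq(250, 700, 0.5), rep(0.3, 901))
  expect_true(all(extract_band_metrics(flat)$boundary))

  # monotone trace across a window peaks at the edge
  mono <- absorption_spectrum(seq(250, 700, 0.5), seq(0, 1, length.out = 901))
  expect_true(all(extract_band_metrics(mono)$boundary))
})

test_that("percent_change matches the reported-decrease convention", {
  expect_equal(percent_change(1, 1), 0)
  expect_equal(percent_change(0.896, 1.000), 10.4, tolerance = 1e-10)
  expect_equal(percent_change(0.977, 1.000), 2.3, tolerance = 1e-10)
  # antisymmetry up to the ratio transform: swapping roles changes sign
  # after rescaling by the ratio of baselines
  expect_equal(percent_change(0.8, 1.0) / 100,
               -(percent_change(1.0, 0.8) / 100) * (0.8 / 1.0),
               tolerance = 1e-12)
  expect_error(percent_change(1, 0), "positive")
  expect_error(percent_change(1, -2), "positive")
})

test_that("spectrum constructor validates grids", {
  expect_error(absorption_spectrum(c(1, 2, 2), c(0, 0, 0)), "increasing")
  expect_error(absorption_spectrum(c(1, 2), c(0, NA)), "finite")
  expect_error(absorption_spectrum(c(1, 2, 3), c(0, 0)), "equal length")
})
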