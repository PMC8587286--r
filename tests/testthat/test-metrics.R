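test_that("background statistics are per-slice population statistics", {
  v <- volume(array(c(1, 3, 5, 7), c(2, 2, 1)))
  bs <- background_stats(v, array(TRUE, c(2, 2, 1)))
  expect_equal(bs$per_slice$mean, 4)
  expect_equal(bs$per_slice$sd, sqrt(5))

  # constant background has zero STD on every slice
  cst <- volume(array(3, c(4, 4, 3)))
  expect_equal(background_stats(cst, array(TRUE, c(4, 4, 3)))$mean_sd, 0)

  # mean STD is the average of per-slice STDs
  two <- volume(array(c(rep(c(1, 3), 8), rep(c(2, 6), 8)), c(4, 4, 2)))
  bs2 <- background_stats(two, array(TRUE, c(4, 4, 2)))
  expect_equal(bs2$mean_sd, mean(bs2$per_slice$sd))
  expect_equal(bs2$per_slice$sd, c(1, 2))

  # empty-background slices are skipped with a warning; all empty errors
  m <- array(TRUE, c(4, 4, 2)); m[, , 2] <- FALSE
  expect_warning(bs3 <- background_stats(two, m), "skipped")
  expect_equal(bs3$n_slices_used, 1)
  expect_error(background_stats(two, array(FALSE, c(4, 4, 2))), "empty")

  # population (divide by N) cross-check against an independent two-pass
  # computation on random data
  set.seed(8)
  x <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  bs4 <- background_stats(volume(x), array(TRUE, c(4, 4, 2)))
  for (z in 1:2) {
    v1 <- x[, , z]
    expect_equal(bs4$per_slice$sd[z],
                 sqrt(sum((v1 - sum(v1) / 16)^2) / 16), tolerance = 1e-12)
  }
})

test_that("SNR is scale-invariant and guards its degenerate case", {
  v <- volume(array(c(1, 3, 0, 0), c(2, 2, 1)))
  roi <- array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2, 1))
  s <- roi_snr(v, roi)
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$snr, 2)

  s2 <- roi_snr(volume(5 * v$values), roi)
  expect_equal(s2$snr, s$snr, tolerance = 1e-12)

  # offsets change SNR (mu/sigma is not offset-invariant)
  s3 <- roi_snr(volume(v$values + 10), roi)
  expect_false(isTRUE(all.equal(s3$snr, s$snr)))

  expect_error(roi_snr(volume(array(1, c(2, 2, 1))),
                       array(TRUE, c(2, 2, 1))),
               class = "mso_degenerate_error")
})

test_that("contrast ratio divides ROI mean by background mean", {
  v <- volume(array(c(10, 10, 2, 2), c(2, 2, 1)))
  roi <- array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2, 1))
  bg <- array(c(FALSE, FALSE, TRUE, TRUE), c(2, 2, 1))
  expect_equal(contrast_ratio(v, roi, bg), 5)
  expect_equal(contrast_ratio(volume(3 * v$values), roi, bg), 5,
               tolerance = 1e-12)
  expect_equal(contrast_ratio(volume(array(4, c(2, 2, 1))), roi, bg), 1)
  expect_error(contrast_ratio(volume(array(c(1, 1, 0, 0), c(2, 2, 1))),
                              roi, bg),
               class = "mso_degenerate_error")
})

test_that("percentage change reproduces the published table conventions", {
  # phantom / rat background-STD reductions
  expect_equal(round(pct_change(750.59, 110.64, "reduction"), 1), 85.3)
  expect_equal(round(pct_change(6.27, 4.19, "reduction"), 1), 33.2)
  expect_equal(round(pct_change(750.59, 96.69, "reduction"), 1), 87.1)
  expect_equal(round(pct_change(6.27, 2.80, "reduction"), 1), 55.3)
  # SNR increases
  expect_equal(round(pct_change(4.53, 5.76, "increase"), 1), 27.2)
  expect_equal(round(pct_change(4.53, 5.80, "increase"), 1), 28.0)
  expect_equal(round(pct_change(14.21, 15.38, "increase"), 1), 8.2)
  expect_equal(round(pct_change(14.21, 15.91, "increase"), 1), 12.0)
  # contrast-ratio increases (two decimals)
  expect_equal(round(pct_change(263.44, 342.52, "increase"), 2), 30.02)
  expect_equal(round(pct_change(263.44, 584.64, "increase"), 2), 121.93)
  expect_equal(round(pct_change(174.64, 182.70, "increase"), 2), 4.62)
  expect_equal(round(pct_change(174.64, 328.22, "increase"), 2), 87.94)

  expect_equal(pct_change(3.3, 3.3, "reduction"), 0)
  expect_error(pct_change(0, 1, "reduction"), "zero")
})

test_that("line profiles sample the image geometry faithfully", {
  v <- volume(array(matrix(1:16, 4, 4), c(4, 4, 1)), spacing_mm = 2)

  # constant image -> constant samples
  cst <- volume(array(5, c(4, 4, 1)), spacing_mm = 2)
  lp0 <- extract_line_profile(cst, 1, c(0, 0), c(6, 6))
  expect_true(all(lp0$samples == 5))

  # a horizontal profile reproduces the row values at voxel centres
  lp <- extract_line_profile(v, 1, c(0, 2), c(6, 2))
  on_grid <- lp$positions_mm %% 2 == 0
  expect_equal(lp$samples[on_grid], as.numeric(v$values[2, 1:4, 1]))

  # profile length equals the Euclidean endpoint distance
  lp2 <- extract_line_profile(v, 1, c(0, 0), c(3, 4))
  expect_equal(max(lp2$positions_mm), 5, tolerance = 1e-12)
  expect_equal(diff(range(diff(lp2$positions_mm))), 0, tolerance = 1e-12)

  expect_error(extract_line_profile(v, 1, c(-1, 0), c(2, 2)), "inside")
  expect_error(extract_line_profile(v, 9, c(0, 0), c(2, 2)), "slice")
})

test_that("FWHM recovers known widths from canonical profiles", {
  sp <- 700 / 168 / 2
  x <- seq(0, 120, by = sp)

  # rectangular dip spanning m samples: half level crosses midway between
  # the bracketing samples on each side, giving m * spacing exactly
  dip <- ifelse(x >= 40 & x < 60, 0, 10)
  m <- sum(dip == 0)
  pr <- structure(list(samples = dip, positions_mm = x, spacing_mm = sp),
                  class = "line_profile")
  expect_equal(fwhm(pr, "dip"), m * sp, tolerance = 1e-9)

  # triangular peak with base 2w has FWHM w (similar triangles)
  w <- 20
  tri <- pmax(0, 1 - abs(x - 60) / w)
  pr2 <- structure(list(samples = tri, positions_mm = x, spacing_mm = sp),
                   class = "line_profile")
  expect_lt(abs(fwhm(pr2, "peak") - w), sp / 2)

  # Gaussian peak: FWHM = 2 sqrt(2 ln 2) sigma, within half a spacing
  sigma <- 3
  g <- exp(-(x - 60)^2 / (2 * sigma^2))
  pr3 <- structure(list(samples = g, positions_mm = x, spacing_mm = sp),
                   class = "line_profile")
  expect_lt(abs(fwhm(pr3, "peak") - 2.3548 * sigma), sp / 2)

  # flat profile: no resolvable aperture
  flat <- structure(list(samples = rep(1, 50),
                         positions_mm = seq(0, 49) * sp,
                         spacing_mm = sp), class = "line_profile")
  expect_error(fwhm(flat, "dip"), "unresolved")
})

test_that("cold-rod FWHM measured on the phantom tracks rod diameter", {
  spec <- phantom_spec(n_slices = 1)
  ph <- make_phantom(spec)
  rods <- streakmso:::phantom_layout(spec)
  # largest rod (sector 1, 31.8 mm): profile through its centre
  ctr_mm <- (spec$grid_size - 1) / 2 * spec$voxel_spacing_mm
  p <- rods[[1]][which.max(rods[[1]][, 1]^2 + rods[[1]][, 2]^2) , ]
  half_len <- 40
  lp <- extract_line_profile(ph, 1,
                             c(ctr_mm + p[1] - half_len, ctr_mm + p[2]),
                             c(ctr_mm + p[1] + half_len, ctr_mm + p[2]))
  w <- fwhm(lp, "dip")
  expect_lt(abs(w - 31.80), 2 * spec$voxel_spacing_mm)
})
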