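test_that("family sizes match the operator combination counts", {
  expect_equal(family_size(c(2, 2)), 16)
  expect_equal(family_size(c(2, 3)), 64)
  expect_equal(family_size(c(3, 2)), 64)
  expect_equal(family_size(c(3, 3)), 512)
  expect_equal(family_size(c(3, 3, 3)), 134217728)
  expect_equal(family_size(c(1, 1)), 2)
  expect_error(family_size(c(4, 4)), "unsupported")
})

test_that("mask enumeration is complete, ordered, and invertible", {
  fam <- enumerate_masks(c(2, 2))
  expect_length(fam, 15)
  expect_equal(sort(vapply(fam, function(m) m$code, numeric(1))), 1:15)

  # axis order: popcount ascending, code ascending within popcount
  pops <- vapply(fam, function(m) m$popcount, numeric(1))
  codes <- vapply(fam, function(m) m$code, numeric(1))
  expect_true(all(diff(pops) >= 0))
  expect_true(all(tapply(codes, pops, function(x) all(diff(x) > 0))))
  expect_equal(mask_at(c(3, 3, 3), 1)$popcount, 1)

  # decode/encode round trip on random codes, 2D and 3D
  set.seed(1)
  for (shape in list(c(3, 3), c(3, 3, 3))) {
    L <- prod(shape)
    for (code in sample(2^L - 1, 100)) {
      se <- structuring_element(shape, code = code)
      expect_equal(structuring_element(shape, bits = se$bits)$code, code)
      expect_equal(mask_at(shape, axis_index(se))$code, code)
    }
  }

  # axis indexing is a bijection on a small family
  idx <- vapply(fam, axis_index, numeric(1))
  expect_equal(idx, 1:15)

  expect_error(structuring_element(c(2, 2), code = 0), "code")
  expect_error(structuring_element(c(2, 2), code = 16), "code")
  expect_error(enumerate_masks(c(3, 3, 3)), "mask_at")
})

test_that("structuring elements serialise to JSON and back", {
  se <- structuring_element(c(3, 3, 2), code = 98765)
  back <- se_from_json(se_to_json(se))
  expect_identical(back$bits, se$bits)
  expect_identical(back$shape, se$shape)
})

test_that("masked local mean matches its definition on small cases", {
  # delta kernel: identity on the interior
  id <- structuring_element(c(3, 3),
                            bits = matrix(c(0, 0, 0, 0, 1, 0, 0, 0, 0),
                                          3, 3))
  v <- fixture_noise_volume()
  expect_equal(apply_mso(v, id)$values, v$values, tolerance = 1e-12)

  # constant image is a fixed point for any mask (reflect padding)
  cst <- volume(array(7, c(6, 6, 2)))
  m <- structuring_element(c(3, 3), code = 511)
  expect_equal(apply_mso(cst, m)$values, cst$values, tolerance = 1e-12)

  # all-ones 2x2 on [[0,2],[4,6]]: the anchor voxel covering the full
  # support holds the mean of the four values
  sl <- volume(matrix(c(0, 4, 2, 6), 2, 2))
  m22 <- structuring_element(c(2, 2), code = 15)
  expect_equal(apply_mso(sl, m22)$values[2, 2, 1], 3.0)
})

test_that("masked mean agrees with an independent brute-force oracle", {
  v <- fixture_noise_volume(dims = c(7, 6, 3))
  set.seed(4)
  cases <- list(
    structuring_element(c(2, 3), code = sample(63, 1)),
    structuring_element(c(3, 3), code = sample(511, 1)),
    structuring_element(c(2, 2, 2), code = sample(255, 1)),
    structuring_element(c(3, 3, 3), code = sample(2^27 - 1, 1)))
  for (se in cases) {
    got <- apply_mso(v, se)$values
    want <- oracle_masked_mean(v$values, se$bits)
    expect_equal(got, want, tolerance = 1e-12,
                 info = paste("shape", paste(se$shape, collapse = "x"),
                              "code", se$code))
  }
})

test_that("operator output obeys linearity and range containment", {
  v <- fixture_noise_volume()
  set.seed(9)
  for (mode in c("normalized_convolution", "opening")) {
    se <- structuring_element(c(3, 3), code = sample(511, 1))
    out <- apply_mso(v, se, mode = mode)$values
    expect_gte(min(out), min(v$values))
    expect_lte(max(out), max(v$values))
  }
  # affine equivariance of the masked mean
  se <- structuring_element(c(3, 3, 2), code = sample(2^18 - 1, 1))
  a <- 2.5; b <- -4
  lhs <- apply_mso(volume(a * v$values + b, v$spacing_mm), se)$values
  rhs <- a * apply_mso(v, se)$values + b
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("2D masks act slice by slice", {
  v <- fixture_noise_volume(dims = c(8, 8, 3))
  se <- structuring_element(c(3, 2), code = 21)
  whole <- apply_mso(v, se)$values
  for (z in 1:3) {
    one <- apply_mso(volume(v$values[, , z, drop = FALSE]), se)$values
    expect_equal(whole[, , z], one[, , 1], tolerance = 1e-12)
  }
})

test_that("opening with a full mask equals classical opening behaviour", {
  # an isolated bright voxel is removed by opening with any mask of
  # popcount > 1 that covers it
  v <- array(0, c(9, 9, 1)); v[5, 5, 1] <- 10
  m <- structuring_element(c(3, 3), code = 511)
  out <- apply_mso(volume(v), m, mode = "opening")$values
  expect_true(all(out == 0))
})

test_that("mask-set averaging is the voxelwise mean of member outputs", {
  v <- fixture_noise_volume(dims = c(4, 4, 2))
  m1 <- structuring_element(c(2, 2), code = 15)
  m2 <- structuring_element(c(2, 2), code = 3)

  # one mask, or repeated masks, reduce to apply_mso
  expect_equal(apply_mask_set_average(v, list(m1))$values,
               apply_mso(v, m1)$values)
  expect_equal(apply_mask_set_average(v, rep(list(m1), 5))$values,
               apply_mso(v, m1)$values, tolerance = 1e-12)

  # two masks: hand-computed mean of the two outputs
  want <- (apply_mso(v, m1)$values + apply_mso(v, m2)$values) / 2
  expect_equal(apply_mask_set_average(v, list(m1, m2))$values, want,
               tolerance = 1e-12)

  expect_error(apply_mask_set_average(v, list()), "non-empty")
  m3 <- structuring_element(c(3, 3), code = 7)
  expect_error(apply_mask_set_average(v, list(m1, m3)), "shape")
})

test_that("masked mean reduces i.i.d. noise by one over root popcount", {
  set.seed(42)
  noise <- volume(array(rnorm(64 * 64 * 8), c(64, 64, 8)))
  interior <- array(FALSE, c(64, 64, 8))
  interior[3:62, 3:62, ] <- TRUE
  for (shape in list(c(2, 2), c(3, 3), c(3, 3, 3))) {
    p <- prod(shape)
    se <- structuring_element(shape, code = 2^p - 1)
    s <- mean_background_std(apply_mso(noise, se), interior)
    expect_lt(abs(s * sqrt(p) - 1), 0.15)
  }
})
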