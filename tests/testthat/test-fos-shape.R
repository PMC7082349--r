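test_that("first-order features of degenerate and tiny ROIs", {
  m <- array(1L, c(2, 2, 2))
  f <- extract_fos(array(4.2, c(2, 2, 2)), m)
  expect_equal(unname(f[c("mean", "median", "maximum", "minimum")]),
               rep(4.2, 4))
  expect_equal(unname(f[c("variance", "entropy", "range", "skewness",
                          "kurtosis")]), rep(0, 5))
  expect_equal(unname(f["uniformity"]), 1)

  # {1,2,3}: hand-computed moments, population denominator
  m3 <- array(c(1L, 1L, 1L, 0L), c(4, 1, 1))
  f3 <- extract_fos(array(c(1, 2, 3, 99), c(4, 1, 1)), m3)
  expect_equal(unname(f3["mean"]), 2)
  expect_equal(unname(f3["range"]), 2)
  expect_equal(unname(f3["standard_deviation"]), sqrt(2 / 3))
  expect_equal(unname(f3["energy"]), 1 + 4 + 9)

  # {0,0,0,1}: two occupied bins, uniformity (3/4)^2 + (1/4)^2
  f4 <- extract_fos(array(c(0, 0, 0, 1), c(4, 1, 1)), array(1L, c(4, 1, 1)))
  expect_equal(unname(f4["uniformity"]), 0.625)

  single <- array(0L, c(3, 3, 3)); single[2, 2, 2] <- 1L
  fs <- extract_fos(array(rnorm(27), c(3, 3, 3)), single)
  expect_equal(unname(fs[c("variance", "standard_deviation",
                           "mean_absolute_deviation",
                           "interquartile_range")]), rep(0, 4))
})

test_that("voxel-face shape values on boxes are exact", {
  m <- array(0L, c(3, 3, 3)); m[2, 2, 2] <- 1L
  s <- extract_shape(m, c(1, 1, 1), surface = "voxel")
  expect_equal(unname(s[c("volume", "surface_area",
                          "surface_to_volume_ratio")]), c(1, 6, 6))
  cube <- array(0L, c(4, 4, 4)); cube[2:3, 2:3, 2:3] <- 1L
  s2 <- extract_shape(cube, c(1, 1, 1), surface = "voxel")
  expect_equal(unname(s2[c("volume", "surface_area")]), c(8, 24))
  expect_equal(unname(s2["max_3d_diameter"]), sqrt(3))
  # anisotropic faces
  s3 <- extract_shape(m, c(0.6, 0.6, 5.0), surface = "voxel")
  expect_equal(unname(s3["volume"]), 0.6 * 0.6 * 5.0)
  expect_equal(unname(s3["surface_area"]), 2 * (0.36 + 3 + 3))
})

test_that("sub-resolution masks fall back to the exact voxel estimate", {
  # a one-slab plate smooths below the 0.5 isolevel; the mesh route must
  # still return finite, exact voxel-face values
  thin <- array(0L, c(6, 6, 3)); thin[2:5, 2:5, 2] <- 1L
  s <- extract_shape(thin, c(2, 2, 3))
  expect_true(all(is.finite(s)))
  expect_equal(unname(s["volume"]), 16 * 12)       # 16 voxels x 12 mm^3
  expect_equal(unname(s["surface_area"]), 128 + 96) # top/bottom + rim
  single <- array(0L, c(3, 3, 3)); single[2, 2, 2] <- 1L
  expect_true(all(is.finite(extract_shape(single, c(1, 1, 1)))))
})

test_that("mesh sphericity of digital balls approaches 1 from below", {
  s10 <- extract_shape(make_ball(10), c(1, 1, 1))
  expect_gte(unname(s10["sphericity"]), 0.9)
  expect_lte(unname(s10["sphericity"]), 1.0)
  s16 <- extract_shape(make_ball(16), c(1, 1, 1))
  expect_gte(unname(s16["sphericity"]), unname(s10["sphericity"]) - 0.005)
  expect_lte(abs(unname(s16["surface_area"]) / (4 * pi * 16^2) - 1), 0.05)
  expect_lte(abs(unname(s16["volume"]) / (4 / 3 * pi * 16^3) - 1), 0.05)
  expect_equal(unname(s16["spherical_disproportion"]),
               1 / unname(s16["sphericity"]))
  # compactness identities
  expect_equal(unname(s16["compactness2"]),
               unname(s16["sphericity"])^3, tolerance = 1e-10)
})
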