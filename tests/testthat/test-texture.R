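test_that("GLCM on the 2x2x1 checker image matches the hand enumeration", {
  lev <- array(c(1L, 1L, 2L, 2L), c(2, 2, 1)) # [[1,2],[1,2]] along y
  attr(lev, "n_levels") <- 2L
  tm <- build_texture_matrices(lev)
  # direction 2 is (0,1,0): two horizontal pairs, symmetric
  P <- tm$glcm$directional[, , 2]
  expect_equal(P, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  f <- texture_features(tm)
  # per-direction maximum probability, averaged: x-direction pairs are
  # (1,1) and (2,2) with max 0.5 each; y gives 0.5; no valid z pairs
  expect_equal(unname(f["GLCM_maximum_probability"]), 0.5)
})

test_that("constant ROI gives the degenerate texture conventions", {
  lev <- array(1L, c(2, 2, 2)); attr(lev, "n_levels") <- 4L
  tm <- build_texture_matrices(lev)
  f <- texture_features(tm)
  expect_equal(unname(f["GLCM_maximum_probability"]), 1)
  expect_equal(unname(f["GLCM_correlation"]), 0)
  expect_equal(unname(f["NGTDM_contrast"]), 0)
  expect_true(all(tm$ngtdm$s == 0))
  # one zone of size 8; zone percentage 1/8
  expect_equal(sum(tm$glszm), 1)
  expect_equal(tm$glszm[1, 8], 1L)
  expect_equal(unname(f["GLSZM_zone_percentage"]), 0.125)
})

test_that("matrix invariants hold on random quantized ROIs", {
  set.seed(101)
  dirs <- texture_directions()
  for (rep in 1:10) {
    lev <- array(sample(0:4, 5 * 4 * 3, replace = TRUE,
                        prob = c(0.3, rep(0.175, 4))), c(5, 4, 3))
    if (!any(lev > 0)) next
    attr(lev, "n_levels") <- 4L
    tm <- build_texture_matrices(lev)
    np <- sum(lev > 0)
    # aggregated GLCM is a symmetric probability distribution
    if (any(tm$glcm$has_pairs)) {
      expect_equal(sum(tm$glcm$aggregated), 1, tolerance = 1e-10)
      expect_equal(tm$glcm$aggregated, t(tm$glcm$aggregated))
    }
    # run and zone mass conservation
    for (d in seq_len(nrow(dirs))) {
      R <- tm$glrlm[, , d]
      expect_equal(sum(R * rep(seq_len(ncol(R)), each = nrow(R))), np)
    }
    expect_equal(sum(tm$glszm * rep(seq_len(ncol(tm$glszm)),
                                    each = nrow(tm$glszm))), np)
    expect_true(all(tm$ngtdm$s >= 0))
  }
})

test_that("all four matrices equal the brute-force enumeration", {
  set.seed(202)
  dirs <- texture_directions()
  for (rep in 1:8) {
    lev <- array(sample(0:3, 64, replace = TRUE), c(4, 4, 4))
    lev[1, 1, 1] <- 1L # nonempty
    attr(lev, "n_levels") <- 3L
    tm <- build_texture_matrices(lev)
    for (d in seq_len(nrow(dirs))) {
      sym <- bf_glcm(lev, dirs[d, ], 3L)
      expect_identical(tm$glcm$counts[, , d], sym,
                       label = sprintf("glcm rep %d dir %d", rep, d))
      expect_identical(tm$glrlm[, , d], bf_glrlm(lev, dirs[d, ], 3L, 4L)[, 1:4],
                       label = sprintf("glrlm rep %d dir %d", rep, d))
    }
    expect_identical(tm$glszm,
                     bf_glszm_dense(lev, 3L, ncol(tm$glszm)))
    nt <- bf_ngtdm(lev, 3L)
    expect_equal(tm$ngtdm$n, nt$n)
    expect_equal(tm$ngtdm$s, nt$s, tolerance = 1e-12)
  }
})

test_that("texture features are invariant to intensity shifts", {
  set.seed(5)
  v <- array(runif(6 * 6 * 4, 10, 60), c(6, 6, 4))
  m <- array(0L, c(6, 6, 4)); m[2:5, 2:5, 2:3] <- 1L
  f1 <- texture_features(build_texture_matrices(quantize_intensities(v, m)))
  f2 <- texture_features(build_texture_matrices(
    quantize_intensities(v + 123.4, m)))
  expect_equal(f1, f2, tolerance = 1e-12)
})
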