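test_that("config invariants are enforced", {
  expect_error(synthetic_config(n_patients = 3), ">= 4")
  expect_error(synthetic_config(base_prevalence = 1), "\\(0, 1\\)")
  expect_error(synthetic_config(tumor_radius_range = c(5, 2)), "radius")
  cfg <- synthetic_config()
  expect_equal(cfg$n_patients, 205L)
  expect_equal(cfg$base_prevalence, 0.678)
})

test_that("phantoms are deterministic and obey the stated geometry", {
  cfg <- tiny_config(seed = 5)
  a <- generate_phantom(cfg, 3)
  b <- generate_phantom(cfg, 3)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$mask, b$mask)
  expect_gt(sum(a$mask), 0)
  expect_identical(dim(a$mask), dim(a$volume$data))
  # different patients differ
  expect_false(identical(a$mask, generate_phantom(cfg, 4)$mask))
  # oversized tumor is a sizing error
  big <- synthetic_config(n_patients = 4, grid_shape = c(10, 10, 10),
                          voxel_spacing = c(1, 1, 1),
                          tumor_radius_range = c(8, 9))
  expect_error(generate_phantom(big, 1), "too large")
})

test_that("zero heterogeneity gives a noiseless constant tumor plateau", {
  cfg <- tiny_config(seed = 8, texture_heterogeneity_range = c(0, 0),
                     noise_sd = 0)
  st <- generate_phantom(cfg, 1)
  expect_equal(sd(st$volume$data[st$mask == 1]), 0)
  expect_equal(unique(st$volume$data[st$mask == 1]), cfg$tumor_intensity)
  expect_equal(unname(st$latent_covariates["heterogeneity"]), 0)
})

test_that("forcing the centroid to the AC zeroes the distance covariate", {
  cfg <- tiny_config(seed = 8)
  ext <- (cfg$grid_shape - 1) * cfg$voxel_spacing
  st <- generate_phantom(cfg, 1, centroid = ext / 2)
  expect_equal(unname(st$latent_covariates["chebyshev"]), 0)
})

test_that("label assignment hits the target prevalence and responds to effects", {
  set.seed(77)
  z <- matrix(rnorm(2000 * 2), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  # zero effect: empirical prevalence within 0.03 of 0.678
  r0 <- assign_epilepsy_type(z, c(a = 0, b = 0), 0.678)
  expect_lt(abs(mean(r0$type == "generalized") - 0.678), 0.03)
  expect_equal(unique(r0$probability), 0.678, tolerance = 1e-9)
  # overwhelming effect: the covariate separates the classes
  r1 <- assign_epilepsy_type(z, c(a = 50, b = 0), 0.5)
  y <- as.integer(r1$type == "generalized")
  expect_gt(bf_auc(z[1:200, "a"], y[1:200]), 0.99)
  # single patient, zero covariates: probability is plogis(intercept)
  r2 <- assign_epilepsy_type(c(a = 0, b = 0), c(a = 1, b = 1), 0.3)
  expect_equal(r2$probability, 0.3, tolerance = 1e-9)
  expect_error(assign_epilepsy_type(z, c(a = Inf, b = 0), 0.5), "finite")
})

test_that("doubling an effect coefficient never lowers that covariate's AUC", {
  aucs <- sapply(c(0.5, 1, 2), function(g) {
    set.seed(123)
    z <- matrix(rnorm(1000), ncol = 1, dimnames = list(NULL, "a"))
    r <- assign_epilepsy_type(z, c(a = g), 0.678)
    y <- as.integer(r$type == "generalized")
    auc_xy <- function(x, y) { # rank AUC
      r <- rank(x); n1 <- sum(y); n0 <- sum(1 - y)
      (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
    auc_xy(z[, 1], y)
  })
  expect_true(all(diff(aucs) > -0.02)) # monotone up to simulation noise
})

test_that("effect calibration is analytic and hits the requested AUC", {
  cal <- calibrate_logistic_effect(0.85, 0.678)
  expect_equal(cal$auc, 0.85, tolerance = 1e-6)
  # verify by independent Monte Carlo
  set.seed(99)
  u <- rnorm(40000)
  y <- as.integer(runif(40000) < plogis(cal$alpha + cal$gamma * u))
  expect_lt(abs(mean(y) - 0.678), 0.01)
  r <- rank(u); n1 <- sum(y); n0 <- sum(1 - y)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  expect_lt(abs(auc - 0.85), 0.01)
})

test_that("cohorts are reproducible, dated, and seed-sensitive", {
  cfg <- tiny_config(n = 4, seed = 41)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$studies[[2]]$volume$data, c2$studies[[2]]$volume$data)
  expect_equal(nrow(c1$manifest), 4L)
  expect_false(is.unsorted(as.Date(c1$manifest$surgery_date), strictly = TRUE))
  # different seeds must change a label or a centroid somewhere
  diffs <- vapply(1:10, function(k) {
    a <- generate_cohort(tiny_config(n = 4, seed = 100 + k))$manifest
    b <- generate_cohort(tiny_config(n = 4, seed = 200 + k))$manifest
    !identical(a$epilepsy_type, b$epilepsy_type) ||
      !identical(a$latent_chebyshev, b$latent_chebyshev)
  }, logical(1))
  expect_true(all(diffs))
})

test_that("written cohorts round-trip through the manifest", {
  dir <- tempfile("cohort_")
  cfg <- tiny_config(n = 4, seed = 51)
  cohort <- generate_cohort(cfg, out_dir = dir)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 4)
  st <- cohort$studies[[1]]
  back <- nifti_read(man$volume_path[1])
  expect_equal(back$data, st$volume$data, tolerance = 1e-5)
  mk <- nifti_read(man$mask_path[1])
  expect_identical(array(as.integer(mk$data), dim(st$mask)), st$mask)
  unlink(dir, recursive = TRUE)
})

test_that("feature-table simulation plants the effect it claims", {
  ft <- simulate_feature_cohort(n = 400, n_noise = 10, seed = 4)
  expect_s3_class(ft, "feature_table")
  expect_equal(dim(ft$features), c(400L, 14L))
  score <- rowSums(ft$features[, attr(ft, "planted")])
  r <- rank(score); n1 <- sum(ft$labels); n0 <- sum(1 - ft$labels)
  auc <- (sum(r[ft$labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  expect_gt(auc, 0.78) # population 0.85, finite-sample wiggle
  expect_lt(abs(mean(ft$labels) - 0.678), 0.08)
})
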