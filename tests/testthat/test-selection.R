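make_table <- function(X, y, cohort = "train") {
  feature_table(sprintf("P%03d", seq_len(nrow(X))), X, y, cohort)
}

test_that("z-score normalization fits on train only and flags constants", {
  X <- cbind(f1 = c(1, 2, 3), f2 = c(5, 5, 5), f3 = c(0, 10, 20))
  tr <- make_table(X, c(0, 1, 1))
  Xv <- cbind(f1 = c(2, 9), f2 = c(1, 2), f3 = c(10, 0))
  va <- make_table(Xv, c(0, 1), "validation")
  suppressMessages(res <- zscore_fit_apply(tr, va))
  expect_equal(res$params$excluded, "f2")
  expect_equal(unname(res$train$features[, "f1"]), c(-1, 0, 1))
  # validation value equal to the train mean maps to 0
  expect_equal(unname(res$other$features[1, "f1"]), 0)
  expect_false("f2" %in% colnames(res$other$features))
  expect_error(zscore_fit_apply(make_table(X[1, , drop = FALSE], 1)),
               "at least 2")
})

test_that("screening keeps perfect predictors in either orientation", {
  set.seed(31)
  y <- rep(c(0L, 1L), each = 20)
  X <- cbind(same = y + rnorm(40, sd = 1e-6),
             inverse = -y + rnorm(40, sd = 1e-6),
             noise = rnorm(40),
             flat = rep(1, 40))
  sc <- univariate_screen(make_table(X, y))
  expect_true(sc$kept[sc$feature == "same"])
  expect_true(sc$kept[sc$feature == "inverse"])
  expect_equal(sc$auc[sc$feature == "inverse"], 1) # oriented
  expect_false(sc$kept[sc$feature == "flat"])
  expect_equal(sc$reason[sc$feature == "flat"], "zero variance")
  expect_true(all(sc$auc >= 0.5, na.rm = TRUE))
})

test_that("screening is monotone in its thresholds", {
  set.seed(13)
  X <- matrix(rnorm(60 * 30), 60, 30,
              dimnames = list(NULL, paste0("f", 1:30)))
  y <- rbinom(60, 1, plogis(X[, 1]))
  tab <- make_table(X, y)
  strict <- univariate_screen(tab, 0.05, 0.6)
  loose <- univariate_screen(tab, 0.10, 0.55)
  expect_true(all(loose$kept[strict$kept]))
})

test_that("near-zero penalty reproduces the unpenalized logistic fit", {
  set.seed(8)
  n <- 200
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(n, 1, plogis(0.3 + X %*% c(1, -0.7, 0.2)))
  tab <- make_table(X, y)
  lam <- exp(seq(log(0.5), log(1e-6), length.out = 60))
  fit <- fit_lasso_loocv(tab, lambda_grid = lam)
  # oracle: plain glm at lambda ~ 0
  or <- glm(y ~ X, family = binomial())
  full_path <- glmnet::glmnet(X, y, family = "binomial", lambda = lam,
                              standardize = FALSE)
  beta_tiny <- as.numeric(coef(full_path, s = min(lam)))
  expect_equal(beta_tiny, unname(coef(or)), tolerance = 1e-3)
  expect_s3_class(fit, "signature_model")
  expect_true(all(fit$coefficients != 0))
})

test_that("lambda large enough shrinks everything to an empty signature", {
  set.seed(12)
  X <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rbinom(40, 1, 0.5)
  tab <- make_table(X, y)
  expect_error(
    fit_lasso_loocv(tab, lambda_grid = c(100, 99)), "nonempty")
  expect_error(fit_lasso_loocv(make_table(X, rep(1L, 40))), "one class")
  expect_error(fit_lasso_loocv(subset_feature_table(tab, patients = 1:8)),
               "10 patients")
})

test_that("LOOCV selects informative features and ties break to larger lambda", {
  ft <- simulate_feature_cohort(n = 150, n_noise = 30, seed = 21)
  nz <- zscore_fit_apply(ft)
  model <- fit_lasso_loocv(nz$train)
  expect_gte(sum(attr(ft, "planted") %in% model$features), 3)
  # tie rule: the reported lambda is the largest grid value achieving the
  # minimal LOOCV error
  best_err <- min(model$cv_error)
  expect_equal(model$lambda,
               max(model$lambda_grid[model$cv_error == best_err]))
  # support grows (weakly) along the decreasing-lambda path here
  sizes <- colSums(model$selection_path)
  expect_true(all(diff(sizes) >= 0))
  # signature separates the classes in the planted direction
  s <- compute_signature(model, nz$train)
  expect_gt(mean(s[ft$labels == 1]), mean(s[ft$labels == 0]))
})

test_that("signature arithmetic is an exact linear weighting", {
  m <- signature_model(c("a", "b"), c(0.5, -2), intercept = 0.25)
  tab <- make_table(cbind(a = c(0, 1, 2), b = c(0, 1, -1)), c(0, 1, 1))
  expect_equal(unname(compute_signature(m, tab)), c(0, -1.5, 3))
  expect_equal(unname(signature_probability(m, tab)),
               plogis(0.25 + c(0, -1.5, 3)))
  expect_error(compute_signature(m, make_table(cbind(a = 1:3), c(0, 1, 1))),
               "missing selected feature.*b")
})

test_that("signature models survive JSON serialization", {
  m <- signature_model(c("x", "y"), c(1.5, -0.25), intercept = 0.1,
                       lambda = 0.067,
                       normalization = list(mean = c(x = 1, y = 2),
                                            sd = c(x = 3, y = 4)))
  path <- tempfile(fileext = ".json")
  signature_to_json(m, path)
  back <- signature_from_json(path)
  expect_equal(back$coefficients, m$coefficients)
  expect_equal(back$lambda, m$lambda)
  expect_equal(back$normalization$sd, m$normalization$sd)
  # raw-table route applies the stored normalization
  tab <- make_table(cbind(x = c(1, 4), y = c(2, 6)), c(0, 1))
  expect_equal(unname(compute_signature(back, tab, normalized = FALSE)),
               c(0, 1.5 * 1 - 0.25 * 1))
  unlink(path)
})
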