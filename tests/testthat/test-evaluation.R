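test_that("AUC handles separation, ties, and matches the pair-count oracle", {
  r <- roc_auc_ci(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  expect_equal(roc_auc_ci(rep(0.3, 8), rep(c(0, 1), 4))$auc, 0.5)
  set.seed(14)
  for (rep in 1:5) {
    s <- sample(round(runif(20), 2)) # ties likely
    y <- rbinom(20, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc_ci(s, y)$auc, bf_auc(s, y), tolerance = 1e-12)
  }
  expect_error(roc_auc_ci(1:5, rep(1, 5)), "both classes")
})

test_that("AUC is invariant under strictly increasing transforms and the CI shrinks with n", {
  set.seed(15)
  s <- rnorm(60); y <- rbinom(60, 1, plogis(s))
  a1 <- roc_auc_ci(s, y)
  a2 <- roc_auc_ci(exp(s), y)
  expect_equal(a1$auc, a2$auc)
  expect_equal(a1$ci, a2$ci)
  width <- function(n, seed) {
    set.seed(seed)
    s <- rnorm(n); y <- rbinom(n, 1, plogis(1.5 * s))
    diff(roc_auc_ci(s, y)$ci)
  }
  w50 <- mean(sapply(1:20, function(k) width(50, k)))
  w200 <- mean(sapply(1:20, function(k) width(200, k)))
  expect_lt(w200, w50 / 1.6) # ~ 1/sqrt(4) = 0.5 expected
})

test_that("Hosmer-Lemeshow matches hand computation and is exact at O = E", {
  # two bins of 4 at p = 0.5 with O = (1, 3): HL = 1 + 1 = 2
  probs <- rep(0.5, 8)
  labels <- c(1, 0, 0, 0, 1, 1, 1, 0)
  hl <- hosmer_lemeshow_calibration(probs, labels, n_bins = 2)
  expect_equal(hl$statistic, 2)
  # perfectly matching observed counts: HL = 0, p = 1
  p2 <- rep(c(0.2, 0.8), each = 10)
  y2 <- c(rep(1, 2), rep(0, 8), rep(1, 8), rep(0, 2))
  hl2 <- hosmer_lemeshow_calibration(p2, y2, n_bins = 2)
  expect_equal(hl2$statistic, 0)
  expect_equal(hl2$p_value, 1)
  expect_equal(hl2$bins$observed_frequency, hl2$bins$mean_predicted)
  expect_error(hosmer_lemeshow_calibration(rep(0.5, 5), rep(0, 5), 10),
               "smaller than n_bins")
})

test_that("Hosmer-Lemeshow type-I error is near nominal under calibration", {
  set.seed(16)
  # the probabilities are the simulation truth, not a fit on these data,
  # so no estimated parameters are subtracted from the df
  rej <- mean(replicate(300, {
    p <- runif(500, 0.05, 0.95)
    y <- rbinom(500, 1, p)
    hosmer_lemeshow_calibration(p, y, estimated_params = 0)$p_value < 0.05
  }))
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.09)
})

test_that("decision curve net benefit matches the closed form", {
  # toy: N = 10, TP = 4, FP = 1 at p_t = 0.2 -> 0.375
  probs <- c(rep(0.9, 4), 0.9, rep(0.05, 5))
  labels <- c(rep(1, 4), 0, 1, rep(0, 4))
  dc <- decision_curve(probs, labels, thresholds = 0.2)
  expect_equal(dc$net_benefit_model, 4 / 10 - (1 / 10) * 0.2 / 0.8)
  expect_equal(dc$net_benefit_model, 0.375)
  # treat-all at prevalence 0.5 and p_t = 0.5 is 0
  dc2 <- decision_curve(rep(0.5, 4), c(1, 1, 0, 0), thresholds = 0.5)
  expect_equal(dc2$net_benefit_all, 0)
  expect_equal(dc2$net_benefit_none, 0)
  # a perfect model attains net benefit = prevalence everywhere, and the
  # model curve never exceeds prevalence
  y <- rbinom(50, 1, 0.4)
  dcp <- decision_curve(y * 0.98 + 0.01, y)
  mid <- dcp$threshold > 0.02 & dcp$threshold < 0.98
  expect_true(all(abs(dcp$net_benefit_model[mid] - mean(y)) < 1e-12))
  set.seed(3)
  dcr <- decision_curve(runif(50), y)
  expect_true(all(dcr$net_benefit_model <= mean(y) + 1e-12))
})

test_that("backward AIC elimination drops noise and keeps signal", {
  drops <- sapply(1:10, function(k) {
    set.seed(400 + k)
    n <- 500
    sig <- rnorm(n); noise <- rnorm(n)
    y <- rbinom(n, 1, plogis(1.2 * sig))
    m <- fit_multivariable_aic(data.frame(signal = sig, flat = noise), y)
    !("flat" %in% m$retained) && ("signal" %in% m$retained)
  })
  expect_gte(mean(drops), 0.8)

  # adding a flat predictor costs ~ 2 - chisq(1) of AIC; removal preferred
  set.seed(55)
  y <- rbinom(300, 1, 0.6)
  x <- rnorm(300)
  a0 <- AIC(glm(y ~ 1, family = binomial()))
  a1 <- AIC(glm(y ~ x, family = binomial()))
  expect_lt(abs((a1 - a0) - (2 - unname(
    2 * (logLik(glm(y ~ x, family = binomial())) -
           logLik(glm(y ~ 1, family = binomial())))))), 1e-9)
  m <- fit_multivariable_aic(data.frame(x = x), y)
  expect_equal(m$retained, character(0))

  # four strong planted predictors are all retained
  set.seed(56)
  n <- 600
  df <- data.frame(signature = rnorm(n), age = rnorm(n),
                   gender = sample(c("male", "female"), n, TRUE),
                   histopathology = sample(c("oligodendroglial",
                                             "astrocytoma"), n, TRUE))
  eta <- 1.5 * df$signature + 0.8 * df$age + 1 * (df$gender == "male") +
    1 * (df$histopathology == "astrocytoma")
  y4 <- rbinom(n, 1, plogis(eta - mean(eta)))
  m4 <- fit_multivariable_aic(df, y4)
  expect_setequal(m4$retained,
                  c("signature", "age", "gender", "histopathology"))
})

test_that("nomogram point scales and probability path are exact", {
  set.seed(66)
  n <- 300
  df <- data.frame(signature = rnorm(n), age = rnorm(n, 40, 12))
  y <- rbinom(n, 1, plogis(0.8 * df$signature + 0.02 * (df$age - 40)))
  fit <- glm(y ~ signature + age, family = binomial(), data = df)
  nomo <- build_nomogram(fit)
  # widest-effect predictor spans exactly 100 points
  expect_equal(max(nomo$scales$point_span), 100)
  X <- model.matrix(fit)[, nomo$terms, drop = FALSE]
  pts <- nomogram_points(nomo, X)
  probs_path <- nomogram_probability(nomo, rowSums(pts))
  expect_equal(probs_path, unname(fitted(fit)), tolerance = 1e-10,
               ignore_attr = TRUE)
  # single-predictor model: that predictor spans 0-100
  f1 <- glm(y ~ signature, family = binomial(), data = df)
  n1 <- build_nomogram(f1)
  expect_equal(n1$scales$point_span, 100)
  p1 <- nomogram_points(n1, model.matrix(f1)[, "signature", drop = FALSE])
  expect_equal(range(p1), c(0, 100), tolerance = 1e-12)
  # two predictors with equal |beta| * range both span 100
  df2 <- data.frame(u = c(0, 1, 0.5, 0.2), v = c(0, -1, -0.3, -0.9))
  y2 <- c(0, 1, 1, 0)
  f2 <- suppressWarnings(glm(y2 ~ u + v, family = binomial(), data = df2))
  f2$coefficients[2:3] <- c(2, -2) # force symmetric effects
  n2 <- build_nomogram(f2)
  expect_equal(unname(n2$scales$point_span), c(100, 100))
})

test_that("cohort comparison reproduces the printed gender p-value pattern", {
  rec <- data.frame(
    epilepsy_type = c(rep("generalized", 139), rep("focal", 66)),
    gender = c(rep("male", 85), rep("female", 54),
               rep("male", 43), rep("female", 23)),
    age = c(rep(37, 139), rep(39, 66)),
    histopathology = c(rep(c("oligodendroglial", "astrocytoma"),
                           c(97, 42)),
                       rep(c("oligodendroglial", "astrocytoma"),
                           c(39, 27))))
  cmp <- compare_cohorts(rec)
  p_gender <- cmp$tests$p_value[cmp$tests$variable == "gender"]
  expect_lt(abs(p_gender - 0.645), 0.001) # printed to 3 decimals
  # hand-enumerable 2x2: (2,0; 0,2) two-sided Fisher p = 1/3
  rec2 <- data.frame(epilepsy_type = rep(c("generalized", "focal"), each = 2),
                     gender = c("male", "male", "female", "female"),
                     age = c(30, 40, 35, 45),
                     histopathology = rep("astrocytoma", 4))
  cmp2 <- compare_cohorts(rec2)
  expect_equal(cmp2$tests$p_value[cmp2$tests$variable == "gender"], 1 / 3,
               tolerance = 1e-12)
  # histopathology has an empty margin here: p = 1 by convention
  expect_equal(cmp2$tests$p_value[cmp2$tests$variable == "histopathology"], 1)
  # identical groups: t statistic 0, p = 1
  rec3 <- data.frame(epilepsy_type = rep(c("generalized", "focal"), each = 3),
                     age = rep(c(30, 40, 50), 2),
                     gender = rep("male", 6),
                     histopathology = rep("astrocytoma", 6),
                     signature = rep(c(-1, 0, 1), 2))
  cmp3 <- compare_cohorts(rec3)
  expect_equal(cmp3$tests$p_value[cmp3$tests$variable == "age"], 1)
  expect_equal(cmp3$tests$statistic[cmp3$tests$variable == "signature"], 0)
})
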