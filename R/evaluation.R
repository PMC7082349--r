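#' ROC AUC with DeLong confidence interval and 0.5-threshold accuracy
#'
#' Empirical AUC via the rank (Mann-Whitney) statistic with midrank tie
#' correction; the 95% CI uses the DeLong placement-variance estimator,
#' clipped to `[0, 1]`. Accuracy, sensitivity and specificity are reported
#' at the probability cut-off `threshold` (0.5), meaningful when `scores`
#' are probabilities.
#'
#' @param scores numeric scores or probabilities (higher = positive class).
#' @param labels binary labels (1 = positive/generalized).
#' @param conf confidence level.
#' @param threshold classification cut-off for the accuracy block.
#' @return list of class `roc_result`: `auc`, `ci` (length 2), `accuracy`,
#'   `sensitivity`, `specificity`, `threshold`, `n_pos`, `n_neg`.
#' @export
roc_auc_ci <- function(scores, labels, conf = 0.95, threshold = 0.5) {
  labels <- as.integer(labels)
  x <- scores[labels == 1]; y <- scores[labels == 0]
  m <- length(x); n0 <- length(y)
  if (m == 0 || n0 == 0)
    stop("roc_auc_ci: both classes must be present")
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(psi)
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  va <- (if (m > 1) stats::var(v10) / m else 0) +
    (if (n0 > 1) stats::var(v01) / n0 else 0)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * z * sqrt(va)))
  pred <- as.integer(scores >= threshold)
  structure(list(auc = auc, ci = ci, se = sqrt(va),
                 accuracy = mean(pred == labels),
                 sensitivity = mean(pred[labels == 1] == 1),
                 specificity = mean(pred[labels == 0] == 0),
                 threshold = threshold, n_pos = m, n_neg = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (95%% CI %.3f-%.3f), accuracy = %.1f%% @ %.2f\n",
              x$auc, x$ci[1], x$ci[2], 100 * x$accuracy, x$threshold))
  invisible(x)
}

#' Hosmer-Lemeshow calibration test and calibration curve
#'
#' Patients are grouped into `n_bins` equal-count bins of predicted risk
#' (deciles by default). Bins whose expected count is degenerate (mean
#' predicted probability 0 or 1) are merged with their neighbor. The
#' statistic is `sum (O - E)^2 / (n_b pbar (1 - pbar))` with
#' `bins - 2` degrees of freedom.
#'
#' @param probabilities predicted probabilities in (0, 1).
#' @param labels binary outcomes.
#' @param n_bins number of risk bins (cohort must be at least this large).
#' @param estimated_params number of model parameters estimated on these
#'   data, subtracted from the degrees of freedom. The canonical
#'   Hosmer-Lemeshow setup for a model developed on the same cohort is 2
#'   (the default, giving `n_bins - 2` df); use 0 when the probabilities
#'   are external to the data (e.g. a known simulation truth or a model
#'   fitted on a different cohort), where the null is chi-square with
#'   `n_bins` df.
#' @return list of class `calibration_result`: `bins` (data.frame with
#'   `n`, `mean_predicted`, `observed_frequency`, `expected`, `observed`),
#'   `statistic`, `df`, `p_value`.
#' @export
hosmer_lemeshow_calibration <- function(probabilities, labels, n_bins = 10L,
                                        estimated_params = 2L) {
  labels <- as.integer(labels)
  n <- length(probabilities)
  if (n < n_bins)
    stop("hosmer_lemeshow_calibration: cohort smaller than n_bins")
  if (any(probabilities <= 0 | probabilities >= 1))
    stop("hosmer_lemeshow_calibration: probabilities must lie in (0, 1)")
  ord <- order(probabilities)
  grp <- ceiling(seq_along(ord) / (n / n_bins))
  agg <- function(ix) c(n = length(ix), O = sum(labels[ix]),
                        E = sum(probabilities[ix]))
  bins <- t(vapply(split(ord, grp), agg, numeric(3)))
  # merge degenerate bins with their neighbor
  repeat {
    pbar <- bins[, "E"] / bins[, "n"]
    bad <- which(pbar <= 0 | pbar >= 1)
    if (length(bad) == 0 || nrow(bins) == 1) break
    b <- bad[1]
    nb <- if (b == 1) 2 else b - 1
    bins[nb, ] <- bins[nb, ] + bins[b, ]
    bins <- bins[-b, , drop = FALSE]
    message("hosmer_lemeshow_calibration: merged a degenerate risk bin")
  }
  pbar <- bins[, "E"] / bins[, "n"]
  stat <- sum((bins[, "O"] - bins[, "E"])^2 / (bins[, "n"] * pbar * (1 - pbar)))
  df <- max(1L, nrow(bins) - as.integer(estimated_params))
  structure(list(
    bins = data.frame(n = bins[, "n"],
                      mean_predicted = pbar,
                      observed_frequency = bins[, "O"] / bins[, "n"],
                      expected = bins[, "E"], observed = bins[, "O"],
                      row.names = NULL),
    statistic = stat, df = df,
    p_value = stats::pchisq(stat, df, lower.tail = FALSE)),
    class = "calibration_result")
}

#' Decision curve analysis
#'
#' Net benefit of calling positive at predicted probability `>= p_t`:
#' `TP/N - (FP/N) * p_t / (1 - p_t)`, compared with treat-all
#' (`pi - (1 - pi) * p_t / (1 - p_t)` at prevalence `pi`) and treat-none
#' (identically 0).
#'
#' @param probabilities predicted probabilities.
#' @param labels binary outcomes.
#' @param thresholds threshold-probability grid in (0, 1).
#' @return data.frame with `threshold`, `net_benefit_model`,
#'   `net_benefit_all`, `net_benefit_none`.
#' @export
decision_curve <- function(probabilities, labels,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  labels <- as.integer(labels)
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("decision_curve: thresholds must lie strictly in (0, 1)")
  n <- length(labels)
  prev <- mean(labels)
  odds <- thresholds / (1 - thresholds)
  nb <- vapply(thresholds, function(pt) {
    call <- probabilities >= pt
    sum(call & labels == 1) / n - sum(call & labels == 0) / n * pt / (1 - pt)
  }, numeric(1))
  data.frame(threshold = thresholds,
             net_benefit_model = nb,
             net_benefit_all = prev - (1 - prev) * odds,
             net_benefit_none = 0)
}

#' Backward AIC selection of the multivariable logistic model
#'
#' Starts from the full logistic model on the candidate predictors and
#' repeatedly removes the predictor whose removal lowers AIC most,
#' stopping when no removal lowers it (`AIC = 2k - 2 logLik`). Candidate
#' order is fixed, making the elimination deterministic.
#'
#' @param data data.frame of candidate predictors (e.g. `signature`, `age`,
#'   `gender`, `histopathology`); characters are treated as factors.
#' @param labels binary outcome.
#' @return list of class `aic_model`: `fit` (the glm), `retained`,
#'   `dropped`, `aic`, `trace` (data.frame of steps).
#' @export
fit_multivariable_aic <- function(data, labels) {
  labels <- as.integer(labels)
  df <- as.data.frame(data, stringsAsFactors = TRUE)
  df[] <- lapply(df, function(x) if (is.character(x)) factor(x) else x)
  df$.y <- labels
  terms <- setdiff(names(df), ".y")
  fit_with <- function(tr) {
    f <- if (length(tr)) stats::reformulate(tr, ".y") else
      stats::as.formula(".y ~ 1")
    stats::glm(f, family = stats::binomial(), data = df)
  }
  cur <- fit_with(terms)
  check_sep <- function(fit) {
    cf <- stats::coef(fit)[-1]
    if (length(cf) && any(abs(cf) > 15))
      stop("fit_multivariable_aic: separation detected (divergent ",
           "coefficient); reduce predictors or add penalization")
  }
  check_sep(cur)
  trace <- data.frame(step = 0L, dropped = "<start>",
                      aic = stats::AIC(cur), stringsAsFactors = FALSE)
  dropped <- character(0)
  step <- 0L
  while (length(terms) > 0L) {
    aics <- vapply(terms, function(tr) {
      stats::AIC(fit_with(setdiff(terms, tr)))
    }, numeric(1))
    if (min(aics) >= stats::AIC(cur)) break
    worst <- terms[which.min(aics)]
    terms <- setdiff(terms, worst)
    dropped <- c(dropped, worst)
    cur <- fit_with(terms)
    check_sep(cur)
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, dropped = worst,
                                     aic = stats::AIC(cur)))
  }
  structure(list(fit = cur, retained = terms, dropped = dropped,
                 aic = stats::AIC(cur), trace = trace),
            class = "aic_model")
}

#' Build a nomogram from a fitted logistic model
#'
#' Each predictor's contribution `beta * x` over its observed range is
#' mapped to a 0-100 point scale; the predictor with the widest effect
#' range spans exactly 100 points. The total-points axis maps back to
#' predicted probability through the logistic form, so the points path and
#' direct logistic evaluation agree exactly. Zero-range (constant)
#' predictors are folded into the baseline and excluded from the point
#' scales.
#'
#' @param model an `aic_model` from [fit_multivariable_aic()] or a fitted
#'   binomial `glm`.
#' @param n_lookup rows in the emitted total-points-to-probability table.
#' @return list of class `nomogram_model`: `terms`, `beta`, `intercept`,
#'   `base` (summed minimum contributions), `points_per_unit` (the linear
#'   scale), `scales` (per-term observed range and point span), `lookup`
#'   (data.frame `total_points`, `probability`).
#' @export
build_nomogram <- function(model, n_lookup = 101L) {
  fit <- if (inherits(model, "aic_model")) model$fit else model
  stopifnot(inherits(fit, "glm"))
  X <- stats::model.matrix(fit)
  beta <- stats::coef(fit)
  intercept <- beta["(Intercept)"]
  terms <- setdiff(colnames(X), "(Intercept)")
  contrib <- sweep(X[, terms, drop = FALSE], 2, beta[terms], `*`)
  rng <- apply(contrib, 2, function(v) diff(range(v)))
  keep <- rng > 0
  if (!any(keep)) stop("build_nomogram: all predictors have zero range")
  L <- max(rng[keep])
  mins <- apply(contrib[, keep, drop = FALSE], 2, min)
  base <- intercept + sum(apply(contrib[, !keep, drop = FALSE], 2,
                                function(v) v[1])) + sum(mins)
  max_total <- sum(rng[keep]) / L * 100
  lookup_pts <- seq(0, max_total, length.out = n_lookup)
  lookup <- data.frame(
    total_points = lookup_pts,
    probability = stats::plogis(base + lookup_pts * L / 100))
  structure(list(terms = terms[keep], beta = beta[terms[keep]],
                 intercept = unname(intercept), base = unname(base),
                 scale = L / 100,
                 mins = mins,
                 scales = data.frame(term = terms[keep],
                                     effect_range = rng[keep],
                                     point_span = 100 * rng[keep] / L,
                                     row.names = NULL),
                 dropped_constant = terms[!keep],
                 lookup = lookup),
            class = "nomogram_model")
}

#' Per-predictor nomogram points and the points-path probability
#'
#' `nomogram_points()` returns the per-term 0-100-scaled points for rows of
#' a design matrix; `nomogram_probability()` converts total points into
#' predicted probability. Evaluating the points path reproduces the direct
#' logistic probability exactly (up to floating-point error).
#'
#' @param nomo a `nomogram_model`.
#' @param newdata design-matrix columns for `nomo$terms` (matrix or
#'   data.frame of numeric/dummy-coded predictors).
#' @return matrix of points (patients x terms).
#' @export
nomogram_points <- function(nomo, newdata) {
  X <- as.matrix(newdata[, nomo$terms, drop = FALSE])
  contrib <- sweep(X, 2, nomo$beta, `*`)
  sweep(contrib, 2, nomo$mins) / (nomo$scale * 100) * 100
}

#' @rdname nomogram_points
#' @param total_points numeric vector of summed points.
#' @export
nomogram_probability <- function(nomo, total_points) {
  stats::plogis(nomo$base + total_points * nomo$scale)
}

#' Cohort comparison in the style of a clinical Table 1
#'
#' Age and signature are compared between epilepsy types with the
#' independent-samples (Student) t-test and summarized as median (range);
#' gender and histopathology with the two-sided Fisher exact test on the
#' 2 x 2 counts. A table with an empty margin yields p = 1 by convention.
#'
#' @param records data.frame with columns `epilepsy_type`, `age`, `gender`,
#'   `histopathology` and optionally `signature`.
#' @return list of class `cohort_comparison`: `tests` (data.frame
#'   `variable`, `test`, `statistic`, `p_value`) and `summary` (per-group
#'   descriptive strings).
#' @export
compare_cohorts <- function(records) {
  g <- records$epilepsy_type
  stopifnot(all(g %in% c("generalized", "focal")))
  if (length(unique(g)) < 2L)
    stop("compare_cohorts: both epilepsy types must be present")
  grp1 <- g == "generalized"

  tt <- function(v) {
    if (stats::sd(v[grp1]) == 0 && stats::sd(v[!grp1]) == 0) {
      # zero pooled variance: identical groups are a perfect null match,
      # distinct constant groups are infinitely separated
      if (mean(v[grp1]) == mean(v[!grp1])) return(c(statistic = 0, p = 1))
      return(c(statistic = Inf, p = 0))
    }
    r <- stats::t.test(v[grp1], v[!grp1], var.equal = TRUE)
    c(statistic = unname(r$statistic), p = r$p.value)
  }
  ft <- function(v) {
    tab <- table(factor(grp1, c(TRUE, FALSE)), v)
    if (any(dim(tab) < 2) || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      return(c(statistic = NA, p = 1))
    r <- stats::fisher.test(tab)
    c(statistic = unname(r$estimate %||% NA), p = r$p.value)
  }

  rows <- list(
    c(variable = "age", test = "t", tt(records$age)),
    c(variable = "gender", test = "fisher", ft(records$gender)),
    c(variable = "histopathology", test = "fisher",
      ft(records$histopathology)))
  if (!is.null(records$signature))
    rows <- c(rows, list(c(variable = "signature", test = "t",
                           tt(records$signature))))
  tests <- data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  tests$statistic <- as.numeric(tests$statistic)
  tests$p_value <- as.numeric(tests$p)
  tests$p <- NULL

  med_rng <- function(v, sel) sprintf("%s (%s-%s)", stats::median(v[sel]),
                                      min(v[sel]), max(v[sel]))
  summary <- list(
    n = c(generalized = sum(grp1), focal = sum(!grp1)),
    age = c(generalized = med_rng(records$age, grp1),
            focal = med_rng(records$age, !grp1)),
    gender = table(records$gender, ifelse(grp1, "generalized", "focal")),
    histopathology = table(records$histopathology,
                           ifelse(grp1, "generalized", "focal")))
  if (!is.null(records$signature))
    summary$signature <- c(
      generalized = sprintf("%.2f +/- %.2f", mean(records$signature[grp1]),
                            stats::sd(records$signature[grp1])),
      focal = sprintf("%.2f +/- %.2f", mean(records$signature[!grp1]),
                      stats::sd(records$signature[!grp1])))
  structure(list(tests = tests, summary = summary),
            class = "cohort_comparison")
}
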