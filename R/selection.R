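#' Construct a feature table
#'
#' The container moved between extraction, selection and evaluation: a
#' patients-by-features numeric matrix with ids, binary labels
#' (generalized = 1, focal = 0) and a cohort tag.
#'
#' @param patient_id character vector.
#' @param features numeric matrix (patients x features) with column names;
#'   no missing values.
#' @param labels 0/1 vector, logical, or character
#'   (`"generalized"`/`"focal"`).
#' @param cohort optional tag, e.g. `"train"` or `"validation"`.
#' @return object of class `feature_table`.
#' @export
feature_table <- function(patient_id, features, labels, cohort = NA_character_) {
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    stop("feature_table: features must have column names")
  if (anyNA(features) || any(!is.finite(features)))
    stop("feature_table: features contain missing or non-finite values")
  if (is.character(labels)) {
    bad <- !labels %in% c("generalized", "focal")
    if (any(bad)) stop("feature_table: unknown label(s) ",
                       paste(unique(labels[bad]), collapse = ", "))
    labels <- as.integer(labels == "generalized")
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)))
    stop("feature_table: labels must be binary")
  if (length(patient_id) != nrow(features) ||
      length(labels) != nrow(features))
    stop("feature_table: row count mismatch")
  structure(list(patient_id = as.character(patient_id), features = features,
                 labels = labels, cohort = cohort), class = "feature_table")
}

#' Subset a feature table by patients and/or features
#' @param table a [feature_table()].
#' @param patients row selector (ids, indices or logical).
#' @param features column selector.
#' @param cohort new cohort tag for the result.
#' @return a [feature_table()].
#' @export
subset_feature_table <- function(table, patients = NULL, features = NULL,
                                 cohort = table$cohort) {
  stopifnot(inherits(table, "feature_table"))
  ri <- seq_len(nrow(table$features))
  if (!is.null(patients)) {
    ri <- if (is.character(patients)) match(patients, table$patient_id)
    else ri[patients]
    if (anyNA(ri)) stop("subset_feature_table: unknown patient id")
  }
  X <- table$features[ri, , drop = FALSE]
  if (!is.null(features)) X <- X[, features, drop = FALSE]
  feature_table(table$patient_id[ri], X, table$labels[ri], cohort)
}

#' Fit z-score normalization on the training cohort and apply it
#'
#' Per-feature mean and standard deviation are estimated on the training
#' cohort only and applied to both cohorts. Features constant in training
#' (sd = 0) are excluded from both tables and reported.
#'
#' @param train training [feature_table()] (>= 2 patients).
#' @param other optional second table on the same feature set.
#' @return list with `train`, `other` (normalized tables) and `params`
#'   (`mean`, `sd`, `excluded`).
#' @export
zscore_fit_apply <- function(train, other = NULL) {
  stopifnot(inherits(train, "feature_table"))
  if (nrow(train$features) < 2L)
    stop("zscore_fit_apply: need at least 2 training patients (sd undefined)")
  mu <- colMeans(train$features)
  sg <- apply(train$features, 2, stats::sd)
  excluded <- names(sg)[sg == 0]
  keep <- sg > 0
  norm <- function(tab) {
    X <- sweep(sweep(tab$features[, keep, drop = FALSE], 2, mu[keep]),
               2, sg[keep], `/`)
    feature_table(tab$patient_id, X, tab$labels, tab$cohort)
  }
  res <- list(train = norm(train),
              other = if (!is.null(other)) norm(other),
              params = list(mean = mu[keep], sd = sg[keep],
                            excluded = excluded))
  if (length(excluded))
    message("zscore_fit_apply: excluded ", length(excluded),
            " train-constant feature(s)")
  res
}

# Rank AUC of x against binary y (ties handled by midranks).
auc_rank <- function(x, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(x)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Univariate screening by Pearson test and oriented AUC
#'
#' For each feature, the two-sided Pearson correlation test against the
#' binary label (point-biserial, t approximation) and the empirical rank
#' AUC oriented so that AUC >= 0.5. A feature is kept when `p < p_threshold`
#' and oriented AUC `> auc_threshold`. Zero-variance features are dropped
#' with a reason.
#'
#' @param train normalized training [feature_table()].
#' @param p_threshold,auc_threshold screening thresholds (0.05 and 0.6).
#' @return data.frame with `feature`, `p_value`, `auc`, `kept`, `reason`.
#' @export
univariate_screen <- function(train, p_threshold = 0.05,
                              auc_threshold = 0.6) {
  stopifnot(inherits(train, "feature_table"))
  X <- train$features; y <- train$labels
  n <- nrow(X)
  if (n < 3L) stop("univariate_screen: need at least 3 patients")
  sds <- apply(X, 2, stats::sd)
  r <- suppressWarnings(as.numeric(stats::cor(X, y)))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  auc <- apply(X, 2, auc_rank, y = y)
  auc <- pmax(auc, 1 - auc)
  degenerate <- sds == 0
  kept <- !degenerate & !is.na(p) & p < p_threshold & auc > auc_threshold
  data.frame(feature = colnames(X),
             p_value = ifelse(degenerate, NA, p),
             auc = ifelse(degenerate, NA, auc),
             kept = kept,
             reason = ifelse(degenerate, "zero variance", ""),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Construct a radiomic signature model
#'
#' Selected features, their logistic-LASSO coefficients, the internal
#' intercept (used only for probability outputs; the signature itself is
#' the intercept-free linear combination), the chosen penalty and the
#' normalization parameters.
#'
#' @param features character vector of selected feature names.
#' @param coefficients numeric vector matching `features`; all nonzero.
#' @param intercept logistic intercept.
#' @param lambda chosen penalty.
#' @param normalization list with `mean` and `sd` (or `NULL` if the model
#'   is applied to pre-normalized tables).
#' @param extra list of additional metadata (grid, CV errors, seed).
#' @return object of class `signature_model`.
#' @export
signature_model <- function(features, coefficients, intercept = 0,
                            lambda = NA_real_, normalization = NULL,
                            extra = list()) {
  coefficients <- as.numeric(coefficients)
  if (length(features) != length(coefficients))
    stop("signature_model: features/coefficients length mismatch")
  if (any(coefficients == 0))
    stop("signature_model: selected coefficients must be nonzero")
  structure(c(list(features = as.character(features),
                   coefficients = stats::setNames(coefficients, features),
                   intercept = intercept, lambda = lambda,
                   normalization = normalization), extra),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("<signature_model> %d feature(s), lambda = %s\n",
              length(x$features), format(x$lambda)))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' LASSO-logistic signature with leave-one-out lambda tuning
#'
#' L1-penalized logistic regression over a 100-point log-spaced lambda grid
#' spanning `[1e-4 * lambda_max, lambda_max]`. For every lambda, the
#' leave-one-out misclassification error at probability cut-off 0.5 is
#' computed; the error-minimizing lambda wins, with ties broken toward the
#' larger (more parsimonious) lambda. The final model is refit on the full
#' training cohort at the chosen lambda; features with nonzero coefficients
#' form the signature.
#'
#' @param train normalized training [feature_table()] restricted to the
#'   screened features (>= 2 features, >= 10 patients, both classes).
#' @param lambda_grid optional decreasing positive grid; by default built
#'   from glmnet's `lambda_max`.
#' @param n_lambda grid size when built automatically.
#' @param normalization normalization parameters to store in the model.
#' @return a [signature_model()] with `lambda_grid` and `cv_error` attached.
#' @export
fit_lasso_loocv <- function(train, lambda_grid = NULL, n_lambda = 100L,
                            normalization = NULL) {
  stopifnot(inherits(train, "feature_table"))
  X <- train$features; y <- train$labels
  n <- nrow(X)
  if (ncol(X) < 2L) stop("fit_lasso_loocv: need at least 2 kept features")
  if (n < 10L) stop("fit_lasso_loocv: need at least 10 patients")
  if (length(unique(y)) < 2L)
    stop("fit_lasso_loocv: training labels are all one class")

  if (is.null(lambda_grid)) {
    lam_max <- glmnet::glmnet(X, y, family = "binomial",
                              standardize = FALSE)$lambda[1]
    lambda_grid <- exp(seq(log(lam_max), log(1e-4 * lam_max),
                           length.out = n_lambda))
  }
  if (any(diff(lambda_grid) >= 0) || any(lambda_grid <= 0))
    stop("fit_lasso_loocv: lambda grid must be positive and decreasing")

  errs <- matrix(NA_real_, n, length(lambda_grid))
  for (i in seq_len(n)) {
    fit <- glmnet::glmnet(X[-i, , drop = FALSE], y[-i], family = "binomial",
                          lambda = lambda_grid, standardize = FALSE)
    pr <- stats::predict(fit, X[i, , drop = FALSE], s = lambda_grid,
                         type = "response")
    errs[i, ] <- as.integer(pr >= 0.5) != y[i]
  }
  cv_error <- colMeans(errs)
  best <- which(cv_error == min(cv_error))[1] # grid decreasing: first = largest
  lambda_star <- lambda_grid[best]

  full <- glmnet::glmnet(X, y, family = "binomial", lambda = lambda_grid,
                         standardize = FALSE)
  beta_path <- as.matrix(full$beta)
  if (all(beta_path == 0))
    stop("fit_lasso_loocv: no lambda on the grid yields a nonempty model; ",
         "extend the grid toward smaller lambda")
  beta <- beta_path[, best]
  a0 <- full$a0[best]
  sel <- which(beta != 0)
  if (length(sel) == 0L) {
    warning("fit_lasso_loocv: chosen lambda shrinks all coefficients to ",
            "zero; empty signature reported")
    return(structure(list(features = character(0),
                          coefficients = numeric(0), intercept = a0,
                          lambda = lambda_star, normalization = normalization,
                          lambda_grid = lambda_grid, cv_error = cv_error),
                     class = "signature_model"))
  }
  signature_model(colnames(X)[sel], beta[sel], intercept = a0,
                  lambda = lambda_star, normalization = normalization,
                  extra = list(lambda_grid = lambda_grid,
                               cv_error = cv_error,
                               selection_path = beta_path != 0))
}

#' Compute per-patient signature values
#'
#' The radiomic signature is the intercept-free linear weighting
#' `s = sum_k beta_k x'_k` of the selected normalized features.
#'
#' @param model a [signature_model()].
#' @param table a [feature_table()] containing every selected feature. If
#'   the model stores normalization parameters and `normalized = FALSE`,
#'   they are applied first.
#' @param normalized is `table` already normalized with the model's
#'   parameters?
#' @return named numeric vector of signature values.
#' @export
compute_signature <- function(model, table, normalized = TRUE) {
  stopifnot(inherits(model, "signature_model"),
            inherits(table, "feature_table"))
  miss <- setdiff(model$features, colnames(table$features))
  if (length(miss))
    stop("compute_signature: missing selected feature(s): ",
         paste(miss, collapse = ", "))
  X <- table$features[, model$features, drop = FALSE]
  if (!normalized) {
    if (is.null(model$normalization))
      stop("compute_signature: model stores no normalization parameters")
    mu <- model$normalization$mean[model$features]
    sg <- model$normalization$sd[model$features]
    X <- sweep(sweep(X, 2, mu), 2, sg, `/`)
  }
  stats::setNames(as.numeric(X %*% model$coefficients), table$patient_id)
}

#' Predicted probability of generalized epilepsy from a signature model
#' @inheritParams compute_signature
#' @return numeric vector of probabilities.
#' @export
signature_probability <- function(model, table, normalized = TRUE) {
  stats::plogis(model$intercept +
                  compute_signature(model, table, normalized))
}

#' Serialize / restore a signature model as JSON
#'
#' Stores feature names, coefficients, lambda, the lambda grid, the
#' normalization parameters and the registry version.
#'
#' @param model a [signature_model()].
#' @param path output path.
#' @return `path` (write) or a [signature_model()] (read).
#' @export
signature_to_json <- function(model, path) {
  obj <- list(registry_version = REGISTRY_VERSION,
              features = model$features,
              coefficients = as.numeric(model$coefficients),
              intercept = model$intercept,
              lambda = model$lambda,
              lambda_grid = model$lambda_grid,
              cv_error = model$cv_error,
              normalization = if (!is.null(model$normalization))
                list(mean = as.numeric(model$normalization$mean),
                     sd = as.numeric(model$normalization$sd),
                     feature = names(model$normalization$mean)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname signature_to_json
#' @export
signature_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  norm <- if (!is.null(obj$normalization)) {
    list(mean = stats::setNames(obj$normalization$mean,
                                obj$normalization$feature),
         sd = stats::setNames(obj$normalization$sd,
                              obj$normalization$feature))
  }
  signature_model(obj$features, obj$coefficients, obj$intercept, obj$lambda,
                  normalization = norm,
                  extra = list(lambda_grid = obj$lambda_grid,
                               cv_error = obj$cv_error))
}
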