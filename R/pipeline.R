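#' Chronological 1:1 cohort split
#'
#' Orders records by surgery date (ties broken by patient id, which is
#' logged) and assigns the first `floor(n * ratio)` cases to the training
#' cohort and the remainder to validation, mirroring the enrol-order 1:1
#' split (102/103 at n = 205).
#'
#' @param records data.frame with `patient_id` and `surgery_date`
#'   (Date or ISO-8601 string).
#' @param ratio training fraction (default 0.5).
#' @return list with `train` and `validation` character id vectors.
#' @export
split_cohort <- function(records, ratio = 0.5) {
  d <- as.Date(records$surgery_date)
  if (anyNA(d)) stop("split_cohort: unparseable surgery dates")
  if (anyDuplicated(d))
    message("split_cohort: duplicate surgery dates; ties broken by patient_id")
  ord <- order(d, records$patient_id)
  n <- length(ord)
  n_train <- floor(n * ratio)
  list(train = records$patient_id[ord[seq_len(n_train)]],
       validation = records$patient_id[ord[(n_train + 1):n]])
}

#' Perturb a mask to emulate a second rater
#'
#' Randomly toggles a fraction of the interface voxels (boundary ROI
#' voxels are eroded, background voxels adjacent to the ROI are dilated),
#' emulating inter-rater segmentation disagreement. The result is kept
#' nonempty.
#'
#' @param mask binary 3D array.
#' @param rate expected fraction of interface voxels toggled.
#' @return perturbed binary array of the same shape.
#' @export
perturb_mask <- function(mask, rate = 0.1) {
  m <- mask != 0
  bd <- boundary_voxels(m)
  d <- dim(m)
  # background voxels 6-adjacent to the ROI
  grow <- unique(do.call(rbind, lapply(list(c(1, 0, 0), c(-1, 0, 0),
                                            c(0, 1, 0), c(0, -1, 0),
                                            c(0, 0, 1), c(0, 0, -1)),
                                       function(s) sweep(bd, 2, s, `+`))))
  ok <- grow[, 1] >= 1 & grow[, 1] <= d[1] & grow[, 2] >= 1 &
    grow[, 2] <= d[2] & grow[, 3] >= 1 & grow[, 3] <= d[3]
  grow <- grow[ok, , drop = FALSE]
  grow <- grow[!m[grow], , drop = FALSE]
  out <- m
  if (nrow(bd) > 0) {
    flip <- stats::runif(nrow(bd)) < rate
    if (sum(!m) > 0 && sum(m) - sum(flip) < 1) flip[] <- FALSE
    out[bd[flip, , drop = FALSE]] <- FALSE
  }
  if (nrow(grow) > 0) {
    add <- stats::runif(nrow(grow)) < rate
    out[grow[add, , drop = FALSE]] <- TRUE
  }
  if (!any(out)) out <- m
  array(as.integer(out), dim = d)
}

#' Two-way random, absolute-agreement, single-measure ICC
#'
#' Shrout-Fleiss ICC(2,1) from the two-way ANOVA decomposition of an
#' n-subjects by k-raters matrix.
#'
#' @param x numeric matrix, subjects in rows, raters in columns.
#' @return the ICC (scalar).
#' @export
icc_absolute_agreement <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L) stop("icc_absolute_agreement: need >= 2 x 2 data")
  G <- mean(x)
  Ri <- rowMeans(x); Cj <- colMeans(x)
  MSR <- k * sum((Ri - G)^2) / (n - 1)
  MSC <- n * sum((Cj - G)^2) / (k - 1)
  SSE <- sum((x - outer(Ri, rep(1, k)) - outer(rep(1, n), Cj) + G)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
}

#' Reconcile dual-rater segmentations by ICC
#'
#' Computes ICC(2,1) across patients on a per-rater summary series (ROI
#' volumes by default, or any per-patient series via `series`). If the ICC
#' exceeds `icc_threshold`, each patient receives one of the two masks by
#' a seeded uniform draw; otherwise the run halts with a classed error
#' (`epiradiomics_icc_disagreement`) carrying the report.
#'
#' @param masks_a,masks_b lists of binary arrays (same grids, both
#'   nonempty), one pair per patient (>= 5 patients).
#' @param voxel_volume mm^3 per voxel, for the volume series.
#' @param series optional n x 2 matrix replacing the volume series (e.g. a
#'   per-feature series).
#' @param seed integer seed for the rater draws.
#' @param icc_threshold agreement threshold (0.8).
#' @return list: `masks` (chosen per patient), `chosen_rater` ("A"/"B"),
#'   `icc`, `series`.
#' @export
icc_reconcile <- function(masks_a, masks_b, voxel_volume = 1, series = NULL,
                          seed = 1L, icc_threshold = 0.8) {
  n <- length(masks_a)
  if (length(masks_b) != n)
    stop("icc_reconcile: rater mask lists differ in length")
  if (n < 5L) stop("icc_reconcile: need >= 5 patients with both raters")
  if (is.null(series)) {
    series <- cbind(A = vapply(masks_a, function(m) sum(m != 0) * voxel_volume,
                               numeric(1)),
                    B = vapply(masks_b, function(m) sum(m != 0) * voxel_volume,
                               numeric(1)))
  }
  icc <- icc_absolute_agreement(series)
  if (!(icc > icc_threshold)) {
    stop(structure(
      list(message = sprintf(
        "icc_reconcile: inter-rater ICC = %.3f <= %.2f; segmentations disagree, run halted",
        icc, icc_threshold),
        call = NULL, icc = icc, series = series),
      class = c("epiradiomics_icc_disagreement", "error", "condition")))
  }
  choice <- with_seed(seed, ifelse(stats::runif(n) < 0.5, "A", "B"))
  masks <- lapply(seq_len(n), function(i)
    if (choice[i] == "A") masks_a[[i]] else masks_b[[i]])
  list(masks = masks, chosen_rater = choice, icc = icc, series = series)
}

#' Pipeline run configuration
#'
#' @param synthetic a [synthetic_config()] describing the cohort.
#' @param n_levels gray levels for quantization.
#' @param split_ratio training fraction of the chronological split.
#' @param rater_perturbation interface-toggle rate for the emulated second
#'   rater (0 disables the dual-rater stage).
#' @param icc_threshold agreement threshold for [icc_reconcile()].
#' @param seed master seed for the label draws, rater draws and choices.
#' @return list of class `run_config`.
#' @export
run_config <- function(synthetic = synthetic_config(), n_levels = 32L,
                       split_ratio = 0.5, rater_perturbation = 0.05,
                       icc_threshold = 0.8, seed = synthetic$seed) {
  stopifnot(inherits(synthetic, "synthetic_config"))
  if (split_ratio <= 0 || split_ratio >= 1)
    stop("run_config: split_ratio must lie in (0, 1)")
  structure(list(synthetic = synthetic, n_levels = as.integer(n_levels),
                 split_ratio = split_ratio,
                 rater_perturbation = rater_perturbation,
                 icc_threshold = icc_threshold, seed = as.integer(seed)),
            class = "run_config")
}

stage_file <- function(out_dir, name) file.path(out_dir, name)

run_stage <- function(out_dir, resume, filename, compute, write, read) {
  path <- stage_file(out_dir, filename)
  if (resume && file.exists(path)) return(read(path))
  res <- compute()
  write(res, path)
  res
}

#' Run the full pipeline: simulate, reconcile, extract, split, select,
#' evaluate
#'
#' Executes every stage in order, writing each stage's artifact into
#' `out_dir` (cohort manifest, feature table, screening report, signature
#' model JSON, per-cohort evaluation, nomogram lookup, Table-1-style
#' comparison, provenance). With `resume = TRUE`, stages whose artifact
#' already exists are loaded instead of recomputed, producing outputs
#' identical to an uninterrupted run.
#'
#' @param config a [run_config()].
#' @param out_dir run directory (created if needed).
#' @param resume reuse existing stage artifacts.
#' @param verbose log per-stage progress.
#' @return invisible list with all stage results.
#' @export
run_pipeline <- function(config, out_dir, resume = FALSE, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  if (config$synthetic$n_patients < 4L)
    stop("run_pipeline: n_patients must be >= 4")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("run_pipeline: cannot create ", out_dir)
  say <- function(...) if (verbose) message("[pipeline] ", ...)

  # provenance first: the config travels verbatim with the outputs
  cfg_path <- stage_file(out_dir, "run_config.json")
  jsonlite::write_json(
    list(synthetic = unclass(config$synthetic),
         n_levels = config$n_levels, split_ratio = config$split_ratio,
         rater_perturbation = config$rater_perturbation,
         icc_threshold = config$icc_threshold, seed = config$seed),
    cfg_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  say("simulate: generating ", config$synthetic$n_patients, " phantoms")
  cohort <- generate_cohort(config$synthetic)
  manifest <- cohort$manifest
  utils::write.csv(manifest, stage_file(out_dir, "manifest.csv"),
                   row.names = FALSE)

  masks <- lapply(cohort$studies, `[[`, "mask")
  if (config$rater_perturbation > 0) {
    say("reconcile: dual-rater ICC on ROI volumes")
    masks_b <- with_seed(substream_seed(config$seed, 0L, 2L),
                         lapply(masks, perturb_mask,
                                rate = config$rater_perturbation))
    rec <- icc_reconcile(masks, masks_b,
                         voxel_volume = prod(config$synthetic$voxel_spacing),
                         seed = substream_seed(config$seed, 0L, 3L),
                         icc_threshold = config$icc_threshold)
    masks <- rec$masks
    jsonlite::write_json(list(icc = rec$icc, chosen = rec$chosen_rater),
                         stage_file(out_dir, "icc_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  for (i in seq_along(cohort$studies)) cohort$studies[[i]]$mask <- masks[[i]]

  feats <- run_stage(out_dir, resume, "features.csv",
    compute = function() {
      say("extract: 734 features x ", length(cohort$studies), " patients")
      extract_cohort_features(cohort$studies, config$n_levels)
    },
    write = function(x, p) utils::write.csv(x, p, row.names = FALSE),
    read = function(p) utils::read.csv(p, check.names = FALSE))

  say("split: chronological ", config$split_ratio, " split")
  sp <- split_cohort(manifest, config$split_ratio)
  fmat <- as.matrix(feats[, -1, drop = FALSE])
  rownames(fmat) <- feats$patient_id
  labels <- stats::setNames(manifest$epilepsy_type, manifest$patient_id)
  tab <- function(ids, tag)
    feature_table(ids, fmat[ids, , drop = FALSE], unname(labels[ids]), tag)
  train_raw <- tab(sp$train, "train")
  valid_raw <- tab(sp$validation, "validation")

  say("select: z-score + univariate screen + LASSO LOOCV")
  nz <- zscore_fit_apply(train_raw, valid_raw)
  screen <- univariate_screen(nz$train)
  utils::write.csv(screen, stage_file(out_dir, "screening.csv"),
                   row.names = FALSE)
  kept <- screen$feature[screen$kept]
  if (length(kept) < 2L)
    stop("run_pipeline: fewer than 2 features survive screening")
  model <- fit_lasso_loocv(subset_feature_table(nz$train, features = kept),
                           normalization = nz$params)
  signature_to_json(model, stage_file(out_dir, "signature.json"))

  say("evaluate: ROC / calibration / DCA / nomogram")
  sig_train <- compute_signature(model, nz$train)
  sig_valid <- compute_signature(model, nz$other)
  p_train <- signature_probability(model, nz$train)
  p_valid <- signature_probability(model, nz$other)

  eval_cohort <- function(p, y) {
    roc <- roc_auc_ci(p, y)
    hl <- tryCatch(hosmer_lemeshow_calibration(pmin(pmax(p, 1e-12),
                                                    1 - 1e-12), y),
                   error = function(e) NULL)
    list(roc = roc, calibration = hl,
         decision_curve = decision_curve(p, y))
  }
  ev_train <- eval_cohort(p_train, train_raw$labels)
  ev_valid <- eval_cohort(p_valid, valid_raw$labels)

  # nomogram on the pooled cohort (as published); the pooled fit is
  # optimistic for the signature term because selection saw the training
  # half -- flagged here and in the report.
  pooled_ids <- c(sp$train, sp$validation)
  mrows <- manifest[match(pooled_ids, manifest$patient_id), ]
  clin <- data.frame(signature = c(sig_train, sig_valid)[pooled_ids],
                     age = mrows$age, gender = mrows$gender,
                     histopathology = mrows$histopathology)
  y_pool <- as.integer(mrows$epilepsy_type == "generalized")
  aic <- fit_multivariable_aic(clin, y_pool)
  nomo <- build_nomogram(aic)
  utils::write.csv(nomo$lookup, stage_file(out_dir, "nomogram_lookup.csv"),
                   row.names = FALSE)

  cmp <- compare_cohorts(data.frame(
    epilepsy_type = mrows$epilepsy_type, age = mrows$age,
    gender = mrows$gender, histopathology = mrows$histopathology,
    signature = clin$signature))

  report <- list(
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    n = list(total = nrow(manifest), train = length(sp$train),
             validation = length(sp$validation)),
    prevalence = mean(manifest$epilepsy_type == "generalized"),
    selected_features = model$features,
    lambda = model$lambda,
    train = list(auc = ev_train$roc$auc, ci = ev_train$roc$ci,
                 accuracy = ev_train$roc$accuracy,
                 hl_p = ev_train$calibration$p_value),
    validation = list(auc = ev_valid$roc$auc, ci = ev_valid$roc$ci,
                      accuracy = ev_valid$roc$accuracy,
                      hl_p = ev_valid$calibration$p_value),
    nomogram = list(retained = aic$retained, aic = aic$aic,
                    note = paste("pooled-cohort fit; signature term is",
                                 "optimistic because feature selection",
                                 "used the training half")),
    comparison = cmp$tests)
  jsonlite::write_json(report, stage_file(out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(ev_train$decision_curve,
                   stage_file(out_dir, "dca_train.csv"), row.names = FALSE)
  utils::write.csv(ev_valid$decision_curve,
                   stage_file(out_dir, "dca_validation.csv"),
                   row.names = FALSE)

  invisible(list(cohort = cohort, features = feats, split = sp,
                 screen = screen, model = model,
                 signature = list(train = sig_train, validation = sig_valid),
                 evaluation = list(train = ev_train, validation = ev_valid),
                 aic = aic, nomogram = nomo, comparison = cmp,
                 report = report))
}
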