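#' Configuration for a synthetic phantom cohort
#'
#' The defaults state the emulated world: a cohort of 205 patients with a
#' 67.8% prevalence of generalized epilepsy, ellipsoidal hyperintense
#' tumors of 6-14 mm radius on a 64 x 64 x 32 grid with anisotropic 2 x 2 x
#' 4 mm voxels (128 mm cube field of view), multiplicative correlated
#' Gaussian texture with heterogeneity in [0.05, 0.6], and a planted
#' logistic effect of the Chebyshev AC-centroid distance and the texture
#' heterogeneity on the epilepsy type, scaled so the population AUC of the
#' planted linear effect is `target_auc` (0.85, the scale of the published
#' signature discrimination).
#'
#' @param n_patients cohort size (>= 4).
#' @param grid_shape voxels per axis.
#' @param voxel_spacing mm per axis.
#' @param tumor_radius_range mm, min/max of the base semi-axis.
#' @param texture_heterogeneity_range dimensionless in [0, 1].
#' @param effect_coefficients named log-odds weights per latent covariate
#'   (on standardized covariates). `NULL` scales the default direction
#'   (Chebyshev distance 1.0, heterogeneity 0.8) to `target_auc`.
#' @param base_prevalence probability of generalized epilepsy, in (0, 1).
#' @param target_auc population AUC of the planted linear effect used when
#'   `effect_coefficients` is `NULL`.
#' @param background,tumor_intensity,noise_sd intensity model: uniform
#'   background, tumor plateau, and additive Gaussian noise sd applied to
#'   the whole volume after construction.
#' @param seed integer master seed; all randomness flows from it through
#'   per-patient substreams.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 205L,
                             grid_shape = c(64L, 64L, 32L),
                             voxel_spacing = c(2, 2, 4),
                             tumor_radius_range = c(6, 14),
                             texture_heterogeneity_range = c(0.05, 0.6),
                             effect_coefficients = NULL,
                             base_prevalence = 0.678,
                             target_auc = 0.85,
                             background = 20,
                             tumor_intensity = 100,
                             noise_sd = 2,
                             seed = 17L) {
  if (n_patients < 4L) stop("synthetic_config: n_patients must be >= 4")
  if (base_prevalence <= 0 || base_prevalence >= 1)
    stop("synthetic_config: base_prevalence must lie in (0, 1)")
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop("synthetic_config: grid_shape must be 3 values >= 8")
  if (diff(tumor_radius_range) < 0 || tumor_radius_range[1] <= 0)
    stop("synthetic_config: invalid tumor_radius_range")
  if (is.null(effect_coefficients)) {
    w <- c(chebyshev = 1.0, heterogeneity = 0.8)
    gamma <- calibrate_logistic_effect(target_auc, base_prevalence)$gamma
    effect_coefficients <- gamma * w / sqrt(sum(w^2))
  }
  structure(list(n_patients = as.integer(n_patients),
                 grid_shape = as.integer(grid_shape),
                 voxel_spacing = as.numeric(voxel_spacing),
                 tumor_radius_range = as.numeric(tumor_radius_range),
                 texture_heterogeneity_range =
                   as.numeric(texture_heterogeneity_range),
                 effect_coefficients = effect_coefficients,
                 base_prevalence = base_prevalence,
                 target_auc = target_auc,
                 background = background,
                 tumor_intensity = tumor_intensity,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-patient substream seed (kept below 2^31).
substream_seed <- function(seed, index, stream = 0L) {
  as.integer((as.numeric(seed) * 48271 + index * 9973 + stream * 7919) %%
               2147483563)
}

#' Calibrate a logistic label model to a target population AUC
#'
#' For a standard-normal latent score `u` and labels drawn with
#' `P(y = 1 | u) = plogis(alpha + gamma * u)`, returns the slope `gamma`
#' whose induced class-conditional distributions of `u` have the requested
#' AUC, and the intercept `alpha` giving the requested prevalence. Solved
#' by deterministic quadrature (no randomness), so the planted effect size
#' is an analytic property of the stated world, not a tuned constant.
#'
#' @param target_auc desired population AUC of `u`, in (0.5, 1).
#' @param prevalence desired `P(y = 1)`, in (0, 1).
#' @return list with `gamma`, `alpha`, and the achieved `auc`.
#' @export
calibrate_logistic_effect <- function(target_auc = 0.85, prevalence = 0.678) {
  if (target_auc <= 0.5 || target_auc >= 1)
    stop("calibrate_logistic_effect: target_auc must be in (0.5, 1)")
  u <- seq(-7, 7, by = 0.005)
  w <- stats::dnorm(u); w <- w / sum(w)
  alpha_for <- function(gamma) {
    stats::uniroot(function(a) sum(w * stats::plogis(a + gamma * u)) -
                     prevalence, c(-40, 40), tol = 1e-12)$root
  }
  auc_for <- function(gamma) {
    p <- stats::plogis(alpha_for(gamma) + gamma * u)
    pi1 <- sum(w * p)
    f1 <- w * p / pi1
    f0 <- w * (1 - p) / (1 - pi1)
    cum0 <- cumsum(f0) - f0 / 2 # midpoint tie handling on the grid
    sum(f1 * cum0)
  }
  gamma <- stats::uniroot(function(g) auc_for(g) - target_auc, c(1e-3, 30),
                          tol = 1e-9)$root
  list(gamma = gamma, alpha = alpha_for(gamma), auc = auc_for(gamma))
}

#' Generate one synthetic phantom study
#'
#' An axis-aligned ellipsoid of hyperintense tumor tissue with
#' multiplicative correlated Gaussian texture, embedded in a uniform
#' low-intensity background; additive Gaussian noise is applied to the
#' whole volume last. The anterior commissure is fixed at the grid's
#' physical center. The recorded latent covariates are the Chebyshev
#' distance of the tumor centroid from the AC (mm) and the texture
#' heterogeneity parameter.
#'
#' @param config a [synthetic_config()].
#' @param patient_index 1-based index, `<= n_patients`.
#' @param centroid optional forced tumor centroid (mm); by default sampled
#'   uniformly within the margins that keep the ellipsoid inside the grid.
#' @param ac optional anterior-commissure override (mm).
#' @return object of class `phantom_study`: `volume` ([image_volume()]),
#'   `mask`, `ac_coordinate`, `record` (epilepsy type unset), and
#'   `latent_covariates`.
#' @export
generate_phantom <- function(config, patient_index, centroid = NULL,
                             ac = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (patient_index < 1L || patient_index > config$n_patients)
    stop("generate_phantom: patient_index out of range")
  g <- config$grid_shape; sp <- config$voxel_spacing
  extent <- (g - 1) * sp
  if (2 * max(config$tumor_radius_range) >= min(extent))
    stop("generate_phantom: tumor_radius_range too large for the grid ",
         "(diameter ", 2 * max(config$tumor_radius_range),
         " mm vs extent ", min(extent), " mm)")
  if (is.null(ac)) ac <- extent / 2
  forced_centroid <- centroid

  with_seed(substream_seed(config$seed, patient_index), {
    r <- stats::runif(1, config$tumor_radius_range[1],
                      config$tumor_radius_range[2])
    semi <- r * stats::runif(3, 0.75, 1.25)
    semi <- pmin(semi, (extent - sp) / 2)
    lo <- semi + sp / 2
    hi <- extent - semi - sp / 2
    if (any(hi < lo))
      stop("generate_phantom: tumor does not fit inside the grid")
    centroid <- if (is.null(forced_centroid)) stats::runif(3, lo, hi)
      else as.numeric(forced_centroid)
    h <- stats::runif(1, config$texture_heterogeneity_range[1],
                      config$texture_heterogeneity_range[2])

    xs <- (seq_len(g[1]) - 1) * sp[1]
    ys <- (seq_len(g[2]) - 1) * sp[2]
    zs <- (seq_len(g[3]) - 1) * sp[3]
    d2 <- outer(outer(((xs - centroid[1]) / semi[1])^2,
                      ((ys - centroid[2]) / semi[2])^2, `+`),
                ((zs - centroid[3]) / semi[3])^2, `+`)
    mask <- array(as.integer(d2 <= 1), dim = g)
    if (!any(mask == 1L)) stop("generate_phantom: degenerate empty tumor")

    field <- smooth_field(array(stats::rnorm(prod(g)), dim = g))
    fv <- field[mask == 1L]
    fsd <- stats::sd(fv)
    if (length(fv) > 1L && fsd > 0) {
      field <- (field - mean(fv)) / fsd
    } else {
      field[] <- 0
    }
    vol <- array(config$background, dim = g)
    vol[mask == 1L] <- config$tumor_intensity * exp(h * field[mask == 1L])
    if (config$noise_sd > 0)
      vol <- vol + array(stats::rnorm(prod(g), 0, config$noise_sd), dim = g)

    age <- round(pmin(70, pmax(15, stats::rnorm(1, 38, 12))))
    gender <- sample(c("male", "female"), 1, prob = c(0.62, 0.38))
    histo <- sample(c("oligodendroglial", "astrocytoma"), 1,
                    prob = c(0.66, 0.34))

    structure(list(
      volume = image_volume(vol, sp, c(0, 0, 0)),
      mask = mask,
      ac_coordinate = ac,
      record = list(patient_id = sprintf("P%04d", patient_index),
                    age = age, gender = gender, histopathology = histo,
                    surgery_date = NA, epilepsy_type = NA_character_),
      latent_covariates = c(chebyshev = max(abs(centroid - ac)),
                            heterogeneity = h)),
      class = "phantom_study")
  })
}

# Light 3D smoothing with a separable 1-2-1 kernel (two passes) to induce
# spatial correlation in the texture field.
smooth_field <- function(a, passes = 2L) {
  shift_ax <- function(x, ax, by) {
    d <- dim(x)
    idx <- lapply(d, seq_len)
    src <- pmin(pmax(idx[[ax]] + by, 1L), d[ax]) # replicate edges
    idx[[ax]] <- src
    do.call(`[`, c(list(x), idx))
  }
  for (p in seq_len(passes)) {
    for (ax in 1:3) {
      a <- (shift_ax(a, ax, -1L) + 2 * a + shift_ax(a, ax, 1L)) / 4
    }
  }
  a
}

#' Assign epilepsy type labels from latent covariates
#'
#' Labels are drawn from a logistic model on the standardized covariates,
#' `P(generalized) = plogis(alpha + z %*% beta)`, with the intercept
#' `alpha` solved so that the mean predicted probability over the supplied
#' sample equals `base_prevalence`. Covariates are standardized within the
#' supplied sample (a cohort); pass pre-standardized covariates and
#' `standardize = FALSE` to skip that.
#'
#' @param latent_covariates numeric matrix (patients x covariates) or a
#'   single patient's named vector.
#' @param effect_coefficients log-odds weights, recycled/matched by name
#'   against the covariate columns; all finite.
#' @param base_prevalence target mean probability.
#' @param standardize z-score the covariates within the sample first.
#' @return list with `type` (character, `"generalized"`/`"focal"`),
#'   `probability`, and `intercept`.
#' @export
assign_epilepsy_type <- function(latent_covariates, effect_coefficients,
                                 base_prevalence, standardize = TRUE) {
  z <- if (is.matrix(latent_covariates)) latent_covariates else
    matrix(latent_covariates, nrow = 1,
           dimnames = list(NULL, names(latent_covariates)))
  if (any(!is.finite(effect_coefficients)))
    stop("assign_epilepsy_type: effect coefficients must be finite")
  if (!is.null(names(effect_coefficients)) && !is.null(colnames(z)))
    z <- z[, names(effect_coefficients), drop = FALSE]
  if (standardize && nrow(z) > 1L) {
    z <- scale(z)
    z[, attr(z, "scaled:scale") == 0] <- 0
  }
  s <- as.numeric(z %*% effect_coefficients)
  alpha <- stats::uniroot(function(a) mean(stats::plogis(a + s)) -
                            base_prevalence, c(-50, 50), tol = 1e-12)$root
  p <- stats::plogis(alpha + s)
  type <- ifelse(stats::runif(length(p)) < p, "generalized", "focal")
  list(type = type, probability = p, intercept = alpha)
}

#' Generate a reproducible phantom cohort
#'
#' Generates `n_patients` phantom studies with per-patient substreams of
#' the master seed, assigns epilepsy labels from the planted logistic
#' effect, and attaches evenly spaced, strictly increasing synthetic
#' surgery dates. Optionally writes volumes/masks as NIfTI-1, the manifest
#' as CSV and the config as JSON.
#'
#' @param config a [synthetic_config()].
#' @param out_dir if non-`NULL`, write the cohort there.
#' @return object of class `phantom_cohort`: `studies` (list of
#'   `phantom_study` with labels filled in), `manifest` (data.frame),
#'   `config`.
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_patients
  studies <- lapply(seq_len(n), function(i) generate_phantom(config, i))

  latent <- do.call(rbind, lapply(studies, `[[`, "latent_covariates"))
  lab <- with_seed(substream_seed(config$seed, 0L, 1L),
                   assign_epilepsy_type(latent, config$effect_coefficients,
                                        config$base_prevalence))
  dates <- as.Date("2012-09-01") + (seq_len(n) - 1L) * 4L
  for (i in seq_len(n)) {
    studies[[i]]$record$epilepsy_type <- lab$type[i]
    studies[[i]]$record$surgery_date <- dates[i]
  }

  manifest <- data.frame(
    patient_id = vapply(studies, function(s) s$record$patient_id, ""),
    age = vapply(studies, function(s) s$record$age, 0),
    gender = vapply(studies, function(s) s$record$gender, ""),
    histopathology = vapply(studies, function(s) s$record$histopathology, ""),
    surgery_date = format(dates, "%Y-%m-%d"),
    epilepsy_type = lab$type,
    ac_x = vapply(studies, function(s) s$ac_coordinate[1], 0),
    ac_y = vapply(studies, function(s) s$ac_coordinate[2], 0),
    ac_z = vapply(studies, function(s) s$ac_coordinate[3], 0),
    latent_chebyshev = latent[, "chebyshev"],
    latent_heterogeneity = latent[, "heterogeneity"],
    volume_path = NA_character_, mask_path = NA_character_,
    stringsAsFactors = FALSE)

  cohort <- structure(list(studies = studies, manifest = manifest,
                           config = config), class = "phantom_cohort")
  if (!is.null(out_dir)) cohort <- write_cohort(cohort, out_dir)
  cohort
}

#' Write a phantom cohort to disk
#'
#' Volumes as float32 and masks as uint8 NIfTI-1 (`.nii.gz`), the manifest
#' as `manifest.csv` and the config as `config.json`.
#'
#' @param cohort a `phantom_cohort`.
#' @param out_dir output directory (created if needed).
#' @return the cohort with manifest paths filled in, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("write_cohort: cannot create output directory ", out_dir)
  for (i in seq_along(cohort$studies)) {
    st <- cohort$studies[[i]]
    vp <- file.path(out_dir, paste0(st$record$patient_id, "_T2.nii.gz"))
    mp <- file.path(out_dir, paste0(st$record$patient_id, "_mask.nii.gz"))
    nifti_write(st$volume, vp, "float32")
    nifti_write(image_volume(cohort$studies[[i]]$mask, st$volume$spacing,
                             st$volume$origin), mp, "uint8")
    cohort$manifest$volume_path[i] <- vp
    cohort$manifest$mask_path[i] <- mp
  }
  utils::write.csv(cohort$manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  cfg <- cohort$config
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(cohort)
}

#' Simulate a feature-table cohort with planted informative features
#'
#' Generates a patients-by-features table of standard-normal radiomic-like
#' features in which `n_informative` planted features carry a logistic
#' effect on the label, plus independent pure-noise features. The planted
#' features share a common latent factor with loading `planted_loading`
#' (pairwise correlation `planted_loading^2`), mirroring the strong
#' within-signature correlation of real radiomic features; labels are
#' drawn from a logistic model on the standardized equal-weight planted
#' score, scaled (via [calibrate_logistic_effect()]) so that score's
#' population AUC equals `target_auc` exactly. This exercises the
#' screening/LASSO/evaluation stages at full cohort size without the cost
#' of image synthesis and extraction.
#'
#' With the default loading 0.7 each planted feature has a univariate
#' population AUC near 0.79 while the combined score sits at the requested
#' 0.85; fully independent planted features (`planted_loading = 0`) would
#' push the per-feature AUC down to ~0.64, where the p<0.05 / AUC>0.6
#' screen drops them too often for a recovery test to be meaningful.
#'
#' @param n patients.
#' @param n_noise pure-noise features.
#' @param n_informative planted features (equal weights).
#' @param target_auc population AUC of the planted equal-weight score.
#' @param prevalence probability of the positive (generalized) class.
#' @param planted_loading common-factor loading of the planted features,
#'   in `[0, 1)`.
#' @param seed integer seed.
#' @return a [feature_table()] with features named `planted_1..k` and
#'   `noise_1..m`; attribute `planted` holds the planted feature names.
#' @export
simulate_feature_cohort <- function(n = 205L, n_noise = 100L,
                                    n_informative = 4L, target_auc = 0.85,
                                    prevalence = 0.678,
                                    planted_loading = 0.7, seed = 1L) {
  if (planted_loading < 0 || planted_loading >= 1)
    stop("simulate_feature_cohort: planted_loading must be in [0, 1)")
  cal <- calibrate_logistic_effect(target_auc, prevalence)
  a <- planted_loading
  with_seed(seed, {
    v <- stats::rnorm(n)
    zi <- a * v + sqrt(1 - a^2) *
      matrix(stats::rnorm(n * n_informative), n, n_informative)
    zn <- matrix(stats::rnorm(n * n_noise), n, n_noise)
    score_sd <- sqrt(n_informative^2 * a^2 + n_informative * (1 - a^2))
    u <- rowSums(zi) / score_sd
    p <- stats::plogis(cal$alpha + cal$gamma * u)
    y <- as.integer(stats::runif(n) < p)
    X <- cbind(zi, zn)
    colnames(X) <- c(paste0("planted_", seq_len(n_informative)),
                     paste0("noise_", seq_len(n_noise)))
    ft <- feature_table(sprintf("S%04d", seq_len(n)), X, y)
    attr(ft, "planted") <- paste0("planted_", seq_len(n_informative))
    ft
  })
}
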