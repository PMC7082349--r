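FOS_NAMES <- c("energy", "entropy", "kurtosis", "skewness", "mean", "median",
               "maximum", "minimum", "range", "mean_absolute_deviation",
               "root_mean_square", "standard_deviation", "variance",
               "uniformity", "percentile_10", "percentile_90",
               "interquartile_range")
SHAPE_NAMES <- c("volume", "surface_area", "surface_to_volume_ratio",
                 "sphericity", "compactness1", "compactness2",
                 "spherical_disproportion", "max_3d_diameter")
LOCATION_NAMES <- c("r", "theta", "phi", "city_block", "chebyshev",
                    "euclidean")
GLCM_NAMES <- c("autocorrelation", "cluster_prominence", "cluster_shade",
                "cluster_tendency", "contrast", "correlation",
                "difference_average", "difference_entropy",
                "difference_variance", "dissimilarity", "inverse_difference",
                "inverse_difference_moment",
                "inverse_difference_moment_normalized",
                "inverse_difference_normalized",
                "informational_measure_correlation1",
                "informational_measure_correlation2", "inverse_variance",
                "joint_average", "joint_energy", "joint_entropy",
                "maximum_probability", "maximal_correlation_coefficient",
                "sum_average", "sum_entropy", "sum_variance",
                "sum_of_squares")
GLRLM_NAMES <- c("short_run_emphasis", "long_run_emphasis",
                 "gray_level_nonuniformity",
                 "gray_level_nonuniformity_normalized",
                 "run_length_nonuniformity",
                 "run_length_nonuniformity_normalized", "run_percentage",
                 "gray_level_variance", "run_variance", "run_entropy",
                 "low_gray_level_run_emphasis", "high_gray_level_run_emphasis",
                 "short_run_low_gray_level_emphasis",
                 "short_run_high_gray_level_emphasis",
                 "long_run_low_gray_level_emphasis",
                 "long_run_high_gray_level_emphasis")
GLSZM_NAMES <- c("small_area_emphasis", "large_area_emphasis",
                 "gray_level_nonuniformity",
                 "gray_level_nonuniformity_normalized",
                 "size_zone_nonuniformity",
                 "size_zone_nonuniformity_normalized", "zone_percentage",
                 "gray_level_variance", "zone_variance", "zone_entropy",
                 "low_gray_level_zone_emphasis", "high_gray_level_zone_emphasis",
                 "small_area_low_gray_level_emphasis",
                 "small_area_high_gray_level_emphasis",
                 "large_area_low_gray_level_emphasis",
                 "large_area_high_gray_level_emphasis")
NGTDM_NAMES <- c("coarseness", "contrast", "busyness", "complexity",
                 "strength")
WAVELET_BANDS <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
REGISTRY_VERSION <- "1.0.0"

#' The 734-feature registry
#'
#' The full ordered catalogue of feature names with their family and the
#' image (original or Coiflet-1 sub-band) they are computed on: 6 location,
#' 17 first-order, 8 shape, 26 GLCM, 16 GLRLM, 16 GLSZM and 5 NGTDM
#' features on the original image, and the 80 intensity-based features
#' (first-order + texture) on each of the 8 wavelet sub-bands (640). The
#' registry is the authoritative definition of the feature order and
#' naming; [write_feature_registry()] serializes it with the formula
#' conventions.
#'
#' @return data.frame with columns `name`, `family`, `image` (734 rows).
#' @export
feature_registry <- function() {
  rows <- list(
    data.frame(name = paste0("location_", LOCATION_NAMES),
               family = "location", image = "original"),
    data.frame(name = paste0("original_FOS_", FOS_NAMES),
               family = "FOS", image = "original"),
    data.frame(name = paste0("original_shape_", SHAPE_NAMES),
               family = "shape", image = "original"),
    data.frame(name = paste0("original_GLCM_", GLCM_NAMES),
               family = "GLCM", image = "original"),
    data.frame(name = paste0("original_GLRLM_", GLRLM_NAMES),
               family = "GLRLM", image = "original"),
    data.frame(name = paste0("original_GLSZM_", GLSZM_NAMES),
               family = "GLSZM", image = "original"),
    data.frame(name = paste0("original_NGTDM_", NGTDM_NAMES),
               family = "NGTDM", image = "original"))
  for (b in WAVELET_BANDS) {
    pre <- paste0("Coiflet_", b, "_")
    rows <- c(rows, list(
      data.frame(name = paste0(pre, "FOS_", FOS_NAMES),
                 family = "wavelet", image = b),
      data.frame(name = paste0(pre, "GLCM_", GLCM_NAMES),
                 family = "wavelet", image = b),
      data.frame(name = paste0(pre, "GLRLM_", GLRLM_NAMES),
                 family = "wavelet", image = b),
      data.frame(name = paste0(pre, "GLSZM_", GLSZM_NAMES),
                 family = "wavelet", image = b),
      data.frame(name = paste0(pre, "NGTDM_", NGTDM_NAMES),
                 family = "wavelet", image = b)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize the feature registry to JSON
#'
#' @param path output path.
#' @param n_levels gray-level count recorded alongside the catalogue.
#' @return `path`, invisibly.
#' @export
write_feature_registry <- function(path, n_levels = 32L) {
  reg <- feature_registry()
  obj <- list(
    version = REGISTRY_VERSION,
    n_features = nrow(reg),
    conventions = list(
      quantization = sprintf(
        "%d equal-width levels over the within-ROI intensity range, recomputed per image and sub-band", n_levels),
      glcm_glrlm = "distance 1, 13 unique 3D directions, features averaged over directions",
      glszm_ngtdm = "26-connectivity zones / 26-neighborhood means",
      fos_moments = "population (n) denominators; kurtosis non-excess",
      surface = "marching-tetrahedra mesh of the 0.5 isosurface",
      wavelet = "one-level periodized orthonormal Coiflet-1 3D transform; sub-bands reconstructed onto the original grid",
      angles = "theta from +z (superior) in [0, pi]; phi from +x, (-pi, pi]; 0 at zero displacement",
      degenerate = "single-level ROI: correlation-type GLCM features are 0"),
    features = reg)
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

# First-order + texture block for one image (80 values, unprefixed families).
fos_texture_block <- function(img, mask, n_levels = 32L) {
  fos <- extract_fos(img, mask, n_levels)
  lev <- quantize_intensities(img, mask, n_levels)
  tex <- texture_features(build_texture_matrices(lev))
  c(stats::setNames(fos, paste0("FOS_", names(fos))), tex)
}

#' Extract the full 734-feature radiomic vector
#'
#' Computes location features from the tumor centroid and the anterior
#' commissure coordinate, shape features from the mask geometry, and the 80
#' intensity-based features (17 first-order + 63 texture) on the original
#' image and on each of the 8 Coiflet-1 wavelet sub-bands, all restricted
#' to the ROI. Quantization to `n_levels` equal-width gray levels is
#' recomputed per image.
#'
#' @param volume [image_volume()] (or 3D array with unit geometry).
#' @param mask binary 3D array on the volume's grid.
#' @param ac anterior-commissure coordinate in mm (length 3).
#' @param n_levels gray levels for quantization (default 32).
#' @param study_id used in error messages.
#' @return named numeric vector of length 734 in registry order.
#' @export
extract_all <- function(volume, mask, ac, n_levels = 32L,
                        study_id = "<unnamed>") {
  if (is.array(volume)) volume <- image_volume(volume)
  if (!identical(dim(volume$data), dim(mask)))
    stop("extract_all: volume and mask grids differ for study ", study_id)
  if (!any(mask != 0))
    stop("extract_all: empty mask for study ", study_id)

  centroid <- compute_centroid(mask, volume$spacing, volume$origin, study_id)
  loc <- extract_location_features(centroid, ac)
  shp <- extract_shape(mask, volume$spacing)
  orig <- fos_texture_block(volume$data, mask, n_levels)
  bands <- wavelet_decompose(volume$data)
  wav <- unlist(lapply(WAVELET_BANDS, function(b) {
    blk <- fos_texture_block(bands[[b]], mask, n_levels)
    stats::setNames(blk, paste0("Coiflet_", b, "_", names(blk)))
  }))

  out <- c(stats::setNames(loc, paste0("location_", names(loc))),
           stats::setNames(orig[paste0("FOS_", FOS_NAMES)],
                           paste0("original_FOS_", FOS_NAMES)),
           stats::setNames(shp, paste0("original_shape_", names(shp))),
           stats::setNames(orig[-seq_along(FOS_NAMES)],
                           paste0("original_", names(orig)[-seq_along(FOS_NAMES)])))
  out <- c(out, wav)
  reg <- feature_registry()
  out <- out[reg$name]
  names(out) <- reg$name
  bad <- !is.finite(out)
  if (any(bad))
    stop("extract_all: non-finite feature(s) ",
         paste(reg$name[bad], collapse = ", "), " for study ", study_id)
  out
}

#' Extract features for a whole cohort
#'
#' @param cohort list of phantom studies from [generate_cohort()], or any
#'   list whose elements have `volume`, `mask`, `ac_coordinate` and
#'   `record$patient_id`.
#' @param n_levels gray levels for quantization.
#' @param verbose print per-study progress.
#' @return data.frame with `patient_id` plus 734 feature columns.
#' @export
extract_cohort_features <- function(cohort, n_levels = 32L, verbose = FALSE) {
  rows <- lapply(cohort, function(st) {
    if (verbose) message("extracting ", st$record$patient_id)
    extract_all(st$volume, st$mask, st$ac_coordinate, n_levels,
                study_id = st$record$patient_id)
  })
  out <- as.data.frame(do.call(rbind, rows))
  data.frame(patient_id = vapply(cohort, function(st) st$record$patient_id,
                                 character(1)),
             out, check.names = FALSE)
}
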