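#' Tumor centroid in physical coordinates
#'
#' Unweighted mean of the ROI voxel centers, in mm. Voxel `(i,j,k)` (0-based)
#' has center `origin + c(i,j,k) * spacing`.
#'
#' @param mask binary 3D array (nonzero = ROI).
#' @param spacing,origin geometry of the grid (mm).
#' @param study_id used in error messages.
#' @return numeric length-3 point in mm.
#' @export
compute_centroid <- function(mask, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                             study_id = "<unnamed>") {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("compute_centroid: empty ROI mask for study ", study_id)
  colMeans((idx - 1) * rep(spacing, each = nrow(idx))) + origin
}

#' Location features of a tumor centroid relative to the anterior commissure
#'
#' Six location features of the displacement `d = centroid - ac`:
#' spherical radius `r` (identical to the Euclidean distance, both kept as
#' separate named features), polar angle `theta` measured from the superior
#' +z axis in `[0, pi]`, azimuth `phi` measured from +x in the axial plane
#' in `(-pi, pi]`, and the city-block, Chebyshev and Euclidean distances
#' (mm). At `d = 0` both angles are defined as 0.
#'
#' @param centroid,ac points in mm (length 3, finite).
#' @return named numeric vector
#'   `c(r, theta, phi, city_block, chebyshev, euclidean)`.
#' @export
extract_location_features <- function(centroid, ac) {
  d <- as.numeric(centroid) - as.numeric(ac)
  if (length(d) != 3L || any(!is.finite(d)))
    stop("extract_location_features: points must be finite length-3")
  r <- sqrt(sum(d^2))
  theta <- if (r == 0) 0 else acos(pmin(1, pmax(-1, d[3] / r)))
  phi <- if (d[1] == 0 && d[2] == 0) 0 else atan2(d[2], d[1])
  c(r = r, theta = theta, phi = phi,
    city_block = sum(abs(d)), chebyshev = max(abs(d)), euclidean = r)
}

#' Quantize within-ROI intensities to gray levels
#'
#' Equal-width binning of the within-ROI intensities over their own
#' `[min, max]` range into `n_levels` integer levels `1..n_levels`.
#' A constant ROI maps entirely to level 1. Voxels outside the ROI are
#' level 0 in the returned array.
#'
#' @param volume 3D numeric array or [image_volume()].
#' @param mask binary 3D array on the same grid.
#' @param n_levels number of gray levels (default 32, minimum 2).
#' @return integer 3D array of levels, 0 outside the ROI; attribute
#'   `n_levels` carries the level count.
#' @export
quantize_intensities <- function(volume, mask, n_levels = 32L) {
  if (inherits(volume, "image_volume")) volume <- volume$data
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop("quantize_intensities: n_levels must be >= 2")
  if (!identical(dim(volume), dim(mask)))
    stop("quantize_intensities: volume and mask dimensions differ")
  roi <- mask != 0
  if (!any(roi)) stop("quantize_intensities: empty ROI")
  x <- volume[roi]
  lo <- min(x); hi <- max(x)
  lev <- array(0L, dim = dim(volume))
  if (hi == lo) {
    lev[roi] <- 1L
  } else {
    # bin k covers [lo + (k-1)w, lo + kw); the maximum lands in bin n_levels
    lev[roi] <- pmin(n_levels, 1L + as.integer(floor((x - lo) / (hi - lo) * n_levels)))
  }
  attr(lev, "n_levels") <- n_levels
  lev
}

#' First-order statistics of the within-ROI intensity distribution
#'
#' The 17 first-order features: energy, entropy, kurtosis, skewness, mean,
#' median, maximum, minimum, range, mean absolute deviation, root mean
#' square, standard deviation, variance, uniformity, 10th percentile, 90th
#' percentile, and interquartile range. Moments use population (n)
#' denominators; kurtosis is non-excess (3 for a normal); entropy (bits)
#' and uniformity are computed on the same equal-width discretization used
#' by the texture matrices. A single-voxel or constant ROI yields zero
#' dispersion, skewness and kurtosis rather than an error.
#'
#' @inheritParams quantize_intensities
#' @return named numeric vector of length 17.
#' @export
extract_fos <- function(volume, mask, n_levels = 32L) {
  if (inherits(volume, "image_volume")) volume <- volume$data
  x <- volume[mask != 0]
  if (length(x) == 0L) stop("extract_fos: empty ROI")
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  lev <- quantize_intensities(volume, mask, n_levels)[mask != 0]
  p <- tabulate(lev, nbins = attr(lev, "n_levels") %||% max(lev)) / n
  p <- p[p > 0]
  qs <- unname(stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), type = 7))
  c(energy = sum(x^2),
    entropy = -sum(p * log2(p)),
    kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    mean = mu,
    median = stats::median(x),
    maximum = max(x),
    minimum = min(x),
    range = max(x) - min(x),
    mean_absolute_deviation = mean(abs(x - mu)),
    root_mean_square = sqrt(mean(x^2)),
    standard_deviation = sqrt(m2),
    variance = m2,
    uniformity = sum(p^2),
    percentile_10 = qs[1],
    percentile_90 = qs[4],
    interquartile_range = qs[3] - qs[2])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
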