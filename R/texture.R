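#' The 13 unique 3D direction offsets at Chebyshev distance 1
#'
#' Half of the 26-neighborhood, one representative per +/- pair, used for
#' GLCM pairs and GLRLM runs.
#'
#' @return 13 x 3 integer matrix of voxel-step offsets.
#' @export
texture_directions <- function() {
  m <- rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
    c(0, 1, 1), c(0, 1, -1),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
  storage.mode(m) <- "integer"
  m
}

#' Build the four texture matrices from a quantized ROI
#'
#' GLCM: symmetric pair counts per direction, normalized to a probability
#' matrix per direction, plus the aggregate (mean over directions that
#' contain at least one pair). GLRLM: maximal same-level run counts per
#' direction. GLSZM: 26-connected equal-level zone counts by level and
#' size. NGTDM: per-level valid-voxel counts `n_i` and summed absolute
#' differences from the 26-neighborhood ROI mean `s_i`.
#'
#' @param levels integer level array from [quantize_intensities()]
#'   (0 outside the ROI).
#' @param n_levels number of gray levels; defaults to the array's
#'   `n_levels` attribute.
#' @return list with elements `glcm` (`directional` ng x ng x 13 probability
#'   array, `counts`, `aggregated`), `glrlm` (ng x Lmax x 13 counts),
#'   `glszm` (ng x Zmax counts), `ngtdm` (`n`, `s`, `p`), `n_voxels`, `ng`.
#' @export
build_texture_matrices <- function(levels, n_levels = NULL) {
  ng <- as.integer(n_levels %||% attr(levels, "n_levels") %||% max(levels))
  dm <- dim(levels)
  if (is.null(dm) || length(dm) != 3L)
    stop("build_texture_matrices: levels must be a 3D array")
  lv <- as.integer(levels)
  np <- sum(lv > 0L)
  if (np == 0L) stop("build_texture_matrices: empty ROI")
  dirs <- texture_directions()
  nd <- nrow(dirs)

  raw <- .glcm_counts(lv, dm, ng, dirs)
  gl_dir <- array(0, dim = dim(raw))
  counts <- array(0L, dim = dim(raw))
  for (d in seq_len(nd)) {
    sym <- raw[, , d] + t(raw[, , d])
    counts[, , d] <- sym
    tot <- sum(sym)
    if (tot > 0) gl_dir[, , d] <- sym / tot
  }
  has_pairs <- apply(counts, 3, sum) > 0
  aggregated <- if (any(has_pairs)) {
    apply(gl_dir[, , has_pairs, drop = FALSE], c(1, 2), mean)
  } else {
    matrix(0, ng, ng)
  }

  glrlm <- .glrlm_counts(lv, dm, ng, dirs, max(dm))

  zones <- .glszm_zones(lv, dm)
  zmax <- max(zones[, 2])
  glszm <- matrix(0L, ng, zmax)
  for (z in seq_len(nrow(zones)))
    glszm[zones[z, 1], zones[z, 2]] <- glszm[zones[z, 1], zones[z, 2]] + 1L

  nt <- .ngtdm_counts(lv, dm, ng)
  ntot <- sum(nt$n)
  list(glcm = list(directional = gl_dir, counts = counts,
                   aggregated = aggregated, has_pairs = has_pairs),
       glrlm = glrlm,
       glszm = glszm,
       ngtdm = list(n = nt$n, s = nt$s,
                    p = if (ntot > 0) nt$n / ntot else rep(0, ng)),
       n_voxels = np, ng = ng)
}

# ---- feature formulas ------------------------------------------------------

# 26 features of one symmetric GLCM probability matrix.
glcm_features_one <- function(P) {
  ng <- nrow(P)
  R <- row(P); C <- col(P)
  px <- rowSums(P)
  mux <- sum(seq_len(ng) * px)
  varx <- sum((seq_len(ng) - mux)^2 * px)
  sigx <- sqrt(varx)

  pd <- vapply(0:(ng - 1), function(k) sum(P[abs(R - C) == k]), numeric(1))
  da <- sum((0:(ng - 1)) * pd)
  ps <- vapply(2:(2 * ng), function(k) sum(P[R + C == k]), numeric(1))
  sa <- sum((2:(2 * ng)) * ps)

  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  HXY <- ent(P)
  HX <- ent(px)
  pp <- outer(px, px)
  pos <- P > 0
  HXY1 <- -sum(P[pos & pp > 0] * log2(pp[pos & pp > 0]))
  HXY2 <- ent(pp)

  correlation <- if (sigx > 0) (sum(R * C * P) - mux^2) / varx else 0
  imc1 <- if (HX > 0) (HXY - HXY1) / HX else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (HXY2 - HXY))))

  occ <- which(px > 0)
  mcc <- 0
  if (length(occ) > 1L) {
    Po <- P[occ, occ, drop = FALSE]
    pxo <- px[occ]
    # Q(i,j) = sum_k p(i,k) p(j,k) / (px(i) py(k))
    Q <- (Po / pxo) %*% t(Po / rep(pxo, each = length(occ)))
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(min(1, max(0, ev[2])))
  }

  c(autocorrelation = sum(R * C * P),
    cluster_prominence = sum((R + C - 2 * mux)^4 * P),
    cluster_shade = sum((R + C - 2 * mux)^3 * P),
    cluster_tendency = sum((R + C - 2 * mux)^2 * P),
    contrast = sum((R - C)^2 * P),
    correlation = correlation,
    difference_average = da,
    difference_entropy = ent(pd),
    difference_variance = sum(((0:(ng - 1)) - da)^2 * pd),
    dissimilarity = sum(abs(R - C) * P),
    inverse_difference = sum(P / (1 + abs(R - C))),
    inverse_difference_moment = sum(P / (1 + (R - C)^2)),
    inverse_difference_moment_normalized = sum(P / (1 + ((R - C) / ng)^2)),
    inverse_difference_normalized = sum(P / (1 + abs(R - C) / ng)),
    informational_measure_correlation1 = imc1,
    informational_measure_correlation2 = imc2,
    inverse_variance = sum(P[R != C] / (R - C)[R != C]^2),
    joint_average = mux,
    joint_energy = sum(P^2),
    joint_entropy = HXY,
    maximum_probability = max(P),
    maximal_correlation_coefficient = mcc,
    sum_average = sa,
    sum_entropy = ent(ps),
    sum_variance = sum(((2:(2 * ng)) - sa)^2 * ps),
    sum_of_squares = sum((R - mux)^2 * P))
}

# 16 run-length (suffix "run"/"r") or size-zone (suffix "zone"/"z") style
# features of a level x size count matrix; np = ROI voxel count.
rl_sz_features <- function(M, np, what = c("run", "zone")) {
  what <- match.arg(what)
  N <- sum(M)
  lev <- row(M); siz <- col(M)
  p <- M / N
  mul <- sum(lev * p); mus <- sum(siz * p)
  pe <- p[p > 0]
  vals <- c(
    sum(M / siz^2) / N,                    # small emphasis
    sum(M * siz^2) / N,                    # large emphasis
    sum(rowSums(M)^2) / N,                 # gray-level non-uniformity
    sum(rowSums(M)^2) / N^2,               # GLN normalized
    sum(colSums(M)^2) / N,                 # size non-uniformity
    sum(colSums(M)^2) / N^2,               # SN normalized
    N / np,                                # percentage
    sum((lev - mul)^2 * p),                # gray-level variance
    sum((siz - mus)^2 * p),                # size variance
    -sum(pe * log2(pe)),                   # entropy
    sum(M / lev^2) / N,                    # low gray-level emphasis
    sum(M * lev^2) / N,                    # high gray-level emphasis
    sum(M / (lev^2 * siz^2)) / N,
    sum(M * lev^2 / siz^2) / N,
    sum(M * siz^2 / lev^2) / N,
    sum(M * siz^2 * lev^2) / N)
  names(vals) <- if (what == "run") {
    c("short_run_emphasis", "long_run_emphasis",
      "gray_level_nonuniformity", "gray_level_nonuniformity_normalized",
      "run_length_nonuniformity", "run_length_nonuniformity_normalized",
      "run_percentage", "gray_level_variance", "run_variance",
      "run_entropy", "low_gray_level_run_emphasis",
      "high_gray_level_run_emphasis", "short_run_low_gray_level_emphasis",
      "short_run_high_gray_level_emphasis",
      "long_run_low_gray_level_emphasis",
      "long_run_high_gray_level_emphasis")
  } else {
    c("small_area_emphasis", "large_area_emphasis",
      "gray_level_nonuniformity", "gray_level_nonuniformity_normalized",
      "size_zone_nonuniformity", "size_zone_nonuniformity_normalized",
      "zone_percentage", "gray_level_variance", "zone_variance",
      "zone_entropy", "low_gray_level_zone_emphasis",
      "high_gray_level_zone_emphasis", "small_area_low_gray_level_emphasis",
      "small_area_high_gray_level_emphasis",
      "large_area_low_gray_level_emphasis",
      "large_area_high_gray_level_emphasis")
  }
  vals
}

# 5 Amadasun-King neighborhood gray-tone difference features from the
# valid-voxel counts n_i and summed neighborhood differences s_i.
ngtdm_features_one <- function(n, s, coarseness_cap = 1e6) {
  N <- sum(n)
  if (N == 0) return(c(coarseness = coarseness_cap, contrast = 0,
                       busyness = 0, complexity = 0, strength = 0))
  p <- n / N
  occ <- which(p > 0)
  ngp <- length(occ)
  i <- occ
  pi_ <- p[occ]; si <- s[occ]
  dif <- abs(outer(i, i, `-`))
  psum <- outer(pi_, pi_, `+`)
  ps <- sum(pi_ * si)
  den_bus <- sum(abs(outer(i * pi_, i * pi_, `-`)))
  c(coarseness = if (ps > 0) 1 / ps else coarseness_cap,
    contrast = if (ngp > 1) {
      (sum(outer(pi_, pi_) * dif^2) / (ngp * (ngp - 1))) * (sum(si) / N)
    } else 0,
    busyness = if (den_bus > 0) ps / den_bus else 0,
    complexity = sum(dif * (outer(pi_ * si, pi_ * si, `+`)) / psum) / N,
    strength = if (sum(si) > 0) sum(psum * dif^2) / sum(si) else 0)
}

#' Texture features from the built matrices
#'
#' 63 named values: 26 GLCM, 16 GLRLM, 16 GLSZM and 5 NGTDM features.
#' GLCM and GLRLM features are computed per direction and averaged over the
#' 13 directions (directions without a single pair are skipped for GLCM).
#' Zone percentage is the zone count divided by the ROI voxel count; NGTDM
#' features follow the Amadasun-King definitions. For a single-level ROI
#' the correlation-type GLCM features (correlation, the two informational
#' measures, the maximal correlation coefficient) are defined as 0.
#'
#' @param tm output of [build_texture_matrices()].
#' @return named numeric vector of length 63 with `GLCM_`, `GLRLM_`,
#'   `GLSZM_` and `NGTDM_` prefixes.
#' @export
texture_features <- function(tm) {
  nd <- dim(tm$glcm$directional)[3]
  keep <- which(tm$glcm$has_pairs)
  glcm <- if (length(keep) > 0) {
    rowMeans(vapply(keep,
                    function(d) glcm_features_one(tm$glcm$directional[, , d]),
                    numeric(26)))
  } else {
    # single isolated voxel: no pairs in any direction; treat as constant
    P1 <- matrix(0, tm$ng, tm$ng); P1[1, 1] <- 1
    glcm_features_one(P1)
  }
  glrlm <- rowMeans(vapply(seq_len(nd), function(d) {
    rl_sz_features(tm$glrlm[, , d], tm$n_voxels, "run")
  }, numeric(16)))
  glszm <- rl_sz_features(tm$glszm, tm$n_voxels, "zone")
  ngtdm <- ngtdm_features_one(tm$ngtdm$n, tm$ngtdm$s)
  c(stats::setNames(glcm, paste0("GLCM_", names(glcm))),
    stats::setNames(glrlm, paste0("GLRLM_", names(glrlm))),
    stats::setNames(glszm, paste0("GLSZM_", names(glszm))),
    stats::setNames(ngtdm, paste0("NGTDM_", names(ngtdm))))
}
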