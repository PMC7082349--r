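#' Coiflet-1 analysis filter pair
#'
#' Orthonormal 6-tap Coiflet-1 filters. The high-pass filter is the
#' quadrature mirror of the low-pass (`hi[k] = (-1)^k lo[L-1-k]`), so detail
#' coefficients of a constant signal are exactly zero.
#'
#' @return list with numeric vectors `lo` and `hi`.
#' @export
coif1_filters <- function() {
  lo <- c(-0.01565572813546454, -0.07273261951285390, 0.38486484686420286,
          0.85257202021225540, 0.33789766245780922, -0.07273261951285390)
  L <- length(lo)
  hi <- (-1)^(0:(L - 1)) * rev(lo)
  list(lo = lo, hi = hi)
}

# Orthonormal one-level circular DWT matrix for an even signal length n:
# first n/2 rows are shifted (wrapped) low-pass filters, last n/2 rows
# high-pass. W %*% x gives c(approx, detail); t(W) inverts exactly.
dwt_matrix <- function(n, filters = coif1_filters()) {
  if (n %% 2L != 0L) stop("dwt_matrix: n must be even")
  L <- length(filters$lo)
  W <- matrix(0, n, n)
  for (k in 0:(n / 2 - 1)) {
    for (m in 0:(L - 1)) {
      col <- (2 * k + m) %% n + 1
      W[k + 1, col] <- W[k + 1, col] + filters$lo[m + 1]
      W[n / 2 + k + 1, col] <- W[n / 2 + k + 1, col] + filters$hi[m + 1]
    }
  }
  W
}

# Apply matrix M along the given axis of a 3D array.
apply_axis <- function(a, M, axis) {
  d <- dim(a)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  res <- M %*% matrix(ap, nrow = dp[1])
  res <- array(res, c(nrow(M), dp[2], dp[3]))
  aperm(res, order(perm))
}

#' One-level Coiflet-1 3D wavelet decomposition into eight same-grid bands
#'
#' Separable one-level 3D discrete wavelet transform with the Coiflet-1
#' filter pair and circular (periodized) boundary handling; axes of odd
#' length are padded by replicating the final slice. Each of the eight
#' sub-bands (LLL, LLH, LHL, LHH, HLL, HLH, HHL, HHH; letters ordered along
#' axes x, y, z with L = low-pass) is reconstructed back onto the original
#' grid by inverting the transform with all other bands zeroed, so the
#' original ROI mask applies to every band and the eight bands sum exactly
#' to the input (the transform is orthonormal).
#'
#' @param volume 3D numeric array or [image_volume()].
#' @return named list of eight 3D arrays with the input's dimensions, in
#'   the fixed order LLL, LLH, LHL, LHH, HLL, HLH, HHL, HHH.
#' @export
wavelet_decompose <- function(volume) {
  if (inherits(volume, "image_volume")) volume <- volume$data
  d0 <- dim(volume)
  if (is.null(d0) || length(d0) != 3L)
    stop("wavelet_decompose: expected a 3D array")
  x <- volume
  for (ax in 1:3) {
    if (dim(x)[ax] %% 2L == 1L) {
      idx <- lapply(dim(x), seq_len)
      idx[[ax]] <- c(idx[[ax]], dim(x)[ax]) # replicate last slice
      x <- do.call(`[`, c(list(x), idx))
    }
  }
  d <- dim(x)
  Ws <- lapply(d, dwt_matrix)
  coef <- x
  for (ax in 1:3) coef <- apply_axis(coef, Ws[[ax]], ax)

  half <- d %/% 2L
  sel <- function(axis, hp) if (hp) (half[axis] + 1):d[axis] else 1:half[axis]
  band_names <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
  bands <- vector("list", 8L)
  names(bands) <- band_names
  for (b in band_names) {
    hp <- strsplit(b, "")[[1]] == "H" # letters map to axes x, y, z
    z <- array(0, d)
    z[sel(1, hp[1]), sel(2, hp[2]), sel(3, hp[3])] <-
      coef[sel(1, hp[1]), sel(2, hp[2]), sel(3, hp[3])]
    for (ax in 1:3) z <- apply_axis(z, t(Ws[[ax]]), ax)
    bands[[b]] <- z[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3]), drop = FALSE]
  }
  bands
}
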