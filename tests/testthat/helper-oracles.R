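# Independent brute-force oracles for the texture matrices: naive
# voxel-by-voxel enumeration, no shared code with the package internals.

bf_glcm <- function(lev, dir, ng) {
  d <- dim(lev)
  M <- matrix(0L, ng, ng)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    a <- lev[i, j, k]
    if (a == 0) next
    p <- c(i, j, k) + dir
    if (any(p < 1) || any(p > d)) next
    b <- lev[p[1], p[2], p[3]]
    if (b == 0) next
    M[a, b] <- M[a, b] + 1L
    M[b, a] <- M[b, a] + 1L # symmetric accumulation
  }
  M
}

bf_glrlm <- function(lev, dir, ng, max_len) {
  d <- dim(lev)
  M <- matrix(0L, ng, max_len)
  inb <- function(p) all(p >= 1) && all(p <= d)
  at <- function(p) lev[p[1], p[2], p[3]]
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    p <- c(i, j, k)
    l <- at(p)
    if (l == 0) next
    prev <- p - dir
    if (inb(prev) && at(prev) == l) next # not a run start
    len <- 1L
    q <- p + dir
    while (inb(q) && at(q) == l) {
      len <- len + 1L
      q <- q + dir
    }
    M[l, len] <- M[l, len] + 1L
  }
  M
}

bf_glszm <- function(lev, ng) {
  d <- dim(lev)
  seen <- array(FALSE, d)
  zones <- list()
  nbrs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nbrs <- nbrs[rowSums(abs(nbrs)) > 0, ]
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (seen[i, j, k] || lev[i, j, k] == 0) next
    l <- lev[i, j, k]
    queue <- list(c(i, j, k))
    seen[i, j, k] <- TRUE
    size <- 0L
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      size <- size + 1L
      for (r in seq_len(nrow(nbrs))) {
        q <- p + nbrs[r, ]
        if (any(q < 1) || any(q > d)) next
        if (!seen[q[1], q[2], q[3]] && lev[q[1], q[2], q[3]] == l) {
          seen[q[1], q[2], q[3]] <- TRUE
          queue <- c(queue, list(q))
        }
      }
    }
    zones[[length(zones) + 1L]] <- c(l, size)
  }
  do.call(rbind, zones)
}

bf_ngtdm <- function(lev, ng) {
  d <- dim(lev)
  s <- numeric(ng); n <- integer(ng)
  nbrs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nbrs <- nbrs[rowSums(abs(nbrs)) > 0, ]
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    l <- lev[i, j, k]
    if (l == 0) next
    vals <- c()
    for (r in seq_len(nrow(nbrs))) {
      q <- c(i, j, k) + nbrs[r, ]
      if (any(q < 1) || any(q > d)) next
      v <- lev[q[1], q[2], q[3]]
      if (v > 0) vals <- c(vals, v)
    }
    if (length(vals) == 0) next
    n[l] <- n[l] + 1L
    s[l] <- s[l] + abs(l - mean(vals))
  }
  list(n = n, s = s)
}

# dense GLSZM matrix from zone pairs, matching build_texture_matrices()
bf_glszm_dense <- function(lev, ng, zmax) {
  z <- bf_glszm(lev, ng)
  M <- matrix(0L, ng, zmax)
  for (r in seq_len(nrow(z))) M[z[r, 1], z[r, 2]] <- M[z[r, 1], z[r, 2]] + 1L
  M
}

# a digital ball mask
make_ball <- function(r, margin = 3L) {
  n <- 2L * r + 2L * margin + 1L
  cs <- (n + 1) / 2
  g <- as.matrix(expand.grid(seq_len(n), seq_len(n), seq_len(n)))
  array(as.integer(colSums((t(g) - cs)^2) <= r^2), c(n, n, n))
}

# a small deterministic phantom configuration for pipeline-level tests
tiny_config <- function(n = 12L, seed = 11L, ...) {
  synthetic_config(n_patients = n, grid_shape = c(24L, 24L, 16L),
                   voxel_spacing = c(2, 2, 3),
                   tumor_radius_range = c(5, 9), seed = seed, ...)
}

# brute-force AUC by exhaustive pair concordance
bf_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
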