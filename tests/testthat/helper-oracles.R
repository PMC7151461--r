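# Brute-force oracles for the texture matrices, independent of the package's
# vectorized constructions: plain loops over voxels/pairs/zones on a dense
# gray-level array (NA outside the mask).

oracle_offsets26 <- function() {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

# GLCM: double loop over all voxels; count (a,b) for the given offset, then
# symmetrize and normalize.
oracle_glcm <- function(lv, off, ng, distance = 1L) {
  d <- dim(lv)
  off <- off * distance
  m <- matrix(0, ng, ng)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    a <- lv[i, j, k]
    if (is.na(a)) next
    p2 <- c(i, j, k) + off
    if (any(p2 < 1) || any(p2 > d)) next
    b <- lv[p2[1], p2[2], p2[3]]
    if (is.na(b)) next
    m[a, b] <- m[a, b] + 1
  }
  m <- m + t(m)
  if (sum(m) == 0) return(NULL)
  m / sum(m)
}

# GLRLM: walk every line in the direction, splitting runs at level changes and
# mask gaps.
oracle_glrlm <- function(lv, off, ng) {
  d <- dim(lv)
  runs <- list()
  inb <- function(p) all(p >= 1) && all(p <= d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    p <- c(i, j, k)
    if (is.na(lv[p[1], p[2], p[3]])) next
    prev <- p - off
    # run starts: predecessor outside grid/mask or different level
    if (inb(prev) && !is.na(lv[prev[1], prev[2], prev[3]]) &&
        lv[prev[1], prev[2], prev[3]] == lv[p[1], p[2], p[3]]) next
    g <- lv[p[1], p[2], p[3]]
    len <- 1L
    q <- p + off
    while (inb(q) && !is.na(lv[q[1], q[2], q[3]]) && lv[q[1], q[2], q[3]] == g) {
      len <- len + 1L
      q <- q + off
    }
    runs[[length(runs) + 1L]] <- c(g, len)
  }
  rr <- do.call(rbind, runs)
  m <- matrix(0, ng, max(rr[, 2]))
  for (r in seq_len(nrow(rr))) m[rr[r, 1], rr[r, 2]] <- m[rr[r, 1], rr[r, 2]] + 1
  m
}

# GLSZM: breadth-first flood fill over 26-connectivity.
oracle_glszm <- function(lv, ng) {
  d <- dim(lv)
  seen <- array(FALSE, d)
  offs <- oracle_offsets26()
  zones <- list()
  idx <- which(!is.na(lv), arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p0 <- idx[r, ]
    if (seen[p0[1], p0[2], p0[3]]) next
    g <- lv[p0[1], p0[2], p0[3]]
    queue <- list(p0)
    seen[p0[1], p0[2], p0[3]] <- TRUE
    size <- 0L
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      size <- size + 1L
      for (o in seq_len(nrow(offs))) {
        q <- p + offs[o, ]
        if (any(q < 1) || any(q > d)) next
        if (seen[q[1], q[2], q[3]]) next
        v <- lv[q[1], q[2], q[3]]
        if (is.na(v) || v != g) next
        seen[q[1], q[2], q[3]] <- TRUE
        queue[[length(queue) + 1L]] <- q
      }
    }
    zones[[length(zones) + 1L]] <- c(g, size)
  }
  zz <- do.call(rbind, zones)
  m <- matrix(0, ng, max(zz[, 2]))
  for (r in seq_len(nrow(zz))) m[zz[r, 1], zz[r, 2]] <- m[zz[r, 1], zz[r, 2]] + 1
  m
}

# NGTDM: per-voxel neighbor mean loop.
oracle_ngtdm <- function(lv, ng) {
  d <- dim(lv)
  offs <- oracle_offsets26()
  s <- rep(0, ng); cnt_valid <- rep(0, ng)
  nvp <- 0L
  idx <- which(!is.na(lv), arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    vals <- c()
    for (o in seq_len(nrow(offs))) {
      q <- p + offs[o, ]
      if (any(q < 1) || any(q > d)) next
      v <- lv[q[1], q[2], q[3]]
      if (!is.na(v)) vals <- c(vals, v)
    }
    if (!length(vals)) next
    g <- lv[p[1], p[2], p[3]]
    nvp <- nvp + 1L
    cnt_valid[g] <- cnt_valid[g] + 1L
    s[g] <- s[g] + abs(g - mean(vals))
  }
  list(p = if (nvp > 0) cnt_valid / nvp else rep(0, ng), s = s, n_valid = nvp)
}

# GLDM: per-voxel dependent-neighbor count loop.
oracle_gldm <- function(lv, ng, alpha = 0L) {
  d <- dim(lv)
  offs <- oracle_offsets26()
  idx <- which(!is.na(lv), arr.ind = TRUE)
  deps <- integer(nrow(idx)); gl <- integer(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    g <- lv[p[1], p[2], p[3]]
    dep <- 0L
    for (o in seq_len(nrow(offs))) {
      q <- p + offs[o, ]
      if (any(q < 1) || any(q > d)) next
      v <- lv[q[1], q[2], q[3]]
      if (!is.na(v) && abs(v - g) <= alpha) dep <- dep + 1L
    }
    deps[r] <- dep; gl[r] <- g
  }
  m <- matrix(0, ng, max(deps) + 1L)
  for (r in seq_along(deps)) m[gl[r], deps[r] + 1L] <- m[gl[r], deps[r] + 1L] + 1
  m
}

# Literal-formula evaluations of the anchored features on oracle matrices.
oracle_glcm_anchors <- function(p, eps = 2.22e-16) {
  ng <- nrow(p)
  i <- matrix(1:ng, ng, ng); j <- t(i)
  mux <- sum(i * p); muy <- sum(j * p)
  pd <- rep(0, ng)
  for (k in 0:(ng - 1)) pd[k + 1] <- sum(p[abs(i - j) == k])
  ks <- 0:(ng - 1)
  c(Autocorrelation = sum(p * i * j),
    ClusterProminence = sum((i + j - mux - muy)^4 * p),
    DifferenceEntropy = -sum(pd[pd > 0] * log2(pd[pd > 0] + eps)),
    Idm = sum(pd / (1 + ks^2)))
}

oracle_glrlm_anchors <- function(P, eps = 2.22e-16) {
  nr <- sum(P)
  p <- P / nr
  ng <- nrow(P); lm <- ncol(P)
  i <- matrix(1:ng, ng, lm); j <- matrix(1:lm, ng, lm, byrow = TRUE)
  mu <- sum(p * i)
  pp <- p[p > 0]
  c(GrayLevelNonUniformity = sum(rowSums(P)^2) / nr,
    GrayLevelVariance = sum(p * (i - mu)^2),
    RunEntropy = -sum(pp * log2(pp + eps)),
    LongRunHighGrayLevelEmphasis = sum(P * i^2 * j^2) / nr)
}

oracle_glszm_sahgle <- function(P) {
  ng <- nrow(P); sm <- ncol(P)
  i <- matrix(1:ng, ng, sm); j <- matrix(1:sm, ng, sm, byrow = TRUE)
  sum(P * i^2 / j^2) / sum(P)
}

oracle_ngtdm_coarseness <- function(m, cap = 1e6) {
  ps <- sum(m$p * m$s)
  if (ps > 0) min(1 / ps, cap) else cap
}

oracle_gldm_anchors <- function(P) {
  nz <- sum(P)
  ng <- nrow(P); dm <- ncol(P)
  j <- matrix(1:dm, ng, dm, byrow = TRUE)
  c(SmallDependenceEmphasis = sum(P / j^2) / nz,
    DependenceNonUniformity = sum(colSums(P)^2) / nz)
}
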