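#' @title Gray-level texture matrices
#' @description Construction of the five texture-matrix kinds from a
#'   discretized ROI: co-occurrence (GLCM, 13 unique lattice directions of the
#'   26-neighborhood), run-length (GLRLM, per direction), size-zone (GLSZM,
#'   26-connected zones, direction-free), neighbouring gray tone difference
#'   (NGTDM) and dependence (GLDM). Matrices are indexed by gray level 1..Ng
#'   (the configured bin count); rows for absent levels are zero.
#' @name texture-matrices
NULL

#' The 13 canonical 3D lattice directions
#'
#' One representative of each +/- pair of the 26-neighborhood offsets (first
#' nonzero component positive).
#'
#' @return 13 x 3 integer matrix.
#' @export
directions13 <- function() {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(abs(g)) > 0, ]
  keep <- apply(g, 1, function(o) { nz <- o[o != 0]; nz[1] > 0 })
  out <- g[keep, , drop = FALSE]
  dimnames(out) <- NULL
  out
}

# Aligned voxel pairs of a dense level array under an integer offset: returns
# list(a, b) of equal-length level vectors (NA where outside mask), or NULL if
# the offset exceeds the array.
.offset_pairs <- function(lv, off) {
  d <- dim(lv)
  if (any(abs(off) >= d)) return(NULL)
  r_to <- lapply(1:3, function(ax) max(1L, 1L + off[ax]):min(d[ax], d[ax] + off[ax]))
  r_from <- lapply(1:3, function(ax) r_to[[ax]] - off[ax])
  list(a = lv[r_from[[1]], r_from[[2]], r_from[[3]]],
       b = lv[r_to[[1]], r_to[[2]], r_to[[3]]])
}

#' Gray-level co-occurrence matrix for one direction
#'
#' Counts voxel pairs (both inside the ROI mask) separated by
#' `offset * distance`, symmetrized (each pair counted in both orders) and
#' normalized to sum 1.
#'
#' @param d a `discretized_roi`.
#' @param offset integer length-3 direction (one of [directions13()]).
#' @param distance positive integer offset multiplier.
#' @return Ng x Ng symmetric matrix summing to 1, or NULL when the direction
#'   yields no valid pair.
#' @export
glcm_matrix <- function(d, offset, distance = 1L) {
  lv <- .disc_dense(d)
  ng <- d$n_levels
  pr <- .offset_pairs(lv, as.integer(offset) * as.integer(distance))
  if (is.null(pr)) return(NULL)
  ok <- !is.na(pr$a) & !is.na(pr$b)
  if (!any(ok)) return(NULL)
  a <- pr$a[ok]; b <- pr$b[ok]
  cnt <- tabulate((a - 1L) * ng + b, nbins = ng * ng)
  m <- matrix(cnt, ng, ng, byrow = TRUE)
  m <- m + t(m)
  m / sum(m)
}

#' Gray-level run-length matrix for one direction
#'
#' Runs are maximal colinear sequences of equal gray level inside the mask;
#' voxels missing from the mask break runs.
#'
#' @param d a `discretized_roi`.
#' @param offset integer length-3 direction.
#' @return Ng x Lmax count matrix (row = level, column = run length); entry
#'   sums equal the number of runs Nr.
#' @export
glrlm_matrix <- function(d, offset) {
  roi <- d$roi
  co <- roi$coords
  g <- d$gray_levels
  ng <- d$n_levels
  off <- as.integer(offset)
  step <- sum(off * off)
  tt <- co %*% off
  # line invariant: p*|d|^2 - d*(p . d) is constant along the line through p
  key3 <- co * step - matrix(off, nrow(co), 3, byrow = TRUE) * as.vector(tt)
  span <- max(abs(key3)) + 1
  key <- (key3[, 1] * (2 * span + 1) + key3[, 2]) * (2 * span + 1) + key3[, 3]
  o <- order(key, tt)
  k <- key[o]; t2 <- tt[o]; gl <- g[o]
  brk <- c(TRUE, diff(k) != 0 | diff(t2) != step | diff(gl) != 0)
  rid <- cumsum(brk)
  len <- tabulate(rid)
  lev <- gl[brk]
  lmax <- max(len)
  m <- matrix(0, ng, lmax)
  cnt <- tabulate((lev - 1L) * lmax + len, nbins = ng * lmax)
  matrix(cnt, ng, lmax, byrow = TRUE)
}

#' Gray-level size-zone matrix
#'
#' Zones are 26-connected components of equal gray level within the mask.
#' Connected components are found by iterative minimum-label propagation over
#' the 26 neighbor offsets.
#'
#' @param d a `discretized_roi`.
#' @return Ng x Smax count matrix (row = level, column = zone size); entries
#'   sum to the number of zones Ns.
#' @export
glszm_matrix <- function(d) {
  lv <- .disc_dense(d)
  ng <- d$n_levels
  dd <- dim(lv)
  lab <- array(NA_real_, dd)
  msk <- !is.na(lv)
  lab[msk] <- seq_len(sum(msk))   # assign by position order; any unique init works
  offs <- rbind(directions13(), -directions13())
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(offs))) {
      off <- offs[r, ]
      if (any(abs(off) >= dd)) next
      r_to <- lapply(1:3, function(ax) max(1L, 1L + off[ax]):min(dd[ax], dd[ax] + off[ax]))
      r_from <- lapply(1:3, function(ax) r_to[[ax]] - off[ax])
      la <- lab[r_to[[1]], r_to[[2]], r_to[[3]]]
      lb <- lab[r_from[[1]], r_from[[2]], r_from[[3]]]
      va <- lv[r_to[[1]], r_to[[2]], r_to[[3]]]
      vb <- lv[r_from[[1]], r_from[[2]], r_from[[3]]]
      upd <- which(!is.na(va) & !is.na(vb) & va == vb & lb < la)
      if (length(upd)) {
        la[upd] <- lb[upd]
        lab[r_to[[1]], r_to[[2]], r_to[[3]]] <- la
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  zid <- lab[msk]
  zlev <- lv[msk]
  uz <- unique(zid)
  size <- as.vector(table(factor(zid, levels = uz)))
  lev <- zlev[match(uz, zid)]
  smax <- max(size)
  cnt <- tabulate((lev - 1L) * smax + size, nbins = ng * smax)
  matrix(cnt, ng, smax, byrow = TRUE)
}

#' Neighbouring gray tone difference matrix
#'
#' For every mask voxel with at least one 26-neighbor in the mask, the
#' absolute difference between its level and the mean level of those
#' neighbors. `s[i]` sums these differences over voxels of level i; `p[i]` is
#' the fraction of valid voxels with level i.
#'
#' @param d a `discretized_roi`.
#' @return list with `p`, `s` (length Ng) and `n_valid` (number of voxels with
#'   a nonempty neighborhood).
#' @export
ngtdm_matrix <- function(d) {
  lv <- .disc_dense(d)
  ng <- d$n_levels
  dd <- dim(lv)
  acc <- array(0, dd)
  cnt <- array(0, dd)
  offs <- rbind(directions13(), -directions13())
  for (r in seq_len(nrow(offs))) {
    off <- offs[r, ]
    if (any(abs(off) >= dd)) next
    pr <- .offset_pairs(lv, off)
    r_to <- lapply(1:3, function(ax) max(1L, 1L + off[ax]):min(dd[ax], dd[ax] + off[ax]))
    ok <- !is.na(pr$a) & !is.na(pr$b)
    add <- ifelse(ok, pr$a, 0)
    sub_acc <- acc[r_to[[1]], r_to[[2]], r_to[[3]]] + add
    sub_cnt <- cnt[r_to[[1]], r_to[[2]], r_to[[3]]] + ok
    acc[r_to[[1]], r_to[[2]], r_to[[3]]] <- sub_acc
    cnt[r_to[[1]], r_to[[2]], r_to[[3]]] <- sub_cnt
  }
  valid <- !is.na(lv) & cnt > 0
  nvp <- sum(valid)
  p <- rep(0, ng); s <- rep(0, ng)
  if (nvp > 0) {
    gl <- lv[valid]
    dif <- abs(gl - acc[valid] / cnt[valid])
    p <- tabulate(gl, nbins = ng) / nvp
    sm <- rowsum(dif, gl)               # present levels only, sorted
    s[as.integer(rownames(sm))] <- sm
  }
  list(p = p, s = s, n_valid = nvp)
}

#' Gray-level dependence matrix
#'
#' The dependence of a voxel is the number of its 26-neighbors inside the mask
#' whose level differs by at most `alpha`. Entry (i, j) counts voxels of level
#' i with dependence j - 1; entries sum to Np.
#'
#' @param d a `discretized_roi`.
#' @param alpha integer level tolerance (default from the engine config is 0).
#' @return Ng x (Dmax + 1) count matrix.
#' @export
gldm_matrix <- function(d, alpha = 0L) {
  lv <- .disc_dense(d)
  ng <- d$n_levels
  dd <- dim(lv)
  dep <- array(0L, dd)
  offs <- rbind(directions13(), -directions13())
  for (r in seq_len(nrow(offs))) {
    off <- offs[r, ]
    if (any(abs(off) >= dd)) next
    pr <- .offset_pairs(lv, off)
    r_to <- lapply(1:3, function(ax) max(1L, 1L + off[ax]):min(dd[ax], dd[ax] + off[ax]))
    ok <- !is.na(pr$a) & !is.na(pr$b) & abs(pr$b - pr$a) <= alpha
    dep[r_to[[1]], r_to[[2]], r_to[[3]]] <-
      dep[r_to[[1]], r_to[[2]], r_to[[3]]] + as.integer(ok)
  }
  msk <- !is.na(lv)
  gl <- lv[msk]
  dp <- dep[msk] + 1L
  dmax <- max(dp)
  cnt <- tabulate((gl - 1L) * dmax + dp, nbins = ng * dmax)
  matrix(cnt, ng, dmax, byrow = TRUE)
}
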