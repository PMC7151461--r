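#' 3D shape features
#'
#' Ten morphological descriptors of the ROI mask: MeshVolume and SurfaceArea
#' from the triangulated iso-surface (signed-tetrahedron volume, summed
#' triangle areas), VoxelVolume = Np * voxel volume, SurfaceVolumeRatio,
#' Sphericity = (36 pi V^2)^(1/3) / A, Maximum3DDiameter (largest pairwise
#' distance between surface-voxel centers), Major/Minor/LeastAxisLength
#' (4 sqrt(lambda) from the physical-coordinate covariance eigenvalues) and
#' Elongation = sqrt(lambda2 / lambda1).
#'
#' A single-voxel ROI takes the degenerate path: volume = voxel volume, area =
#' the voxel box's face area, axis lengths 0, Elongation 1.
#'
#' @param roi a `roi_voxels`.
#' @return named numeric vector of 10 finite values.
#' @export
shape3d_features <- function(roi) {
  sp <- roi$spacing
  np <- nrow(roi$coords)
  vvox <- prod(sp)
  if (np == 1L) {
    a <- 2 * (sp[1] * sp[2] + sp[1] * sp[3] + sp[2] * sp[3])
    return(c(MeshVolume = vvox, VoxelVolume = vvox, SurfaceArea = a,
             SurfaceVolumeRatio = a / vvox,
             Sphericity = (36 * pi * vvox^2)^(1 / 3) / a,
             Maximum3DDiameter = 0, MajorAxisLength = 0, MinorAxisLength = 0,
             LeastAxisLength = 0, Elongation = 1))
  }
  lo <- roi$bbox["lo", ]; hi <- roi$bbox["hi", ]
  mask <- array(FALSE, hi - lo + 1L)
  cc <- roi$coords + 1L - rep(lo - 1L, each = np)
  mask[cc] <- TRUE
  mm <- mesh_measures(mesh_mask(mask, spacing = sp))
  phys <- sweep(roi$coords, 2, sp, "*")
  cov <- stats::cov(phys) * (np - 1) / np
  ev <- sort(eigen(cov, symmetric = TRUE, only.values = TRUE)$values, decreasing = TRUE)
  ev <- pmax(ev, 0)
  # surface voxels: fewer than 6 face-neighbors inside the mask
  nb <- array(0L, dim(mask))
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    sh <- .shift_get(mask, .axis_offset(ax, s))
    nb[sh$to] <- nb[sh$to] + as.integer(mask[sh$from])
  }
  surf <- which(mask & nb < 6L, arr.ind = TRUE)
  sphys <- sweep(surf, 2, sp, "*")
  maxd <- sqrt(max(.pairwise_sq(sphys)))
  vol <- mm["volume"]; area <- mm["area"]
  c(MeshVolume = unname(vol),
    VoxelVolume = np * vvox,
    SurfaceArea = unname(area),
    SurfaceVolumeRatio = unname(area / vol),
    Sphericity = unname((36 * pi * vol^2)^(1 / 3) / area),
    Maximum3DDiameter = maxd,
    MajorAxisLength = 4 * sqrt(ev[1]),
    MinorAxisLength = 4 * sqrt(ev[2]),
    LeastAxisLength = 4 * sqrt(ev[3]),
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1)
}

# offset vector for axis/sign
.axis_offset <- function(axis, s) { o <- c(0L, 0L, 0L); o[axis] <- s; o }

# For an offset, returns index lists: from = source subarray, to = target, so
# that a[to] aligns with a[from] shifted by offset. Used for neighbor counts.
.shift_get <- function(a, off) {
  d <- dim(a)
  rngs_to <- lapply(1:3, function(ax) max(1L, 1L + off[ax]):min(d[ax], d[ax] + off[ax]))
  rngs_from <- lapply(1:3, function(ax) rngs_to[[ax]] - off[ax])
  ix <- function(r) {
    g <- expand.grid(i = r[[1]], j = r[[2]], k = r[[3]])
    cbind(g$i, g$j, g$k)
  }
  list(to = ix(rngs_to), from = ix(rngs_from))
}

.pairwise_sq <- function(x) {
  g <- rowSums(x^2)
  d2 <- outer(g, g, "+") - 2 * tcrossprod(x)
  pmax(d2, 0)
}

#' 2D shape features
#'
#' Ten in-plane descriptors computed on the axial (third-axis) slice of
#' maximal ROI cross-sectional area (smallest slice index on ties):
#' MeshSurface (contoured area), PixelSurface, Perimeter,
#' PerimeterSurfaceRatio, Sphericity = 2 sqrt(pi A)/P, SphericalDisproportion
#' (its reciprocal), MaximumDiameter, Major/MinorAxisLength (4 sqrt(lambda) of
#' the in-plane covariance) and Elongation.
#'
#' @param roi a `roi_voxels`.
#' @return named numeric vector of 10 finite values.
#' @export
shape2d_features <- function(roi) {
  sp2 <- roi$spacing[1:2]
  kz <- roi$coords[, 3]
  counts <- table(kz)
  kbest <- as.integer(names(counts)[which.max(counts)])
  inpl <- roi$coords[kz == kbest, 1:2, drop = FALSE]
  npix <- nrow(inpl)
  pixA <- npix * prod(sp2)
  if (npix == 1L) {
    a <- prod(sp2); p <- 2 * sum(sp2)
    return(c(MeshSurface = a, PixelSurface = a, Perimeter = p,
             PerimeterSurfaceRatio = p / a, Sphericity = 2 * sqrt(pi * a) / p,
             SphericalDisproportion = p / (2 * sqrt(pi * a)),
             MaximumDiameter = 0, MajorAxisLength = 0, MinorAxisLength = 0,
             Elongation = 1))
  }
  lo <- apply(inpl, 2, min); hi <- apply(inpl, 2, max)
  m <- matrix(FALSE, hi[1] - lo[1] + 1L, hi[2] - lo[2] + 1L)
  m[cbind(inpl[, 1] - lo[1] + 1L, inpl[, 2] - lo[2] + 1L)] <- TRUE
  cm <- .contour_measures(.march_squares(m), spacing2 = sp2)
  phys <- sweep(inpl, 2, sp2, "*")
  cov <- stats::cov(phys) * (npix - 1) / npix
  ev <- sort(pmax(eigen(cov, symmetric = TRUE, only.values = TRUE)$values, 0),
             decreasing = TRUE)
  maxd <- sqrt(max(.pairwise_sq(phys)))
  a <- unname(cm["area"]); p <- unname(cm["perimeter"])
  c(MeshSurface = a,
    PixelSurface = pixA,
    Perimeter = p,
    PerimeterSurfaceRatio = p / a,
    Sphericity = 2 * sqrt(pi * a) / p,
    SphericalDisproportion = p / (2 * sqrt(pi * a)),
    MaximumDiameter = maxd,
    MajorAxisLength = 4 * sqrt(ev[1]),
    MinorAxisLength = 4 * sqrt(ev[2]),
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1)
}
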