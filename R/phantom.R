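#' @title Synthetic labeled-volume phantoms
#' @description Seeded generator of 3D "subcortical-like" phantoms: 16 disjoint
#'   ellipsoidal structures (8 mirrored left/right pairs) embedded in a noisy
#'   background, with per-class region intensity shifts and textured (smoothed
#'   Gaussian random field) noise. The default cohort mirrors the 203/66/637
#'   control/prodromal/PD imbalance at a scale of 20/7/64 scans.
#' @name phantom
NULL

.classes <- c("control", "prodromal", "pd")

#' Default ellipsoid geometry for the 16 structures
#'
#' Eight mirrored pairs with distinct semi-axes, laid out on a y-z grid and
#' reflected through the mid-sagittal (x) plane. Centers/semi-axes are in voxel
#' units of the default 64^3 grid. Odd labels are "left", even "right",
#' matching the bilateral label convention of subcortical atlases.
#'
#' @param grid_shape integer length-3 grid the geometry must fit into.
#' @return data.frame with columns label, cx, cy, cz, ax, ay, az.
#' @export
default_structure_geometry <- function(grid_shape = c(64, 64, 64)) {
  sc <- grid_shape / 64
  yz <- rbind(c(13, 13), c(13, 32), c(13, 51), c(32, 13),
              c(32, 51), c(51, 13), c(51, 32), c(51, 51))
  semi <- rbind(c(6, 5, 4), c(5, 6, 5), c(4, 4, 3), c(7, 5, 4),
                c(5, 4, 4), c(4, 5, 5), c(6, 4, 3), c(5, 5, 6))
  semi <- pmax(semi, 2 / min(sc))   # keep semi-axes >= 2 voxels on small grids
  g <- do.call(rbind, lapply(1:8, function(p) {
    rbind(
      data.frame(label = 2L * p - 1L, cx = 16 * sc[1], cy = yz[p, 1] * sc[2],
                 cz = yz[p, 2] * sc[3], ax = semi[p, 1] * sc[1],
                 ay = semi[p, 2] * sc[2], az = semi[p, 3] * sc[3]),
      data.frame(label = 2L * p, cx = (grid_shape[1] + 1) - 16 * sc[1],
                 cy = yz[p, 1] * sc[2], cz = yz[p, 2] * sc[3],
                 ax = semi[p, 1] * sc[1], ay = semi[p, 2] * sc[2],
                 az = semi[p, 3] * sc[3])
    )
  }))
  g[order(g$label), , drop = FALSE]
}

#' Phantom specification
#'
#' @param grid_shape integer length-3, voxels per axis (default 64^3).
#' @param spacing mm per axis (default 1 mm isotropic).
#' @param geometry data.frame as from [default_structure_geometry()]; exactly
#'   16 rows (labels 1..16), pairwise-disjoint ellipsoids inside the grid.
#' @param background_mean,background_sd background intensity mean / white-noise
#'   sd (intensity units).
#' @param per_class_params named list (control/prodromal/pd), each a list with
#'   `mu_shift` (region mean shift over background), `texture_sd` (sd of the
#'   textured noise inside regions) and `texture_smooth` (Gaussian smoothing
#'   scale in voxels; larger = coarser texture).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64),
                         spacing = c(1, 1, 1),
                         geometry = default_structure_geometry(grid_shape),
                         background_mean = 100,
                         background_sd = 2,
                         per_class_params = list(
                           control   = list(mu_shift = 10, texture_sd = 4, texture_smooth = 0.5),
                           prodromal = list(mu_shift = 20, texture_sd = 6, texture_smooth = 1.0),
                           pd        = list(mu_shift = 30, texture_sd = 8, texture_smooth = 1.5)
                         )) {
  grid_shape <- as.integer(grid_shape)
  spec <- structure(list(grid_shape = grid_shape, spacing = as.numeric(spacing),
                         geometry = geometry, background_mean = background_mean,
                         background_sd = background_sd,
                         per_class_params = per_class_params),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

#' Validate a phantom specification
#'
#' Checks semi-axes >= 2 voxels, containment of every ellipsoid in the grid,
#' pairwise disjointness of the digitized ellipsoids, and positive texture sds.
#'
#' @param spec a `phantom_spec`.
#' @return `spec` invisibly; stops with a geometry/parameter error otherwise.
#' @export
validate_phantom_spec <- function(spec) {
  g <- spec$geometry
  if (nrow(g) != 16L || !identical(sort(as.integer(g$label)), 1:16))
    stop("geometry error: need exactly 16 structures labeled 1..16")
  if (any(g[, c("ax", "ay", "az")] < 2))
    stop("geometry error: semi-axes must be >= 2 voxels")
  for (a in 1:3) {
    lo <- g[[c("cx", "cy", "cz")[a]]] - g[[c("ax", "ay", "az")[a]]]
    hi <- g[[c("cx", "cy", "cz")[a]]] + g[[c("ax", "ay", "az")[a]]]
    if (any(lo < 1) || any(hi > spec$grid_shape[a]))
      stop("geometry error: ellipsoid outside grid on axis ", a)
  }
  lab <- .rasterize_labels(spec)   # stops on overlap
  for (p in spec$per_class_params) {
    if (p$texture_sd <= 0) stop("texture_sd must be > 0")
    if (p$texture_smooth < 0) stop("texture_smooth must be >= 0")
  }
  invisible(spec)
}

# Digitize the 16 ellipsoids into an integer label array; voxel (i,j,k) gets
# label L iff its center satisfies the ellipsoid inequality. Errors on overlap.
.rasterize_labels <- function(spec) {
  d <- spec$grid_shape
  lab <- array(0L, d)
  g <- spec$geometry
  for (r in seq_len(nrow(g))) {
    xi <- max(1L, floor(g$cx[r] - g$ax[r])):min(d[1], ceiling(g$cx[r] + g$ax[r]))
    yi <- max(1L, floor(g$cy[r] - g$ay[r])):min(d[2], ceiling(g$cy[r] + g$ay[r]))
    zi <- max(1L, floor(g$cz[r] - g$az[r])):min(d[3], ceiling(g$cz[r] + g$az[r]))
    ell <- outer(outer(((xi - g$cx[r]) / g$ax[r])^2, ((yi - g$cy[r]) / g$ay[r])^2, "+"),
                 ((zi - g$cz[r]) / g$az[r])^2, "+") <= 1
    sub <- lab[xi, yi, zi]
    if (any(sub[ell] != 0L))
      stop("geometry error: ellipsoids overlap (label ", g$label[r], ")")
    sub[ell] <- as.integer(g$label[r])
    lab[xi, yi, zi] <- sub
  }
  lab
}

# Separable Gaussian smoothing of a 3D array (reflects at borders); sigma in
# voxels. Returns list(field, wss) where wss is the sum of squared 3D kernel
# weights, so white noise smoothed this way has sd sqrt(wss).
.gauss_smooth3 <- function(x, sigma) {
  if (sigma <= 0) return(list(field = x, wss = 1))
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  conv1 <- function(a, along) {
    d <- dim(a)
    m <- aperm(a, c(along, setdiff(1:3, along)))
    dm <- dim(m)
    n <- dm[1]
    m2 <- matrix(m, nrow = n)
    if (n == 1L) return(a)
    idx <- outer(seq_len(n), -r:r, "+")
    idx <- abs(idx - 1L)                  # reflect low edge
    idx <- n - 1L - abs(n - 1L - idx)     # reflect high edge (0-based)
    idx <- pmin(pmax(idx, 0L), n - 1L) + 1L
    out <- matrix(0, n, ncol(m2))
    for (t in seq_along(k)) out <- out + k[t] * m2[idx[, t], , drop = FALSE]
    aperm(array(out, dm), order(c(along, setdiff(1:3, along))))
  }
  y <- conv1(conv1(conv1(x, 1), 2), 3)
  list(field = y, wss = sum(k^2)^3)
}

#' Generate one labeled phantom
#'
#' Background voxels are `background_mean` plus white noise; voxels of every
#' labeled structure are `background_mean + mu_shift` plus a stationary
#' textured noise field (white noise Gaussian-smoothed at scale
#' `texture_smooth`, rescaled analytically to sd `texture_sd`). Deterministic
#' given `(spec, class_label, seed)`.
#'
#' @param spec a `phantom_spec`.
#' @param class_label one of `"control"`, `"prodromal"`, `"pd"`.
#' @param seed integer seed.
#' @return list with `volume` (`image_volume`) and `labels` (`image_volume`
#'   with integer values 0..16).
#' @export
generate_phantom <- function(spec, class_label, seed) {
  class_label <- match.arg(class_label, .classes)
  validate_phantom_spec(spec)
  p <- spec$per_class_params[[class_label]]
  lab <- .rasterize_labels(spec)
  d <- spec$grid_shape
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed %% .Machine$integer.max))
  vol <- array(spec$background_mean, d)
  if (spec$background_sd > 0)
    vol <- vol + array(stats::rnorm(prod(d), 0, spec$background_sd), d)
  tex <- array(stats::rnorm(prod(d)), d)
  sm <- .gauss_smooth3(tex, p$texture_smooth)
  tex <- sm$field / sqrt(sm$wss) * p$texture_sd
  inside <- lab > 0L
  vol[inside] <- spec$background_mean + p$mu_shift + tex[inside]
  list(volume = image_volume(vol, spec$spacing),
       labels = image_volume(lab, spec$spacing))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Cohort specification
#'
#' @param n_per_class named or positional integer length-3
#'   (control, prodromal, pd); default 20/7/64, the reference cohort's 203/66/637
#'   imbalance scaled by ~1/10.
#' @param seed master seed; per-scan seeds are derived deterministically.
#' @param phantom a `phantom_spec`.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_class = c(control = 20, prodromal = 7, pd = 64),
                        seed = 1L, phantom = phantom_spec()) {
  n <- as.integer(n_per_class)
  if (length(n) != 3L || any(n < 0)) stop("n_per_class must be 3 nonnegative integers")
  if (sum(n >= 2) < 2L) stop("at least 2 classes need n >= 2 for cross-validation")
  structure(list(n_per_class = stats::setNames(n, .classes), seed = as.integer(seed),
                 phantom = phantom), class = "cohort_spec")
}

#' Generate a cohort of phantoms on disk
#'
#' Writes one NIfTI volume + label-map pair per scan plus a CSV manifest with
#' columns `scan_id, volume_path, labelmap_path, class`. Per-scan seeds are
#' `seed * 10000 + scan index` (kept below 2^31).
#'
#' @param cohort a `cohort_spec`.
#' @param out_dir output directory (created if needed).
#' @return data.frame, the manifest (also written to `manifest.csv`).
#' @export
generate_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "cohort_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("I/O error: cannot create output directory ", out_dir)
  classes <- rep(.classes, cohort$n_per_class)
  rows <- vector("list", length(classes))
  for (i in seq_along(classes)) {
    scan_seed <- (cohort$seed %% 200000L) * 10000L + i
    ph <- generate_phantom(cohort$phantom, classes[i], scan_seed)
    sid <- sprintf("scan_%03d", i)
    vp <- file.path(out_dir, paste0(sid, ".nii.gz"))
    lp <- file.path(out_dir, paste0(sid, "_labels.nii.gz"))
    write_nifti(ph$volume, vp)
    write_nifti(ph$labels, lp, datatype = "int16")
    rows[[i]] <- data.frame(scan_id = sid, volume_path = vp, labelmap_path = lp,
                            class = classes[i], stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}
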