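#' Engine configuration
#'
#' Numerical knobs of the feature engine. `n_bins` is the fixed number of gray
#' levels used to discretize each ROI over its own intensity range;
#' `glcm_distance` the co-occurrence offset length in voxels; `epsilon` the
#' guard added inside every log2; `energy_offset` the optional shift c in
#' (Total) Energy; `gldm_alpha` the dependence tolerance.
#'
#' @param n_bins integer >= 2 (default 32).
#' @param glcm_distance integer >= 1 (default 1).
#' @param epsilon positive guard for logs (default 2.22e-16).
#' @param energy_offset numeric c added to intensities in Energy/TotalEnergy
#'   (default 0).
#' @param gldm_alpha integer level tolerance for GLDM dependence (default 0).
#' @return object of class `engine_config`.
#' @export
engine_config <- function(n_bins = 32L, glcm_distance = 1L, epsilon = 2.22e-16,
                          energy_offset = 0, gldm_alpha = 0L) {
  if (n_bins < 2) stop("config error: n_bins must be >= 2")
  if (glcm_distance < 1) stop("config error: glcm_distance must be >= 1")
  if (epsilon <= 0) stop("config error: epsilon must be > 0")
  structure(list(n_bins = as.integer(n_bins), glcm_distance = as.integer(glcm_distance),
                 epsilon = epsilon, energy_offset = energy_offset,
                 gldm_alpha = as.integer(gldm_alpha)),
            class = "engine_config")
}

#' Discretize an ROI into Ng gray levels
#'
#' Equal-width bins over the ROI's own [min, max]. A constant ROI maps wholly
#' to level 1 (one effective level). The maximum intensity is included in the
#' top bin.
#'
#' @param roi a `roi_voxels`.
#' @param config an `engine_config`.
#' @return object of class `discretized_roi`: list with `gray_levels` (integer
#'   in 1..Ng per voxel, ROI voxel order), `n_levels` (Ng requested),
#'   `n_levels_effective`, `histogram_p` (length Ng, sums to 1), and the source
#'   `roi`.
#' @export
discretize <- function(roi, config = engine_config()) {
  x <- roi$intensities
  ng <- config$n_bins
  rng <- range(x)
  if (rng[1] == rng[2]) {
    lv <- rep(1L, length(x))
    eff <- 1L
  } else {
    w <- (rng[2] - rng[1]) / ng
    lv <- pmin(ng, as.integer(floor((x - rng[1]) / w)) + 1L)
    eff <- length(unique(lv))
  }
  p <- tabulate(lv, nbins = ng) / length(lv)
  structure(list(gray_levels = lv, n_levels = ng, n_levels_effective = eff,
                 histogram_p = p, roi = roi),
            class = "discretized_roi")
}

# Dense bbox array of gray levels (NA outside mask) for a discretized ROI.
.disc_dense <- function(d) {
  roi <- d$roi
  lo <- roi$bbox["lo", ]; hi <- roi$bbox["hi", ]
  a <- array(NA_real_, hi - lo + 1L)
  a[roi$coords + 1L - rep(lo - 1L, each = nrow(roi$coords))] <- d$gray_levels
  a
}
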