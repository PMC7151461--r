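# Shared fixture builders. All randomness is seeded by the caller.

# An ROI whose discretized gray levels are exactly known: intensities are
# integers 1..ng, and equal-width binning with n_bins = ng maps intensity k to
# level k. mask_frac < 1 knocks random voxels out of the mask.
random_test_roi <- function(shape, ng, seed, mask_frac = 1) {
  set.seed(seed)
  n <- prod(shape)
  vals <- array(sample.int(ng, n, replace = TRUE), shape)
  lab <- array(1L, shape)
  if (mask_frac < 1) {
    drop <- sample.int(n, round((1 - mask_frac) * n))
    drop <- setdiff(drop, which.max(vals))  # keep the max so binning spans 1..ng
    lab[drop] <- 0L
  }
  # guarantee level span 1..ng so bin width stays (ng-1)/ng
  vals[which(lab == 1L)[1]] <- 1L
  vals[which(lab == 1L)[sum(lab)]] <- ng
  vol <- image_volume(vals + 0)
  lm <- image_volume(lab + 0L)
  roi <- extract_roi_voxels(vol, lm, 1L)
  d <- discretize(roi, engine_config(n_bins = ng))
  stopifnot(identical(as.integer(d$gray_levels), as.integer(roi$intensities)))
  list(roi = roi, disc = d, dense = voxrad:::.disc_dense(d))
}

# An ROI built from an explicit gray-level array (NA = outside mask).
roi_from_levels <- function(lv) {
  ng <- max(lv, na.rm = TRUE)
  vals <- lv
  vals[is.na(vals)] <- 0
  lab <- array(as.integer(!is.na(lv)), dim(lv))
  roi <- extract_roi_voxels(image_volume(vals), image_volume(lab), 1L)
  d <- discretize(roi, engine_config(n_bins = max(2L, ng)))
  list(roi = roi, disc = d)
}

# A small three-class feature table with `n_informative` planted class-mean
# shifts among `p` features.
planted_feature_table <- function(n = 150, p = 20, n_informative = 3,
                                  shift = 2, seed = 1) {
  set.seed(seed)
  cls <- sample(rep(c("control", "prodromal", "pd"), length.out = n))
  x <- matrix(rnorm(n * p), n, p)
  mu <- list(control = 0, prodromal = shift, pd = -shift)
  for (f in seq_len(n_informative)) {
    x[, f] <- x[, f] + unlist(mu[cls]) * (1 + 0.2 * f)
  }
  colnames(x) <- sprintf("feat%02d", seq_len(p))
  cbind(data.frame(scan_id = sprintf("s%03d", seq_len(n)), class = cls,
                   stringsAsFactors = FALSE),
        as.data.frame(x))
}

# Small phantom spec for fast cohort-level tests: 32^3 grid, scaled geometry.
small_phantom_spec <- function(...) {
  phantom_spec(grid_shape = c(32, 32, 32),
               geometry = default_structure_geometry(c(32, 32, 32)), ...)
}
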