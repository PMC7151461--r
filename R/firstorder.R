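#' First-order statistical features
#'
#' The 17 intensity-distribution features of the manifest: Mean, Median,
#' Minimum, Maximum, Range, Variance (population), Skewness and Kurtosis
#' (population moment forms; 0 for a constant ROI), Energy and TotalEnergy
#' (voxel-volume scaled), Entropy and Uniformity (over the discretized
#' histogram, log2 with the epsilon guard), InterquartileRange, 10th/90th
#' percentiles (linear-interpolation quantiles), MeanAbsoluteDeviation and
#' RootMeanSquared.
#'
#' @param roi a `roi_voxels`.
#' @param config an `engine_config`.
#' @return named numeric vector of 17 finite values.
#' @export
first_order_features <- function(roi, config = engine_config()) {
  x <- roi$intensities
  np <- length(x)
  eps <- config$epsilon
  cshift <- config$energy_offset
  vvox <- prod(roi$spacing)
  mu <- mean(x)
  v <- mean((x - mu)^2)
  sdev <- sqrt(v)
  skew <- if (sdev > 0) mean((x - mu)^3) / sdev^3 else 0
  kurt <- if (sdev > 0) mean((x - mu)^4) / v^2 else 0
  p <- discretize(roi, config)$histogram_p
  pp <- p[p > 0]
  ent <- -sum(pp * log2(pp + eps))
  qs <- stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  energy <- sum((x + cshift)^2)
  c(Mean = mu,
    Median = stats::median(x),
    Minimum = min(x),
    Maximum = max(x),
    Range = max(x) - min(x),
    Variance = v,
    Skewness = skew,
    Kurtosis = kurt,
    Energy = energy,
    TotalEnergy = vvox * energy,
    Entropy = ent,
    Uniformity = sum(p^2),
    InterquartileRange = qs[3] - qs[2],
    Percentile10 = qs[1],
    Percentile90 = qs[4],
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RootMeanSquared = sqrt(energy / np))
}
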