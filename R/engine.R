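#' The 107-feature manifest
#'
#' The canonical ordered list of feature names and their families, with the
#' required family cardinalities 17 (first-order), 10 (shape 2D), 10
#' (shape 3D), 24 (GLCM), 12 (GLRLM), 12 (GLSZM), 12 (NGTDM), 10 (GLDM) - 107
#' in total. Full feature names are `<family>_<name>`. A copy is shipped as
#' `inst/extdata/feature_manifest.csv`.
#'
#' @return data.frame with columns `feature` (full name), `family`, `name`.
#' @export
feature_manifest <- function() {
  fam <- list(
    firstorder = c("Mean", "Median", "Minimum", "Maximum", "Range", "Variance",
                   "Skewness", "Kurtosis", "Energy", "TotalEnergy", "Entropy",
                   "Uniformity", "InterquartileRange", "Percentile10",
                   "Percentile90", "MeanAbsoluteDeviation", "RootMeanSquared"),
    shape2D = c("MeshSurface", "PixelSurface", "Perimeter",
                "PerimeterSurfaceRatio", "Sphericity", "SphericalDisproportion",
                "MaximumDiameter", "MajorAxisLength", "MinorAxisLength",
                "Elongation"),
    shape3D = c("MeshVolume", "VoxelVolume", "SurfaceArea",
                "SurfaceVolumeRatio", "Sphericity", "Maximum3DDiameter",
                "MajorAxisLength", "MinorAxisLength", "LeastAxisLength",
                "Elongation"),
    glcm = c("Autocorrelation", "JointAverage", "ClusterProminence",
             "ClusterShade", "ClusterTendency", "Contrast", "Correlation",
             "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
             "JointEnergy", "JointEntropy", "Imc1", "Imc2", "Idm", "Id",
             "Idmn", "Idn", "InverseVariance", "MaximumProbability",
             "SumAverage", "SumEntropy", "SumSquares", "MCC"),
    glrlm = c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
              "RunLengthNonUniformity", "RunPercentage", "GrayLevelVariance",
              "RunVariance", "RunEntropy", "LowGrayLevelRunEmphasis",
              "HighGrayLevelRunEmphasis", "ShortRunHighGrayLevelEmphasis",
              "LongRunHighGrayLevelEmphasis"),
    glszm = c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
              "SizeZoneNonUniformity", "ZonePercentage", "GrayLevelVariance",
              "ZoneVariance", "ZoneEntropy", "LowGrayLevelZoneEmphasis",
              "HighGrayLevelZoneEmphasis", "SmallAreaHighGrayLevelEmphasis",
              "LargeAreaLowGrayLevelEmphasis"),
    ngtdm = c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength",
              "GrayLevelMean", "GrayLevelVariance", "GrayLevelEntropy",
              "TotalDifference", "MeanDifference", "DifferenceEntropy",
              "NormalizedTotalDifference"),
    gldm = c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
             "GrayLevelNonUniformity", "DependenceNonUniformity",
             "DependenceNonUniformityNormalized", "GrayLevelVariance",
             "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
             "HighGrayLevelEmphasis")
  )
  do.call(rbind, lapply(names(fam), function(f) {
    data.frame(feature = paste0(f, "_", fam[[f]]), family = f, name = fam[[f]],
               stringsAsFactors = FALSE)
  }))
}

#' Extract all 107 features of one ROI
#'
#' Runs every family on the ROI and returns the values in manifest order.
#' Deterministic; all values finite.
#'
#' @param roi a `roi_voxels`.
#' @param config an `engine_config`.
#' @return object of class `feature_record`: list with `roi_label` and
#'   `values` (named numeric vector of 107 features).
#' @export
extract_all <- function(roi, config = engine_config()) {
  d <- discretize(roi, config)
  fo <- first_order_features(roi, config)
  s2 <- shape2d_features(roi)
  s3 <- shape3d_features(roi)
  gc <- glcm_features(d, config)
  gr <- glrlm_features(d, config)
  gz <- glszm_features(d, config)
  ngt <- ngtdm_features(d, config)
  gld <- gldm_features(d, config)
  vals <- c(stats::setNames(fo, paste0("firstorder_", names(fo))),
            stats::setNames(s2, paste0("shape2D_", names(s2))),
            stats::setNames(s3, paste0("shape3D_", names(s3))),
            stats::setNames(gc, paste0("glcm_", names(gc))),
            stats::setNames(gr, paste0("glrlm_", names(gr))),
            stats::setNames(gz, paste0("glszm_", names(gz))),
            stats::setNames(ngt, paste0("ngtdm_", names(ngt))),
            stats::setNames(gld, paste0("gldm_", names(gld))))
  mf <- feature_manifest()
  if (!identical(names(vals), mf$feature))
    stop("internal error: engine output does not match the feature manifest")
  if (!all(is.finite(vals)))
    stop("internal error: non-finite feature values: ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "))
  structure(list(roi_label = roi$label, values = vals), class = "feature_record")
}
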