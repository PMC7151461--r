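test_that("anchored features match literal-formula oracles to 1e-10", {
  dirs <- directions13()
  cfg <- engine_config(n_bins = 4L)
  for (s in 1:8) {
    fx <- random_test_roi(c(4, 4, 4), ng = 4L, seed = 300 + s,
                          mask_frac = if (s %% 2) 1 else 0.8)
    lv <- fx$dense
    # GLCM anchors: average the per-direction literal evaluations
    acc <- NULL; nd <- 0
    for (r in 1:13) {
      p <- oracle_glcm(lv, dirs[r, ], 4L)
      if (is.null(p)) next
      a <- oracle_glcm_anchors(p)
      acc <- if (is.null(acc)) a else acc + a
      nd <- nd + 1
    }
    got <- glcm_features(fx$disc, cfg)
    for (nm in names(acc))
      expect_equal(unname(got[nm]), unname(acc[nm] / nd), tolerance = 1e-10)
    # GLRLM anchors
    racc <- NULL
    for (r in 1:13) {
      a <- oracle_glrlm_anchors(oracle_glrlm(lv, dirs[r, ], 4L))
      racc <- if (is.null(racc)) a else racc + a
    }
    rgot <- glrlm_features(fx$disc, cfg)
    for (nm in names(racc))
      expect_equal(unname(rgot[nm]), unname(racc[nm] / 13), tolerance = 1e-10)
    # GLSZM / NGTDM / GLDM anchors
    expect_equal(unname(glszm_features(fx$disc, cfg)["SmallAreaHighGrayLevelEmphasis"]),
                 oracle_glszm_sahgle(oracle_glszm(lv, 4L)), tolerance = 1e-10)
    expect_equal(unname(ngtdm_features(fx$disc, cfg)["Coarseness"]),
                 oracle_ngtdm_coarseness(oracle_ngtdm(lv, 4L)), tolerance = 1e-10)
    ga <- oracle_gldm_anchors(oracle_gldm(lv, 4L))
    ggot <- gldm_features(fx$disc, cfg)
    expect_equal(unname(ggot["SmallDependenceEmphasis"]),
                 unname(ga["SmallDependenceEmphasis"]), tolerance = 1e-10)
    expect_equal(unname(ggot["DependenceNonUniformity"]),
                 unname(ga["DependenceNonUniformity"]), tolerance = 1e-10)
  }
})

test_that("constant-ROI limits are the analytic ones", {
  cst <- roi_from_levels(array(1, c(3, 3, 3)))
  f <- glcm_features(cst$disc)
  expect_equal(unname(f["Autocorrelation"]), 1)
  expect_equal(unname(f["ClusterProminence"]), 0)
  expect_lt(abs(f["DifferenceEntropy"]), 1e-12)
  expect_equal(unname(f["Idm"]), 1)
  expect_equal(unname(f["JointEnergy"]), 1)
  r <- glrlm_features(cst$disc)
  expect_equal(unname(r["GrayLevelVariance"]), 0)
  expect_equal(unname(r["HighGrayLevelRunEmphasis"]), 1)
  # single-direction limit: a lone run has GLN = 1 and zero run entropy
  line <- roi_from_levels(array(1, c(1, 1, 4)))
  P <- glrlm_matrix(line$disc, c(0, 0, 1))
  f1d <- voxrad:::.glrlm_feats_one(P, 4, 2.22e-16)
  expect_equal(unname(f1d["GrayLevelNonUniformity"]), 1)
  expect_lt(abs(f1d["RunEntropy"]), 1e-12)
  n <- ngtdm_features(cst$disc)
  expect_equal(unname(n["Coarseness"]), 1e6)
  expect_equal(unname(n["TotalDifference"]), 0)
})

test_that("single-voxel ROI degenerates to the single-cell limits", {
  one <- roi_from_levels(array(1, c(1, 1, 1)))
  f <- glcm_features(one$disc)
  expect_equal(unname(f["Autocorrelation"]), 1)
  expect_equal(unname(f["Idm"]), 1)
  g <- gldm_features(one$disc)
  expect_equal(unname(g["DependenceNonUniformity"]), 1)
  expect_equal(unname(g["SmallDependenceEmphasis"]), 1)
  z <- glszm_features(one$disc)
  expect_equal(unname(z["ZonePercentage"]), 1)
})

test_that("direction-averaged GLCM/GLRLM features are 90-degree rotation invariant", {
  fx <- random_test_roi(c(4, 5, 3), ng = 4L, seed = 71)
  lv <- fx$dense
  # rotate 90 degrees about the third axis: (i, j) -> (j, ni + 1 - i)
  rot <- aperm(lv, c(2, 1, 3))[, dim(lv)[1]:1, , drop = FALSE]
  fr <- roi_from_levels(rot)
  expect_equal(glcm_features(fx$disc), glcm_features(fr$disc), tolerance = 1e-12)
  expect_equal(glrlm_features(fx$disc), glrlm_features(fr$disc), tolerance = 1e-12)
})

test_that("texture features are invariant to an intensity shift", {
  fx <- random_test_roi(c(4, 4, 4), ng = 5L, seed = 55)
  roi2 <- fx$roi
  roi2$intensities <- roi2$intensities + 250
  d2 <- discretize(roi2, engine_config(n_bins = 5L))
  expect_equal(glcm_features(fx$disc), glcm_features(d2), tolerance = 1e-12)
  expect_equal(glszm_features(fx$disc), glszm_features(d2), tolerance = 1e-12)
  expect_equal(gldm_features(fx$disc), gldm_features(d2), tolerance = 1e-12)
})
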