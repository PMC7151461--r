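test_that("texture matrices equal brute-force enumeration on random ROIs", {
  dirs <- directions13()
  shapes <- list(c(4, 4, 4), c(5, 5, 5), c(5, 4, 3), c(3, 3, 3), c(5, 5, 2))
  cases <- 0L
  for (s in 1:20) {
    shape <- shapes[[(s - 1L) %% length(shapes) + 1L]]
    frac <- if (s %% 2 == 0) 0.8 else 1
    fx <- random_test_roi(shape, ng = 4L, seed = 1000 + s, mask_frac = frac)
    lv <- fx$dense
    ng <- 4L
    for (r in 1:13) {
      got <- glcm_matrix(fx$disc, dirs[r, ])
      want <- oracle_glcm(lv, dirs[r, ], ng)
      if (is.null(want)) expect_null(got) else expect_equal(got, want)
      expect_equal(glrlm_matrix(fx$disc, dirs[r, ]),
                   oracle_glrlm(lv, dirs[r, ], ng))
    }
    expect_equal(glszm_matrix(fx$disc), oracle_glszm(lv, ng))
    o_ng <- oracle_ngtdm(lv, ng)
    g_ng <- ngtdm_matrix(fx$disc)
    expect_equal(g_ng$p, o_ng$p)
    expect_equal(g_ng$s, o_ng$s)
    expect_equal(g_ng$n_valid, o_ng$n_valid)
    expect_equal(gldm_matrix(fx$disc, alpha = 0L), oracle_gldm(lv, ng, 0L))
    cases <- cases + 1L
  }
  expect_gte(cases, 20L)
})

test_that("matrix normalizations hold", {
  fx <- random_test_roi(c(5, 5, 5), ng = 6L, seed = 9, mask_frac = 0.75)
  np <- length(fx$disc$gray_levels)
  dirs <- directions13()
  for (r in 1:13) {
    p <- glcm_matrix(fx$disc, dirs[r, ])
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(p, t(p))
    expect_true(all(p >= 0))
  }
  m <- ngtdm_matrix(fx$disc)
  expect_equal(sum(m$p), 1, tolerance = 1e-12)
  expect_equal(sum(gldm_matrix(fx$disc)), np)        # every voxel counted once
  expect_equal(sum(glrlm_matrix(fx$disc, c(1, 0, 0)) > 0) >= 1, TRUE)
})

test_that("hand-computed matrix examples", {
  # constant 2x2x2: one co-occurrence cell in every direction
  cst <- roi_from_levels(array(1, c(2, 2, 2)))
  dirs <- directions13()
  for (r in 1:13) {
    p <- glcm_matrix(cst$disc, dirs[r, ])
    expect_equal(p[1, 1], 1)
  }
  # 1x1x2 with levels 1,2 along z: p(1,2) = p(2,1) = 0.5
  two <- roi_from_levels(array(c(1, 2), c(1, 1, 2)))
  p <- glcm_matrix(two$disc, c(0, 0, 1))
  expect_equal(p[1, 2], 0.5)
  expect_equal(p[2, 1], 0.5)
  # constant 1x1x4 line: a single run of length 4
  line <- roi_from_levels(array(1, c(1, 1, 4)))
  P <- glrlm_matrix(line$disc, c(0, 0, 1))
  expect_equal(sum(P), 1)
  expect_equal(P[1, 4], 1)
  # (1,1,2): runs (1, len 2) and (2, len 1)
  l2 <- roi_from_levels(array(c(1, 1, 2), c(1, 1, 3)))
  P2 <- glrlm_matrix(l2$disc, c(0, 0, 1))
  expect_equal(P2[1, 2], 1)
  expect_equal(P2[2, 1], 1)
  expect_equal(sum(P2), 2)
  # two single-voxel level-2 islands in a level-1 sea: P(2,1) = 2
  sea <- array(1, c(3, 3, 3)); sea[1, 1, 1] <- 2; sea[3, 3, 3] <- 2
  sz <- glszm_matrix(roi_from_levels(sea)$disc)
  expect_equal(sz[2, 1], 2)
  expect_equal(sz[1, 25], 1)   # the sea is one 25-voxel zone
  # NGTDM on the 1,2,1 line: s2 = 1, s1 = 2, p = (2/3, 1/3)
  l3 <- roi_from_levels(array(c(1, 2, 1), c(1, 1, 3)))
  m3 <- ngtdm_matrix(l3$disc)
  expect_equal(m3$s[1:2], c(2, 1))
  expect_equal(m3$p[1:2], c(2 / 3, 1 / 3))
  # GLDM on a constant 3x3x3 cube: center has 26 dependents, corners 7
  cube <- roi_from_levels(array(1, c(3, 3, 3)))
  P3 <- gldm_matrix(cube$disc)
  expect_equal(P3[1, 27], 1)    # dependence 26 -> column 27 (the center)
  expect_equal(P3[1, 8], 8)     # dependence 7 -> the 8 corners
})

test_that("runs break at mask gaps", {
  lv <- array(c(1, 1, NA, 1, 1), c(1, 1, 5))
  fx <- roi_from_levels(lv)
  P <- glrlm_matrix(fx$disc, c(0, 0, 1))
  expect_equal(P[1, 2], 2)      # two runs of length 2, not one of 4
})
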