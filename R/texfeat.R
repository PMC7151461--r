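#' @title Texture feature families
#' @description Feature formulas applied to the texture matrices. GLCM and
#'   GLRLM features are computed per direction and averaged over the 13
#'   lattice directions (averaging feature values, not matrices); GLSZM, NGTDM
#'   and GLDM are direction-free. Degenerate ROIs (single voxel, or constant
#'   intensity) take the analytic limits: entropies 0, uniformities 1, NGTDM
#'   Coarseness capped at 1e6.
#' @name texture-features
NULL

.ngtdm_coarseness_cap <- 1e6

# ---- GLCM ------------------------------------------------------------------

# 24 features from one normalized symmetric GLCM.
.glcm_feats_one <- function(p, eps) {
  ng <- nrow(p)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p)
  mux <- sum(seq_len(ng) * px)
  sigx2 <- sum((seq_len(ng) - mux)^2 * px)
  # difference distribution p_{x-y}(k), k = 0..Ng-1
  k <- abs(i - j)
  pxy_d <- as.vector(rowsum(as.vector(p), as.vector(k)))
  kd <- sort(unique(as.vector(k)))
  pd <- rep(0, ng); pd[kd + 1L] <- pxy_d   # index k+1
  ks <- 0:(ng - 1)
  # sum distribution p_{x+y}(k), k = 2..2Ng
  sm <- i + j
  pxy_s <- as.vector(rowsum(as.vector(p), as.vector(sm)))
  su <- sort(unique(as.vector(sm)))
  ps <- rep(0, 2 * ng - 1); ps[su - 1L] <- pxy_s  # index k-1
  kss <- 2:(2 * ng)
  da <- sum(ks * pd)
  hx <- -sum(px[px > 0] * log2(px[px > 0] + eps))
  pp <- p[p > 0]
  hxy <- -sum(pp * log2(pp + eps))
  pij_prod <- outer(px, px)
  sel <- p > 0
  hxy1 <- -sum(p[sel] * log2(pij_prod[sel] + eps))
  sel2 <- pij_prod > 0
  hxy2 <- -sum(pij_prod[sel2] * log2(pij_prod[sel2] + eps))
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  corr <- if (sigx2 > 0) (sum(i * j * p) - mux^2) / sigx2 else 1
  # MCC: second largest eigenvalue of Q over the present levels
  lvls <- which(px > 0)
  mcc <- if (length(lvls) < 2) 1 else {
    psub <- p[lvls, lvls, drop = FALSE]
    pxs <- px[lvls]
    # Q(a, b) = sum_k p(a,k) p(b,k) / (px(a) px(k))
    q <- (psub / pxs) %*% t(sweep(psub, 2, pxs, "/"))
    ev <- sort(Re(eigen(q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(pmax(0, ev[2]))
  }
  c(Autocorrelation = sum(i * j * p),
    JointAverage = mux,
    ClusterProminence = sum((i + j - 2 * mux)^4 * p),
    ClusterShade = sum((i + j - 2 * mux)^3 * p),
    ClusterTendency = sum((i + j - 2 * mux)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pd[pd > 0] * log2(pd[pd > 0] + eps)),
    DifferenceVariance = sum((ks - da)^2 * pd),
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    Imc1 = imc1,
    Imc2 = imc2,
    Idm = sum(pd / (1 + ks^2)),
    Id = sum(pd / (1 + ks)),
    Idmn = sum(pd / (1 + (ks / ng)^2)),
    Idn = sum(pd / (1 + ks / ng)),
    InverseVariance = sum(pd[-1] / ks[-1]^2),
    MaximumProbability = max(p),
    SumAverage = sum(kss * ps),
    SumEntropy = -sum(ps[ps > 0] * log2(ps[ps > 0] + eps)),
    SumSquares = sum((i - mux)^2 * p),
    MCC = mcc)
}

#' GLCM features (24, direction-averaged)
#'
#' @param d a `discretized_roi`.
#' @param config an `engine_config`.
#' @return named numeric vector of 24 values.
#' @export
glcm_features <- function(d, config = engine_config()) {
  dirs <- directions13()
  acc <- NULL; nd <- 0L
  for (r in 1:13) {
    p <- glcm_matrix(d, dirs[r, ], config$glcm_distance)
    if (is.null(p)) next
    f <- .glcm_feats_one(p, config$epsilon)
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1L
  }
  if (nd == 0L) {  # Np = 1: single-cell limit
    return(.glcm_feats_one(matrix(1, 1, 1), config$epsilon))
  }
  acc / nd
}

# ---- GLRLM -----------------------------------------------------------------

.glrlm_feats_one <- function(P, np, eps) {
  nr <- sum(P)
  p <- P / nr
  ng <- nrow(P); lmax <- ncol(P)
  i <- matrix(seq_len(ng), ng, lmax)
  j <- matrix(seq_len(lmax), ng, lmax, byrow = TRUE)
  mu_i <- sum(p * i)
  mu_j <- sum(p * j)
  pp <- p[p > 0]
  c(ShortRunEmphasis = sum(P / j^2) / nr,
    LongRunEmphasis = sum(P * j^2) / nr,
    GrayLevelNonUniformity = sum(rowSums(P)^2) / nr,
    RunLengthNonUniformity = sum(colSums(P)^2) / nr,
    RunPercentage = nr / np,
    GrayLevelVariance = sum(p * (i - mu_i)^2),
    RunVariance = sum(p * (j - mu_j)^2),
    RunEntropy = -sum(pp * log2(pp + eps)),
    LowGrayLevelRunEmphasis = sum(P / i^2) / nr,
    HighGrayLevelRunEmphasis = sum(P * i^2) / nr,
    ShortRunHighGrayLevelEmphasis = sum(P * i^2 / j^2) / nr,
    LongRunHighGrayLevelEmphasis = sum(P * i^2 * j^2) / nr)
}

#' GLRLM features (12, direction-averaged)
#'
#' @param d a `discretized_roi`.
#' @param config an `engine_config`.
#' @return named numeric vector of 12 values.
#' @export
glrlm_features <- function(d, config = engine_config()) {
  dirs <- directions13()
  np <- length(d$gray_levels)
  acc <- NULL
  for (r in 1:13) {
    f <- .glrlm_feats_one(glrlm_matrix(d, dirs[r, ]), np, config$epsilon)
    acc <- if (is.null(acc)) f else acc + f
  }
  acc / 13
}

# ---- GLSZM -----------------------------------------------------------------

.glszm_feats_one <- function(P, np, eps) {
  nz <- sum(P)
  p <- P / nz
  ng <- nrow(P); smax <- ncol(P)
  i <- matrix(seq_len(ng), ng, smax)
  j <- matrix(seq_len(smax), ng, smax, byrow = TRUE)
  mu_i <- sum(p * i)
  mu_j <- sum(p * j)
  pp <- p[p > 0]
  c(SmallAreaEmphasis = sum(P / j^2) / nz,
    LargeAreaEmphasis = sum(P * j^2) / nz,
    GrayLevelNonUniformity = sum(rowSums(P)^2) / nz,
    SizeZoneNonUniformity = sum(colSums(P)^2) / nz,
    ZonePercentage = nz / np,
    GrayLevelVariance = sum(p * (i - mu_i)^2),
    ZoneVariance = sum(p * (j - mu_j)^2),
    ZoneEntropy = -sum(pp * log2(pp + eps)),
    LowGrayLevelZoneEmphasis = sum(P / i^2) / nz,
    HighGrayLevelZoneEmphasis = sum(P * i^2) / nz,
    SmallAreaHighGrayLevelEmphasis = sum(P * i^2 / j^2) / nz,
    LargeAreaLowGrayLevelEmphasis = sum(P * j^2 / i^2) / nz)
}

#' GLSZM features (12)
#'
#' @param d a `discretized_roi`.
#' @param config an `engine_config`.
#' @return named numeric vector of 12 values.
#' @export
glszm_features <- function(d, config = engine_config()) {
  .glszm_feats_one(glszm_matrix(d), length(d$gray_levels), config$epsilon)
}

# ---- NGTDM -----------------------------------------------------------------

#' NGTDM features (12)
#'
#' The five canonical neighbourhood-tone features (Coarseness, Contrast,
#' Busyness, Complexity, Strength) extended, to reach the family's required
#' cardinality of 12, with documented summaries of the level distribution
#' (GrayLevelMean/Variance/Entropy) and of the difference strengths
#' (TotalDifference, MeanDifference, DifferenceEntropy over normalized s,
#' NormalizedTotalDifference). Coarseness is capped at 1e6 when sum(p*s) = 0.
#'
#' @param d a `discretized_roi`.
#' @param config an `engine_config`.
#' @return named numeric vector of 12 values.
#' @export
ngtdm_features <- function(d, config = engine_config()) {
  m <- ngtdm_matrix(d)
  .ngtdm_feats_one(m, config$epsilon)
}

.ngtdm_feats_one <- function(m, eps) {
  p <- m$p; s <- m$s; nvp <- m$n_valid
  ng <- length(p)
  lv <- seq_len(ng)
  act <- which(p > 0)
  ngp <- length(act)
  ps <- sum(p * s)
  coarse <- if (ps > 0) min(1 / ps, .ngtdm_coarseness_cap) else .ngtdm_coarseness_cap
  contrast <- if (ngp > 1 && nvp > 0) {
    sum(outer(p[act], p[act]) * outer(lv[act], lv[act], "-")^2) /
      (ngp * (ngp - 1)) * sum(s) / nvp
  } else 0
  busy_den <- if (ngp > 0) sum(abs(outer(lv[act] * p[act], lv[act] * p[act], "-"))) else 0
  busy <- if (busy_den > 0) ps / busy_den else 0
  cmplx <- if (nvp > 0 && ngp > 0) {
    pi_ <- p[act]; si_ <- s[act]; li <- lv[act]
    sum(abs(outer(li, li, "-")) *
          (outer(pi_ * si_, rep(1, ngp)) + outer(rep(1, ngp), pi_ * si_)) /
          (outer(pi_, rep(1, ngp)) + outer(rep(1, ngp), pi_))) / nvp
  } else 0
  strength <- if (sum(s) > 0 && ngp > 0) {
    sum((outer(p[act], rep(1, ngp)) + outer(rep(1, ngp), p[act])) *
          outer(lv[act], lv[act], "-")^2) / sum(s)
  } else 0
  mu <- sum(p * lv)
  pp <- p[p > 0]
  q <- if (sum(s) > 0) s / sum(s) else rep(0, ng)
  qq <- q[q > 0]
  c(Coarseness = coarse,
    Contrast = contrast,
    Busyness = busy,
    Complexity = cmplx,
    Strength = strength,
    GrayLevelMean = mu,
    GrayLevelVariance = sum(p * (lv - mu)^2),
    GrayLevelEntropy = -sum(pp * log2(pp + eps)),
    TotalDifference = sum(s),
    MeanDifference = ps,
    DifferenceEntropy = if (length(qq)) -sum(qq * log2(qq + eps)) else 0,
    NormalizedTotalDifference = if (nvp > 0) sum(s) / nvp else 0)
}

# ---- GLDM ------------------------------------------------------------------

.gldm_feats_one <- function(P, eps) {
  nz <- sum(P)
  p <- P / nz
  ng <- nrow(P); dmax <- ncol(P)
  i <- matrix(seq_len(ng), ng, dmax)
  j <- matrix(seq_len(dmax), ng, dmax, byrow = TRUE)
  mu_i <- sum(p * i)
  mu_j <- sum(p * j)
  pp <- p[p > 0]
  c(SmallDependenceEmphasis = sum(P / j^2) / nz,
    LargeDependenceEmphasis = sum(P * j^2) / nz,
    GrayLevelNonUniformity = sum(rowSums(P)^2) / nz,
    DependenceNonUniformity = sum(colSums(P)^2) / nz,
    DependenceNonUniformityNormalized = sum(colSums(P)^2) / nz^2,
    GrayLevelVariance = sum(p * (i - mu_i)^2),
    DependenceVariance = sum(p * (j - mu_j)^2),
    DependenceEntropy = -sum(pp * log2(pp + eps)),
    LowGrayLevelEmphasis = sum(P / i^2) / nz,
    HighGrayLevelEmphasis = sum(P * i^2) / nz)
}

#' GLDM features (10)
#'
#' @param d a `discretized_roi`.
#' @param config an `engine_config`.
#' @return named numeric vector of 10 values.
#' @export
gldm_features <- function(d, config = engine_config()) {
  .gldm_feats_one(gldm_matrix(d, config$gldm_alpha), config$epsilon)
}
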