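#' @title Tree learners: CART, random forest, gradient boosting
#' @description A weighted CART implementation (gini impurity for
#'   classification, variance reduction for regression) underlying two
#'   ensemble classifiers: a bootstrap random forest with feature subsampling
#'   (gini, depth/leaf-size limits per the reference hyperparameters) and a
#'   softmax gradient-boosting machine (one regression tree per class per
#'   round, Newton leaf values, shrinkage).
#' @name trees
NULL

# Grow one CART. x: n x p matrix; resp: for "gini", integer class in 1..K plus
# weights; for "var", numeric target (g) and hessian (h) for Newton leaves.
# Returns a flat list of nodes.
.cart_grow <- function(x, idx, depth, opts, node_fun, score_fun) {
  node <- node_fun(idx)
  if (depth >= opts$max_depth || length(idx) < opts$min_split) return(node)
  p <- ncol(x)
  mtry <- min(p, opts$mtry)
  cand <- if (mtry < p) sort(opts$sample_feats(p, mtry)) else seq_len(p)
  best <- list(gain = 0)
  for (f in cand) {
    v <- x[idx, f]
    o <- order(v)
    sv <- v[o]
    cut_ok <- which(diff(sv) > 0)
    if (!length(cut_ok)) next
    sc <- score_fun(idx[o], cut_ok)      # per-cut gain honoring min_leaf
    if (is.null(sc)) next
    gi <- which.max(sc$gain)
    if (sc$gain[gi] > best$gain) {
      ci <- sc$cut[gi]
      best <- list(gain = sc$gain[gi], feat = f,
                   thr = (sv[ci] + sv[ci + 1]) / 2)
    }
  }
  if (best$gain <= 0) return(node)
  left <- idx[x[idx, best$feat] <= best$thr]
  right <- idx[x[idx, best$feat] > best$thr]
  if (length(left) < opts$min_leaf || length(right) < opts$min_leaf) return(node)
  node$feat <- best$feat
  node$thr <- best$thr
  node$left <- .cart_grow(x, left, depth + 1L, opts, node_fun, score_fun)
  node$right <- .cart_grow(x, right, depth + 1L, opts, node_fun, score_fun)
  node
}

# Classification tree with sample weights; leaf stores the weighted class
# distribution.
.cart_class <- function(x, y, w, k, opts) {
  node_fun <- function(idx) {
    dist <- vapply(seq_len(k), function(c) sum(w[idx][y[idx] == c]), numeric(1))
    list(dist = dist / sum(dist))
  }
  score_fun_factory <- function() {
    function(oidx, cut_ok) {
      n <- length(oidx)
      keep <- cut_ok[cut_ok >= opts$min_leaf & (n - cut_ok) >= opts$min_leaf]
      if (!length(keep)) return(NULL)
      wo <- w[oidx]
      cw <- vapply(seq_len(k), function(c) cumsum(wo * (y[oidx] == c)), numeric(n))
      tot <- cw[n, ]
      wl <- rowSums(cw)[keep]; wr <- sum(tot) - wl
      gl <- 1 - rowSums((cw[keep, , drop = FALSE] / wl)^2)
      cr <- matrix(tot, length(keep), k, byrow = TRUE) - cw[keep, , drop = FALSE]
      gr <- 1 - rowSums((cr / wr)^2)
      g0 <- 1 - sum((tot / sum(tot))^2)
      list(gain = g0 - (wl * gl + wr * gr) / sum(tot), cut = keep)
    }
  }
  .cart_grow(x, seq_len(nrow(x)), 0L, opts, node_fun, score_fun_factory())
}

# Regression tree on gradient/hessian pairs; leaf = Newton step -G/(H+lambda).
.cart_newton <- function(x, g, h, opts, lambda = 1) {
  node_fun <- function(idx) list(value = -sum(g[idx]) / (sum(h[idx]) + lambda))
  score_fun <- function(oidx, cut_ok) {
    n <- length(oidx)
    keep <- cut_ok[cut_ok >= opts$min_leaf & (n - cut_ok) >= opts$min_leaf]
    if (!length(keep)) return(NULL)
    cg <- cumsum(g[oidx]); ch <- cumsum(h[oidx])
    G <- cg[n]; H <- ch[n]
    gl <- cg[keep]; hl <- ch[keep]
    gain <- gl^2 / (hl + lambda) + (G - gl)^2 / (H - hl + lambda) -
      G^2 / (H + lambda)
    list(gain = gain, cut = keep)
  }
  .cart_grow(x, seq_len(nrow(x)), 0L, opts, node_fun, score_fun)
}

.cart_predict <- function(node, x) {
  n <- nrow(x)
  out <- vector("list", n)
  rec <- function(nd, rows) {
    if (is.null(nd$feat)) { out[rows] <<- list(nd); return(invisible()) }
    go_l <- x[rows, nd$feat] <= nd$thr
    if (any(go_l)) rec(nd$left, rows[go_l])
    if (any(!go_l)) rec(nd$right, rows[!go_l])
  }
  rec(node, seq_len(n))
  out
}

#' Fit a random forest classifier
#'
#' Bootstrap-sampled, feature-subsampled (sqrt(p)) gini trees; probabilities
#' are the average of per-tree leaf class distributions.
#'
#' @param x numeric matrix.
#' @param y factor of classes.
#' @param sample_weights per-sample weights entering the gini computation.
#' @param n_trees,max_depth,min_split,min_leaf forest hyperparameters
#'   (reference defaults 1000 / 7 / 20 / 10).
#' @param seed RNG seed (bootstrap + feature subsampling).
#' @return object of class `voxrad_rf`.
#' @export
rf_fit <- function(x, y, sample_weights = NULL, n_trees = 1000L, max_depth = 7L,
                   min_split = 20L, min_leaf = 10L, seed = 1L) {
  y <- factor(y)
  k <- nlevels(y)
  yi <- as.integer(y)
  n <- nrow(x)
  w <- if (is.null(sample_weights)) rep(1, n) else sample_weights
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed %% .Machine$integer.max))
  opts <- list(max_depth = max_depth, min_split = min_split, min_leaf = min_leaf,
               mtry = max(1L, floor(sqrt(ncol(x)))),
               sample_feats = function(p, m) sample.int(p, m))
  trees <- lapply(seq_len(n_trees), function(t) {
    bs <- sample.int(n, n, replace = TRUE)
    .cart_class(x[bs, , drop = FALSE], yi[bs], w[bs], k, opts)
  })
  structure(list(trees = trees, classes = levels(y)), class = "voxrad_rf")
}

#' @export
predict.voxrad_rf <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  k <- length(object$classes)
  acc <- matrix(0, nrow(x), k)
  for (tr in object$trees) {
    leaves <- .cart_predict(tr, x)
    acc <- acc + t(vapply(leaves, function(l) l$dist, numeric(k)))
  }
  p <- acc / length(object$trees)
  colnames(p) <- object$classes
  if (type == "prob") p else object$classes[max.col(p, ties.method = "first")]
}

#' Fit a softmax gradient-boosted tree classifier
#'
#' One Newton regression tree per class per round on the softmax gradients,
#' with shrinkage; sample weights multiply the per-sample gradients and
#' hessians.
#'
#' @param x numeric matrix.
#' @param y factor.
#' @param sample_weights per-sample loss weights.
#' @param n_rounds,max_depth boosting hyperparameters (reference defaults
#'   600 / 9).
#' @param eta shrinkage (0.3).
#' @param min_leaf minimum samples per leaf.
#' @param lambda L2 regularization of leaf values.
#' @param seed unused (fitting is deterministic) but kept for interface
#'   uniformity.
#' @return object of class `voxrad_gbt`.
#' @export
gbt_fit <- function(x, y, sample_weights = NULL, n_rounds = 600L, max_depth = 9L,
                    eta = 0.3, min_leaf = 1L, lambda = 1, seed = 1L) {
  y <- factor(y)
  k <- nlevels(y)
  n <- nrow(x)
  yk <- matrix(0, n, k)
  yk[cbind(seq_len(n), as.integer(y))] <- 1
  w <- if (is.null(sample_weights)) rep(1, n) else sample_weights
  opts <- list(max_depth = max_depth, min_split = 2L * min_leaf,
               min_leaf = min_leaf, mtry = ncol(x),
               sample_feats = function(p, m) seq_len(p))
  scores <- matrix(0, n, k)
  forest <- vector("list", n_rounds)
  for (r in seq_len(n_rounds)) {
    p <- .softmax(scores)
    round_trees <- vector("list", k)
    for (c in seq_len(k)) {
      g <- w * (p[, c] - yk[, c])
      h <- w * pmax(p[, c] * (1 - p[, c]), 1e-12)
      tr <- .cart_newton(x, g, h, opts, lambda)
      leaves <- .cart_predict(tr, x)
      scores[, c] <- scores[, c] + eta * vapply(leaves, function(l) l$value, numeric(1))
      round_trees[[c]] <- tr
    }
    forest[[r]] <- round_trees
  }
  structure(list(forest = forest, classes = levels(y), eta = eta),
            class = "voxrad_gbt")
}

#' @export
predict.voxrad_gbt <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  k <- length(object$classes)
  scores <- matrix(0, nrow(x), k)
  for (round_trees in object$forest) {
    for (c in seq_len(k)) {
      leaves <- .cart_predict(round_trees[[c]], x)
      scores[, c] <- scores[, c] +
        object$eta * vapply(leaves, function(l) l$value, numeric(1))
    }
  }
  p <- .softmax(scores)
  colnames(p) <- object$classes
  if (type == "prob") p else object$classes[max.col(p, ties.method = "first")]
}
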