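#' @title Two-level feature selection
#' @description Level one removes redundant features with a Pearson
#'   correlation filter (default threshold |r| > 0.90); level two ranks the
#'   survivors by recursive feature elimination (RFE) under an L2-penalized
#'   multinomial logistic base model and keeps the k best.
#' @name feature-selection
NULL

.feature_cols <- function(table) {
  setdiff(colnames(table), c("scan_id", "class"))
}

#' Pearson correlation redundancy filter
#'
#' Greedy elimination: while any surviving pair has |r| above the threshold,
#' the pair with the largest |r| is found and the member with the larger mean
#' |r| against all other survivors is dropped (ties: the later column).
#' Zero-variance features are excluded from the correlation computation and
#' retained with a warning.
#'
#' @param table feature table (data.frame with scan_id, class, features).
#' @param threshold drop threshold on |r|, default 0.90.
#' @return list with `table` (reduced), `kept` (feature names) and `dropped`
#'   (data.frame dropped / partner / r).
#' @export
correlation_filter <- function(table, threshold = 0.90) {
  feats <- .feature_cols(table)
  x <- as.matrix(table[, feats, drop = FALSE])
  sds <- apply(x, 2, stats::sd)
  constant <- feats[sds == 0]
  if (length(constant))
    warning("zero-variance features retained without correlation screening: ",
            paste(constant, collapse = ", "))
  active <- feats[sds > 0]
  drops <- list()
  if (length(active) >= 2) {
    r <- abs(stats::cor(x[, active, drop = FALSE]))
    diag(r) <- 0
    while (max(r) > threshold) {
      idx <- which(r == max(r), arr.ind = TRUE)[1, ]
      a <- rownames(r)[idx[1]]; b <- colnames(r)[idx[2]]
      mean_a <- mean(r[a, ]); mean_b <- mean(r[b, ])
      drop <- if (mean_a > mean_b) a else if (mean_b > mean_a) b else {
        if (match(a, active) > match(b, active)) a else b
      }
      partner <- if (drop == a) b else a
      drops[[length(drops) + 1L]] <- data.frame(dropped = drop, partner = partner,
                                                r = max(r), stringsAsFactors = FALSE)
      keep <- setdiff(rownames(r), drop)
      r <- r[keep, keep, drop = FALSE]
      if (length(keep) < 2) break
    }
    active <- rownames(r)
  }
  kept <- feats[feats %in% c(active, constant)]
  list(table = table[, c("scan_id", "class", kept)],
       kept = kept,
       dropped = if (length(drops)) do.call(rbind, drops)
                 else data.frame(dropped = character(), partner = character(),
                                 r = numeric()))
}

# Multinomial logistic base model (L2, fixed small penalty) on z-scored
# features; returns per-feature importance = L2 norm of the coefficient
# vector across classes.
.base_model_importance <- function(x, y, lambda = 1e-3) {
  xs <- scale(x)
  xs[, attr(xs, "scaled:scale") == 0] <- 0
  fit <- glmnet::glmnet(xs, y, family = "multinomial", alpha = 0,
                        lambda = c(10, 1, lambda), standardize = FALSE,
                        maxit = 1e5)
  b <- stats::coef(fit, s = lambda)
  m <- do.call(cbind, lapply(b, function(bc) as.matrix(bc)[-1, 1]))
  sqrt(rowSums(m^2))
}

#' Recursive feature elimination
#'
#' Repeatedly fits the base model (multinomial logistic regression with L2
#' penalty on standardized features) and removes the feature with the
#' smallest coefficient-norm importance, one per iteration, until `k` remain.
#' Ranking: the kept features take ranks 1..k ordered by final-model
#' importance; eliminated features follow in reverse elimination order.
#'
#' @param table feature table.
#' @param k number of features to keep (reference operating point: 20).
#' @return object of class `selection_result`: list with `kept` (ordered by
#'   rank), `ranking` (named integer vector over all input features), `k` and
#'   `base_model` (description string).
#' @export
recursive_feature_elimination <- function(table, k = 20L) {
  feats <- .feature_cols(table)
  if (k > length(feats))
    stop("selection error: k = ", k, " exceeds the ", length(feats),
         " available features")
  x <- as.matrix(table[, feats, drop = FALSE])
  y <- factor(table$class)
  surviving <- feats
  eliminated <- character()
  while (length(surviving) > k) {
    imp <- .base_model_importance(x[, surviving, drop = FALSE], y)
    worst <- surviving[which.min(imp)]
    eliminated <- c(worst, eliminated)   # reverse elimination order
    surviving <- setdiff(surviving, worst)
  }
  imp_final <- .base_model_importance(x[, surviving, drop = FALSE], y)
  kept <- surviving[order(imp_final, decreasing = TRUE)]
  ranking <- stats::setNames(seq_along(c(kept, eliminated)), c(kept, eliminated))
  structure(list(kept = kept, ranking = ranking, k = as.integer(k),
                 base_model = "multinomial logistic regression (L2, z-scored features)"),
            class = "selection_result")
}

#' Score candidate subset sizes
#'
#' For each k, runs RFE and scores the kept subset by stratified
#' cross-validated accuracy of the base model.
#'
#' @param table feature table.
#' @param k_list integer vector of candidate sizes (default 10, 20, 30, 40).
#' @param n_folds folds for the internal CV (default 3).
#' @param seed seed for the fold assignment.
#' @return data.frame with columns k, score.
#' @export
selection_sweep <- function(table, k_list = c(10L, 20L, 30L, 40L),
                            n_folds = 3L, seed = 1L) {
  stopifnot(length(k_list) >= 1)
  y <- factor(table$class)
  folds <- .stratified_folds(y, n_folds, seed)
  scores <- vapply(k_list, function(k) {
    sel <- recursive_feature_elimination(table, k)
    x <- as.matrix(table[, sel$kept, drop = FALSE])
    acc <- vapply(seq_len(n_folds), function(f) {
      tr <- folds != f; te <- folds == f
      xs <- scale(x[tr, , drop = FALSE])
      ctr <- attr(xs, "scaled:center"); sc <- attr(xs, "scaled:scale")
      sc[sc == 0] <- 1
      xs[, attr(xs, "scaled:scale") == 0] <- 0
      fit <- glmnet::glmnet(xs, y[tr], family = "multinomial", alpha = 0,
                            lambda = c(10, 1, 1e-3), standardize = FALSE)
      xte <- sweep(sweep(x[te, , drop = FALSE], 2, ctr), 2, sc, "/")
      pr <- stats::predict(fit, xte, s = 1e-3, type = "class")
      mean(pr == as.character(y[te]))
    }, numeric(1))
    mean(acc)
  }, numeric(1))
  data.frame(k = as.integer(k_list), score = scores)
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin into n_folds folds.
.stratified_folds <- function(y, n_folds, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed %% .Machine$integer.max))
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    if (length(idx) < n_folds)
      stop("stratified splitting error: class '", cl, "' has ", length(idx),
           " samples for ", n_folds, " folds")
    folds[sample(idx)] <- rep(seq_len(n_folds), length.out = length(idx))
  }
  folds
}
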