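#' @title RBF support vector machine
#' @description A kernel SVM trained with the simplified SMO algorithm,
#'   extended to the 3-class problem one-vs-rest. Per-sample box constraints
#'   are C times the class weight, which is how class weighting enters a
#'   hinge-loss model. The SVM does not emit probabilities natively; decision
#'   values are calibrated per class with a Platt-style logistic fit on the
#'   training fold and normalized across classes.
#' @name svm
NULL

.rbf_kernel <- function(x1, x2, gamma) {
  d2 <- outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * tcrossprod(x1, x2)
  exp(-gamma * pmax(d2, 0))
}

# Simplified SMO for a binary problem; y in {-1, +1}, per-sample C.
.smo_binary <- function(K, y, C, tol = 1e-3, max_passes = 10L, max_iter = 2000L,
                        seed = 1L) {
  n <- length(y)
  a <- rep(0, n)
  b <- 0
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed %% .Machine$integer.max))
  passes <- 0L; iter <- 0L
  while (passes < max_passes && iter < max_iter) {
    changed <- 0L
    for (i in seq_len(n)) {
      ei <- sum(K[, i] * a * y) + b - y[i]
      if ((y[i] * ei < -tol && a[i] < C[i]) || (y[i] * ei > tol && a[i] > 0)) {
        j <- sample.int(n - 1L, 1L)
        if (j >= i) j <- j + 1L
        ej <- sum(K[, j] * a * y) + b - y[j]
        ai_old <- a[i]; aj_old <- a[j]
        if (y[i] != y[j]) {
          L <- max(0, a[j] - a[i]); H <- min(C[j], C[i] + a[j] - a[i])
        } else {
          L <- max(0, a[i] + a[j] - C[i]); H <- min(C[j], a[i] + a[j])
        }
        if (L >= H) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        a[j] <- min(H, max(L, a[j] - y[j] * (ei - ej) / eta))
        if (abs(a[j] - aj_old) < 1e-5) next
        a[i] <- a[i] + y[i] * y[j] * (aj_old - a[j])
        b1 <- b - ei - y[i] * (a[i] - ai_old) * K[i, i] -
          y[j] * (a[j] - aj_old) * K[i, j]
        b2 <- b - ej - y[i] * (a[i] - ai_old) * K[i, j] -
          y[j] * (a[j] - aj_old) * K[j, j]
        b <- if (a[i] > 0 && a[i] < C[i]) b1
             else if (a[j] > 0 && a[j] < C[j]) b2 else (b1 + b2) / 2
        changed <- changed + 1L
      }
    }
    passes <- if (changed == 0L) passes + 1L else 0L
    iter <- iter + 1L
  }
  list(alpha = a, b = b)
}

#' Fit a one-vs-rest RBF SVM
#'
#' @param x numeric matrix (standardized by the caller).
#' @param y factor.
#' @param sample_weights per-sample weights multiplying C.
#' @param C,gamma,tol SVM hyperparameters (reference defaults 1.0 / 1e-4 /
#'   1e-3).
#' @param seed seed for SMO's random second-index choice.
#' @return object of class `voxrad_svm`.
#' @export
svm_fit <- function(x, y, sample_weights = NULL, C = 1.0, gamma = 1e-4,
                    tol = 1e-3, seed = 1L) {
  y <- factor(y)
  n <- nrow(x)
  w <- if (is.null(sample_weights)) rep(1, n) else sample_weights
  K <- .rbf_kernel(x, x, gamma)
  machines <- lapply(levels(y), function(cl) {
    yy <- ifelse(y == cl, 1, -1)
    m <- .smo_binary(K, yy, C * w, tol = tol, seed = seed)
    dec <- as.vector(K %*% (m$alpha * yy)) + m$b
    # Platt-style calibration of the decision values on the training fold
    cal <- suppressWarnings(stats::glm((yy + 1) / 2 ~ dec,
                                       family = stats::binomial()))
    list(class = cl, alpha = m$alpha, b = m$b, yy = yy, cal = stats::coef(cal))
  })
  structure(list(machines = machines, x = x, gamma = gamma, classes = levels(y)),
            class = "voxrad_svm")
}

#' @export
predict.voxrad_svm <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  xte <- as.matrix(newdata)
  K <- .rbf_kernel(xte, object$x, object$gamma)
  dec <- vapply(object$machines, function(m)
    as.vector(K %*% (m$alpha * m$yy)) + m$b, numeric(nrow(xte)))
  dec <- matrix(dec, nrow = nrow(xte))
  praw <- vapply(seq_along(object$machines), function(i) {
    cf <- object$machines[[i]]$cal
    stats::plogis(cf[1] + cf[2] * dec[, i])
  }, numeric(nrow(xte)))
  praw <- matrix(praw, nrow = nrow(xte))
  p <- praw / rowSums(praw)
  colnames(p) <- object$classes
  if (type == "prob") p else object$classes[max.col(p, ties.method = "first")]
}
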