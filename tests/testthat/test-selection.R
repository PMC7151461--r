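test_that("correlation filter drops duplicates and spares independent noise", {
  tab <- planted_feature_table(n = 200, p = 10, n_informative = 0, seed = 3)
  tab$dup <- tab$feat01                       # exact duplicate, r = 1
  res <- correlation_filter(tab, 0.90)
  expect_equal(sum(c("feat01", "dup") %in% res$kept), 1)
  expect_true(all(c("feat05", "feat09") %in% res$kept))   # independent noise
  r <- abs(cor(as.matrix(res$table[, res$kept])))
  diag(r) <- 0
  expect_lt(max(r), 0.90)
  expect_equal(nrow(res$dropped), 1)
  expect_gt(res$dropped$r[1], 0.999)
})

test_that("greedy elimination matches a hand-run oracle on a planted block", {
  set.seed(12)
  n <- 200
  base <- rnorm(n)
  tab <- data.frame(scan_id = 1:n,
                    class = rep(c("control", "prodromal", "pd"), length.out = n))
  tab$a <- base + rnorm(n, 0, 0.05)
  tab$b <- base + rnorm(n, 0, 0.05)
  tab$c <- base + rnorm(n, 0, 0.05)
  for (f in paste0("n", 1:7)) tab[[f]] <- rnorm(n)
  res <- correlation_filter(tab, 0.90)
  # oracle: iteratively drop the member of the worst pair with larger mean |r|
  feats <- setdiff(colnames(tab), c("scan_id", "class"))
  r <- abs(cor(as.matrix(tab[, feats]))); diag(r) <- 0
  while (max(r) > 0.90) {
    ij <- which(r == max(r), arr.ind = TRUE)[1, ]
    pair <- c(rownames(r)[ij[1]], colnames(r)[ij[2]])
    means <- rowMeans(r[pair, , drop = FALSE])
    drop <- pair[which.max(means)]
    keep <- setdiff(rownames(r), drop)
    r <- r[keep, keep]
  }
  expect_setequal(res$kept, rownames(r))
  # two of the three correlated features must have gone
  expect_equal(sum(c("a", "b", "c") %in% res$kept), 1)
})

test_that("filter is idempotent and monotone in the threshold", {
  tab <- planted_feature_table(n = 120, p = 15, n_informative = 3, seed = 8)
  tab$extra <- tab$feat02 * 1.00001 + rnorm(120, 0, 1e-4)
  r1 <- correlation_filter(tab, 0.90)
  r2 <- correlation_filter(r1$table, 0.90)
  expect_equal(nrow(r2$dropped), 0)
  expect_identical(r2$kept, r1$kept)
  survivors <- vapply(c(0.99, 0.9, 0.5, 0.2),
                      function(th) length(correlation_filter(tab, th)$kept),
                      numeric(1))
  expect_true(all(diff(survivors) <= 0))
})

test_that("zero-variance features are retained with a warning", {
  tab <- planted_feature_table(n = 60, p = 6, seed = 2)
  tab$flat <- 1
  expect_warning(res <- correlation_filter(tab), "zero-variance")
  expect_true("flat" %in% res$kept)
})

test_that("RFE keeps k features, ranks them, and is scale invariant", {
  tab <- planted_feature_table(n = 120, p = 12, n_informative = 2, seed = 4)
  all_k <- recursive_feature_elimination(tab, 12)
  expect_length(all_k$kept, 12)
  expect_identical(sort(unname(all_k$ranking)), 1:12)
  sel <- recursive_feature_elimination(tab, 5)
  expect_length(sel$kept, 5)
  expect_error(recursive_feature_elimination(tab, 13), "selection error")
  # per-feature affine rescaling must not change the selection
  tab2 <- tab
  tab2$feat03 <- tab2$feat03 * 1000 + 5
  tab2$feat07 <- tab2$feat07 / 500 - 2
  sel2 <- recursive_feature_elimination(tab2, 5)
  expect_identical(sel2$kept, sel$kept)
})

test_that("RFE recovers planted informative features", {
  hits <- vapply(1:20, function(s) {
    tab <- planted_feature_table(n = 150, p = 20, n_informative = 3,
                                 shift = 2, seed = 400 + s)
    sel <- recursive_feature_elimination(tab, 3)
    all(c("feat01", "feat02", "feat03") %in% sel$kept)
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("selection_sweep scores candidate subset sizes", {
  tab <- planted_feature_table(n = 90, p = 10, n_informative = 3, seed = 6)
  sw <- selection_sweep(tab, k_list = c(5L), seed = 2)
  expect_equal(nrow(sw), 1)
  sw2 <- selection_sweep(tab, k_list = c(3L, 6L), seed = 2)
  expect_equal(sw2$k, c(3L, 6L))
  expect_true(all(sw2$score >= 0 & sw2$score <= 1))
})

test_that("a k=20 subset scores at least as well as k=10 on 20-signal tables", {
  wins <- vapply(1:10, function(s) {
    tab <- planted_feature_table(n = 150, p = 30, n_informative = 20,
                                 shift = 1, seed = 700 + s)
    sw <- selection_sweep(tab, k_list = c(10L, 20L), seed = s)
    sw$score[sw$k == 20] >= sw$score[sw$k == 10]
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})
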