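test_that("phylogenetic covariance matches shared path lengths", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(unname(phylo_cov(tr)), diag(2))

  tr2 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  C <- phylo_cov(tr2)[c("A", "B", "C"), c("A", "B", "C")]
  # brute-force path enumeration: depth of the MRCA of each pair
  expect_equal(unname(C), rbind(c(2, 1, 0), c(1, 2, 0), c(0, 0, 2)))

  # ultrametric tree: constant diagonal
  tru <- simulate_tree(15, seed = 50)
  expect_equal(unname(diag(phylo_cov(tru))), rep(1, 15), tolerance = 1e-10)
})

test_that("the whitening transform inverts the covariance square root", {
  expect_equal(phylo_transform(diag(3)), diag(3))
  expect_equal(phylo_transform(4 * diag(3)), 0.5 * diag(3))
  set.seed(51)
  a <- matrix(rnorm(25), 5)
  C <- crossprod(a) + diag(5)
  P <- phylo_transform(C)
  expect_equal(P %*% C %*% t(P), diag(5), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(phylo_transform(diag(c(1, -1, 2))), "positive definite")
})

test_that("Kmult is calibrated under Brownian motion and detects its absence", {
  tr <- simulate_tree(50, seed = 52)
  set.seed(53)
  ks <- replicate(60, kmult(bm_tips(tr, 20), tr, n_perm = 1, seed = 1)$observed)
  expect_gt(mean(ks), 0.9)
  expect_lt(mean(ks), 1.1)

  # tree-independent data: K well below 1, permutation test non-significant
  tr2 <- simulate_tree(50, seed = 54)
  set.seed(55)
  y <- matrix(rnorm(50 * 20), 50, 20,
              dimnames = list(tr2$tip.label, NULL))
  res <- kmult(y, tr2, n_perm = 999, seed = 56)
  expect_lt(res$observed, 0.75)
  expect_gt(res$p, 0.05)

  # invariance to global branch-length rescaling
  tr3 <- tr2; tr3$edge.length <- 7.3 * tr3$edge.length
  expect_equal(kmult(y, tr2, n_perm = 1, seed = 1)$observed,
               kmult(y, tr3, n_perm = 1, seed = 1)$observed,
               tolerance = 1e-10)

  # univariate K agrees with the standard implementation
  y1 <- bm_tips(tr, 1)
  ref <- unname(phytools::phylosig(tr, y1[, 1], method = "K"))
  expect_equal(kmult(y1, tr, n_perm = 1, seed = 1)$observed, c(ref),
               tolerance = 1e-6)
})

test_that("Procrustes regression recovers exact fits and rejects degenerate input", {
  set.seed(57)
  n <- 40
  x <- rnorm(n)
  beta <- rnorm(9)
  y <- tcrossprod(x, beta)  # pure linear signal, no noise
  fit <- procrustes_lm(y, data.frame(logCS = x), n_perm = 99, seed = 1)
  expect_equal(unname(fit$R2["logCS"]), 1, tolerance = 1e-10)
  expect_lt(fit$SS_residual, 1e-16 * fit$SS_total)

  expect_error(procrustes_lm(matrix(1, 10, 3), data.frame(x = rnorm(10)),
                             n_perm = 9), "zero total variance")
  expect_error(procrustes_lm(matrix(rnorm(30), 10),
                             data.frame(a = rnorm(10), b = rep(1, 10)),
                             n_perm = 9),
               "rank-deficient")

  # sequential SS add up to the total
  y2 <- y + matrix(rnorm(n * 9), n, 9)
  g <- sample(c("a", "b", "c"), n, replace = TRUE)
  fit2 <- procrustes_lm(y2, data.frame(logCS = x, diet = g),
                        n_perm = 49, seed = 2)
  expect_equal(sum(fit2$SS) + fit2$SS_residual, fit2$SS_total,
               tolerance = 1e-8)
  expect_true(all(fit2$R2 >= 0 & fit2$R2 <= 1))
  # term R2 is invariant to the factor's level coding
  g2 <- factor(g, levels = c("c", "a", "b"))
  fit3 <- procrustes_lm(y2, data.frame(logCS = x, diet = g2),
                        n_perm = 49, seed = 2)
  expect_equal(fit2$R2, fit3$R2, tolerance = 1e-10)
})

test_that("PGLS reduces to OLS on star trees and is scale invariant", {
  n <- 30
  st <- star_tree(n)
  set.seed(58)
  y <- matrix(rnorm(n * 8), n, 8, dimnames = list(st$tip.label, NULL))
  preds <- data.frame(logCS = rnorm(n),
                      diet = sample(c("MMR", "mixed", "LMR"), n, TRUE))
  ols <- procrustes_lm(y, preds, n_perm = 199, seed = 3)
  pgls <- procrustes_pgls(y, preds, st, n_perm = 199, seed = 3)
  expect_equal(ols$F, pgls$F, tolerance = 1e-8)
  expect_equal(ols$R2, pgls$R2, tolerance = 1e-8)
  expect_equal(ols$p_perm, pgls$p_perm)

  # scaling C by a constant leaves R2 unchanged
  st2 <- star_tree(n, bl = 5)
  pgls2 <- procrustes_pgls(y, preds, st2, n_perm = 9, seed = 3)
  expect_equal(pgls$R2, pgls2$R2, tolerance = 1e-10)
})

test_that("permutation p-values are seeded, reproducible, and floored at 1/(n+1)", {
  tr <- simulate_tree(25, seed = 60)
  y <- bm_tips(tr, 6)
  a <- kmult(y, tr, n_perm = 99, seed = 7)
  b <- kmult(y, tr, n_perm = 99, seed = 7)
  expect_identical(a$p, b$p)
  expect_identical(a$null_values, b$null_values)
  expect_gte(a$p, 1 / 100)
  preds <- data.frame(x = rnorm(25))
  f1 <- procrustes_pgls(y, preds, tr, n_perm = 99, seed = 8)
  f2 <- procrustes_pgls(y, preds, tr, n_perm = 99, seed = 8)
  expect_identical(f1$p_perm, f2$p_perm)
})

test_that("two-block PLS: duplicated blocks give rPLS 1, independent blocks fail to reject", {
  set.seed(61)
  b1 <- matrix(rnorm(40 * 6), 40, 6)
  dup <- phylo_pls(b1, b1, n_perm = 99, seed = 9)
  expect_equal(dup$rPLS, 1, tolerance = 1e-10)
  expect_true(all(diff(dup$singular_values) <= 1e-12))

  st <- star_tree(100)
  set.seed(62)
  x1 <- matrix(rnorm(100 * 9), 100, 9, dimnames = list(st$tip.label, NULL))
  x2 <- matrix(rnorm(100 * 9), 100, 9, dimnames = list(st$tip.label, NULL))
  indep <- phylo_pls(x1, x2, st, n_perm = 999, seed = 10)
  expect_gt(indep$p_perm, 0.05)
  expect_lt(indep$rPLS, 0.8)

  # rPLS is invariant to rotation of either block's coordinate axes
  r <- qr.Q(qr(matrix(rnorm(81), 9)))
  rot <- phylo_pls(x1 %*% r, x2, st, n_perm = 1, seed = 1)
  expect_equal(rot$rPLS, phylo_pls(x1, x2, st, n_perm = 1, seed = 1)$rPLS,
               tolerance = 1e-8)

  expect_error(phylo_pls(b1[, 1, drop = FALSE], b1), "2 columns")
})
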