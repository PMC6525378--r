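sim_for_decomp <- function(n, fa, fb, seed, size = "tiny", ...) {
  tr <- simulate_tree(n, seed = seed)
  tp <- skull_template(size)
  truth <- synthetic_truth(tr, tp, allometric_fraction = fa,
                           integration_fraction = fb, seed = seed + 1L, ...)
  sim <- simulate_shapes(tr, truth, seed = seed + 2L)
  list(tree = tr, template = tp, sim = sim)
}

test_that("allometric stage: zero for size-free shapes, one for pure allometry", {
  s <- sim_for_decomp(100, 0, 0.3, seed = 70)
  st <- allometric_stage(s$sim$aligned, s$tree, n_perm = 9, seed = 1)
  expect_lt(st$allometric_fraction, 2 / 99)

  # shapes exactly beta * logCS: fraction 1, residual SS ~ 0
  tr <- simulate_tree(40, seed = 71)
  set.seed(72)
  logcs <- rnorm(40)
  y <- tcrossprod(logcs, rnorm(18))
  rownames(y) <- tr$tip.label
  al <- list(flattened = y, centroid_size = setNames(exp(logcs), tr$tip.label))
  st2 <- allometric_stage(al, tr, n_perm = 9, seed = 1)
  expect_equal(st2$allometric_fraction, 1, tolerance = 1e-10)
  expect_lt(sum(st2$non_allometric^2), 1e-16 * st2$fit$SS_total)
})

test_that("integration stage: near zero for independent blocks, full for duplicated", {
  s <- sim_for_decomp(100, 0.3, 0, seed = 73)
  st1 <- allometric_stage(s$sim$aligned, s$tree, n_perm = 9, seed = 1)
  st2 <- integration_stage(st1$non_allometric, s$template$blocks, s$tree,
                           n_perm = 9, seed = 1)
  expect_lt(st2$integration_fraction_non_allometric, 0.12)

  # a rank-1 factor duplicated into both blocks: rPLS 1 and the stage-3
  # R2 approaches the factor's variance share (here ~96% by construction)
  tr <- simulate_tree(60, seed = 74)
  f <- bm_tips(tr, 1)
  set.seed(79)
  w <- rnorm(9); w <- w / sqrt(sum(w^2))
  one_block <- tcrossprod(f[, 1], w) + 0.05 * bm_tips(tr, 9)
  dup <- cbind(one_block, one_block)
  rownames(dup) <- tr$tip.label
  blocks <- list(block1 = 1:3, block2 = 4:6)   # point indices, 3 cols each
  st3 <- integration_stage(dup, blocks, tr, n_perm = 9, seed = 1)
  expect_equal(st3$pls$rPLS, 1, tolerance = 1e-6)
  expect_gt(st3$integration_fraction_non_allometric, 0.8)
})

test_that("injected variance fractions are recovered and fractions are additive", {
  s <- sim_for_decomp(150, 0.3, 0.25, seed = 75)
  dec <- decompose_shape(s$sim$aligned, s$tree, s$template$blocks,
                         diet = setNames(s$sim$metadata$diet,
                                         s$sim$metadata$species),
                         n_perm = 19, seed = 2)
  expect_lt(abs(dec$allometric_fraction - 0.30), 0.08)
  expect_lt(abs(dec$integration_fraction - 0.25), 0.08)
  expect_equal(dec$combined_fraction,
               dec$allometric_fraction + dec$integration_fraction)
  expect_true(all(c(dec$allometric_fraction, dec$integration_fraction) >= 0))
  expect_true(dec$combined_fraction <= 1)

  # no injected structure at all: combined fraction small
  s0 <- sim_for_decomp(150, 0, 0, seed = 76)
  dec0 <- decompose_shape(s0$sim$aligned, s0$tree, s0$template$blocks,
                          n_perm = 9, seed = 3)
  expect_lt(dec0$combined_fraction, 0.1)
})

test_that("NANI residuals are orthogonal to both removed directions in the whitened metric", {
  s <- sim_for_decomp(80, 0.3, 0.25, seed = 77)
  dec <- decompose_shape(s$sim$aligned, s$tree, s$template$blocks,
                         n_perm = 9, seed = 4)
  P <- phylo_transform(phylo_cov(s$tree))
  nani_t <- P %*% dec$nani_shapes
  logcs_t <- P %*% cbind(log(s$sim$aligned$centroid_size[s$tree$tip.label]))
  pred <- stats::fitted(stats::lm(dec$per_stage_fits$pls$block1_scores[, 1] ~
                                    dec$per_stage_fits$pls$block2_scores[, 1]))
  pred_t <- P %*% cbind(pred)
  scale_ref <- sqrt(sum(nani_t^2)) * sqrt(sum(logcs_t^2))
  expect_lt(max(abs(crossprod(logcs_t, nani_t))) / scale_ref, 1e-8)
  scale_ref2 <- sqrt(sum(nani_t^2)) * sqrt(sum(pred_t^2))
  expect_lt(max(abs(crossprod(pred_t, nani_t))) / scale_ref2, 1e-8)
})

test_that("fractions are invariant to global rescaling of the landmark coordinates", {
  s <- sim_for_decomp(60, 0.3, 0.2, seed = 78)
  al <- s$sim$aligned
  al2 <- al
  al2$flattened <- 10 * al$flattened
  d1 <- decompose_shape(al, s$tree, s$template$blocks, n_perm = 9, seed = 5)
  d2 <- decompose_shape(al2, s$tree, s$template$blocks, n_perm = 9, seed = 5)
  expect_equal(d1$allometric_fraction, d2$allometric_fraction,
               tolerance = 1e-10)
  expect_equal(d1$integration_fraction, d2$integration_fraction,
               tolerance = 1e-10)
})

test_that("allometric fraction estimation tightens as the sample grows", {
  err <- vapply(c(50, 200), function(n) {
    reps <- vapply(1:4, function(r) {
      s <- sim_for_decomp(n, 0.3, 0, seed = 1000 * n + r)
      st <- allometric_stage(s$sim$aligned, s$tree, n_perm = 1, seed = 1)
      st$allometric_fraction
    }, numeric(1))
    abs(mean(reps) - 0.3)
  }, numeric(1))
  expect_lt(err[2], err[1] + 0.02)
})
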