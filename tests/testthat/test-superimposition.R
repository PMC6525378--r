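test_that("centroid size matches its defining formula and scales linearly", {
  sq <- cbind(c(0.5, 0.5, -0.5, -0.5), c(0.5, -0.5, 0.5, -0.5), 0)
  expect_equal(centroid_size(sq), sqrt(2))
  cfg <- random_config(60, seed = 3)
  brute <- sqrt(sum(sweep(cfg, 2, colMeans(cfg))^2))
  expect_equal(centroid_size(cfg), brute)
  expect_equal(centroid_size(3.7 * cfg), 3.7 * centroid_size(cfg))
  expect_error(centroid_size(matrix(1, 4, 3)), "degenerate")
})

test_that("GPA removes rigid motion and scale, centers outputs, is order-invariant", {
  cfg <- random_config(15, seed = 4)
  rot <- random_rotation(seed = 5)
  copy <- 2.5 * cfg %*% rot + matrix(c(3, -1, 7), 15, 3, byrow = TRUE)
  arr <- array(c(cfg, copy, cfg), c(15, 3, 3))
  al <- gpa(arr)
  expect_lt(sqrt(sum((al$coords[, , 1] - al$coords[, , 2])^2)), 1e-10)
  for (i in 1:3)
    expect_lt(max(abs(colMeans(al$coords[, , i]))), 1e-10)
  expect_lt(max(abs(colMeans(al$consensus))), 1e-10)
  expect_equal(unname(al$centroid_size[2]),
               2.5 * unname(al$centroid_size[1]))

  # identical configurations: consensus is the centered, scaled config
  arr2 <- array(rep(cfg, 4), c(15, 3, 4))
  al2 <- gpa(arr2)
  cs <- sweep(cfg, 2, colMeans(cfg)); cs <- cs / sqrt(sum(cs^2))
  expect_equal(procrustes_distance(al2$consensus, cs), 0, tolerance = 1e-8)

  # permuting specimen order leaves the consensus unchanged
  set.seed(6)
  lms <- perturbed_set(8, 12, sd = 0.08)
  a <- gpa(lms)
  perm <- c(5, 3, 8, 1, 7, 2, 6, 4)
  b <- gpa(lms$coords[, , perm])
  expect_equal(a$consensus, b$consensus, tolerance = 1e-8)
})

test_that("full Procrustes distance agrees with a grid-refined rotation search", {
  # planar triangles: the optimal proper 3D rotation maps the plane onto
  # itself, i.e. an in-plane angle optionally composed with the in-plane
  # flip that a half-turn about an in-plane axis realises; search both
  # branches over the angle by grid + refine
  brute_pd <- function(a, b) {
    norm2 <- function(x) { x <- sweep(x, 2, colMeans(x)); x / sqrt(sum(x^2)) }
    a <- norm2(a); b <- norm2(b)
    flip <- diag(c(1, -1, -1))   # half-turn about x: in-plane reflection
    f <- function(th, fl) {
      r <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
      if (fl) r <- flip %*% r
      sqrt(sum((a - b %*% r)^2))
    }
    best <- Inf
    for (fl in c(FALSE, TRUE)) {
      opt <- optimize(f, c(0, 2 * pi), fl = fl, tol = 1e-12)
      grid <- min(vapply(seq(0, 2 * pi, length.out = 721), f, numeric(1),
                         fl = fl))
      best <- min(best, opt$objective, grid)
    }
    best
  }
  set.seed(7)
  tris <- replicate(3, cbind(matrix(rnorm(6), 3, 2), 0), simplify = FALSE)
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(procrustes_distance(tris[[i]], tris[[j]]),
                 brute_pd(tris[[i]], tris[[j]]), tolerance = 1e-6)
})

test_that("bending energy vanishes for affine maps and is positive semi-definite", {
  ref <- random_config(12, seed = 8)
  m <- bending_energy_model(ref)
  expect_lt(abs(bending_energy(m, ref)), 1e-9)
  aff <- ref %*% matrix(rnorm(9), 3) + matrix(rnorm(3), 12, 3, byrow = TRUE)
  expect_lt(abs(bending_energy(m, aff)), 1e-9)
  ev <- eigen(m$bending_energy, symmetric = TRUE)$values
  expect_gt(min(ev), -1e-9)
  expect_equal(m$bending_energy, t(m$bending_energy))
  set.seed(9)
  for (i in 1:5)
    expect_gte(bending_energy(m, ref + matrix(rnorm(36, 0, 0.1), 12, 3)),
               -1e-12)
})

test_that("sliding reduces bending energy and is null at the reference", {
  tp <- skull_template("tiny")
  # one slider toy: optimum along the tangent matches a dense grid search
  ref <- tp$coords
  m <- bending_energy_model(ref)
  spec <- ref
  spec[8, ] <- spec[8, ] + c(0.05, 0, 0.08)   # displace one semilandmark
  sliders1 <- tp$sliders[tp$sliders[, "slide"] == 8L, , drop = FALSE]
  tang <- (spec[sliders1[, "after"], , drop = FALSE] -
             spec[sliders1[, "before"], , drop = FALSE])
  tang <- tang / sqrt(sum(tang^2))
  grid <- seq(-0.5, 0.5, length.out = 4001)
  be_at <- vapply(grid, function(t) {
    s <- spec; s[8, ] <- s[8, ] + t * tang
    bending_energy(m, s)
  }, numeric(1))
  slid1 <- craniomorph:::slide_one(spec, m, 8L, tang)
  t_opt <- sum((slid1[8, ] - spec[8, ]) * tang)
  expect_lt(abs(t_opt - grid[which.min(be_at)]), 3e-4)
  expect_lte(bending_energy(m, slid1), min(be_at) + 1e-10)

  # specimen identical to the reference: zero displacement
  tang_all <- craniomorph:::chord_tangents(ref, tp$sliders)
  same <- craniomorph:::slide_one(ref, m, tp$sliders[, "slide"], tang_all)
  expect_equal(same, ref, tolerance = 1e-8)

  # full sliding never increases total bending energy between passes
  tr <- simulate_tree(10, seed = 21)
  truth <- synthetic_truth(tr, tp, 0.3, 0.2, seed = 22, total_scale = 0.04)
  sim <- simulate_shapes(tr, truth, seed = 23)
  slid <- slide_semilandmarks(sim$landmarks, tp$sliders)
  trace <- attr(slid, "bending_energy_trace")
  expect_true(all(trace[, "post_slide"] <= trace[, "pre_slide"] + 1e-10))
})

test_that("symmetric component fixes symmetric shapes and averages mirror pairs", {
  tp <- skull_template("tiny")
  sym <- symmetry_map(tp$pairs, nrow(tp$coords))
  base <- tp$coords  # bilaterally symmetric template
  arr <- array(rep(base, 3), c(nrow(base), 3, 3))
  arr[, , 2] <- arr[, , 2] * 1.3
  lms <- landmark_set(arr)
  sc <- symmetric_component(lms, sym, axis = 2)
  al <- gpa(lms, project_tangent = FALSE)
  # a perfectly symmetric configuration is its own symmetric component
  expect_equal(procrustes_distance(sc$coords[, , 1], al$coords[, , 1]), 0,
               tolerance = 1e-7)

  # swapping left/right roles leaves the symmetric component unchanged
  set.seed(31)
  pert <- arr
  pert[, , 2] <- pert[, , 2] + matrix(rnorm(36, 0, 0.03), 12, 3)
  lp <- landmark_set(pert)
  s1 <- symmetric_component(lp, sym, axis = 2)
  sym_sw <- symmetry_map(tp$pairs[, c(2, 1)], nrow(tp$coords))
  s2 <- symmetric_component(lp, sym_sw, axis = 2)
  expect_equal(s1$flattened, s2$flattened, tolerance = 1e-9)

  # asymmetric perturbation: symmetric component = average of the aligned
  # original and its relabeled mirror (direct construction)
  relabel <- seq_len(12)
  relabel[tp$pairs[, 1]] <- tp$pairs[, 2]
  relabel[tp$pairs[, 2]] <- tp$pairs[, 1]
  x <- pert[, , 2]
  mir <- x; mir[, 2] <- -mir[, 2]; mir <- mir[relabel, ]
  both <- array(c(x, mir), c(12, 3, 2))
  alb <- gpa(both, project_tangent = FALSE)
  hand <- (alb$coords[, , 1] + alb$coords[, , 2]) / 2
  s3 <- symmetric_component(landmark_set(array(c(x, x), c(12, 3, 2))),
                            sym, axis = 2)
  expect_equal(procrustes_distance(s3$coords[, , 1], hand), 0,
               tolerance = 1e-6)
})
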