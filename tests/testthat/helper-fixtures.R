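# Shared builders for small test objects. Everything is generated in code;
# no fixture files ship with the package.

random_config <- function(n_pts, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(n_pts * 3L), n_pts, 3L)
}

random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r <- qr.Q(qr(matrix(rnorm(9L), 3L)))
  if (det(r) < 0) r[, 1L] <- -r[, 1L]
  r
}

# small landmark_set of perturbed copies of one base configuration
perturbed_set <- function(n_spec, n_pts, sd = 0.05, seed = 1) {
  set.seed(seed)
  base <- random_config(n_pts)
  arr <- array(NA_real_, c(n_pts, 3L, n_spec))
  for (i in seq_len(n_spec))
    arr[, , i] <- base + matrix(rnorm(n_pts * 3L, 0, sd), n_pts, 3L)
  landmark_set(arr)
}

two_tip_tree <- function(bl = c(1, 1)) {
  tr <- ape::read.tree(text = sprintf("(A:%g,B:%g);", bl[1], bl[2]))
  tr
}

star_tree <- function(n, bl = 1) {
  tr <- ape::stree(n, "star")
  tr$edge.length <- rep(bl, n)
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

bm_tips <- function(tree, p, sigma = 1) {
  C <- phylo_cov(tree)
  L <- t(chol(C))
  y <- L %*% matrix(rnorm(ape::Ntip(tree) * p), ncol = p) * sigma
  rownames(y) <- tree$tip.label
  y
}

# groups with strongly separated means in q dimensions
separated_groups <- function(sizes, q = 4, gap = 20, seed = 1) {
  set.seed(seed)
  g <- rep(paste0("g", seq_along(sizes)), sizes)
  x <- matrix(rnorm(sum(sizes) * q), ncol = q)
  for (i in seq_along(sizes))
    x[g == paste0("g", i), 1] <- x[g == paste0("g", i), 1] + i * gap
  list(scores = x, groups = g)
}
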