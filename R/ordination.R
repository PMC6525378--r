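#' Principal component analysis of aligned shapes
#'
#' Eigen-decomposition of the covariance of the flattened, mean-centered
#' Procrustes coordinates. Axes are ordered by decreasing eigenvalue; the
#' sign of each axis is fixed so that the specimen with the largest
#' absolute score on it scores positively (eigenvector signs are otherwise
#' arbitrary).
#'
#' @param aligned an `aligned_shapes` object, or a specimen x coordinate
#'   matrix.
#' @param tol eigenvalues below `tol * max(eigenvalue)` are dropped as
#'   null axes.
#' @return object of class `shape_pca`: list with `eigenvalues`,
#'   `percent_variance`, `scores` (specimen x axis), `vectors`
#'   (coordinate x axis, orthonormal columns), and `mean` (flattened
#'   consensus).
#' @export
shape_pca <- function(aligned, tol = 1e-10) {
  x <- if (inherits(aligned, "aligned_shapes")) aligned$flattened else
    as.matrix(aligned)
  if (nrow(x) < 2L) stop("need at least 2 specimens")
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  if (sum(xc^2) <= 0) stop("zero shape variance: all specimens identical")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  keep <- ev > tol * ev[1L]
  ev <- ev[keep]
  scores <- pc$x[, keep, drop = FALSE]
  vectors <- pc$rotation[, keep, drop = FALSE]
  for (j in seq_along(ev)) {
    if (scores[which.max(abs(scores[, j])), j] < 0) {
      scores[, j] <- -scores[, j]
      vectors[, j] <- -vectors[, j]
    }
  }
  colnames(scores) <- colnames(vectors) <- paste0("PC", seq_along(ev))
  structure(list(eigenvalues = ev,
                 percent_variance = 100 * ev / sum(ev),
                 scores = scores, vectors = vectors, mean = mu),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  k <- min(5L, length(x$eigenvalues))
  cat("shape_pca:", nrow(x$scores), "specimens,",
      length(x$eigenvalues), "axes\n")
  cat("  % variance:",
      paste(sprintf("PC%d %.1f", seq_len(k), x$percent_variance[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Maximum-likelihood Brownian ancestral states for multivariate traits
#'
#' Estimates ancestral values at every internal node under multivariate
#' Brownian motion, using the GLS formula: the root equals the
#' phylogenetic (GLS) mean of the tips and each node's estimate is the
#' conditional expectation given the tip data. Equivalent to weighted
#' squared-change parsimony on the rooted tree, applied per coordinate.
#'
#' @param tree an [ape::phylo] rooted tree with branch lengths.
#' @param tip_shapes matrix with one row per tip (rownames matched to tip
#'   labels after name normalization) and one column per trait.
#' @return object of class `ancestral_states`: list with `node_coords`
#'   (internal-node x trait matrix, rows named by node number) and `root`
#'   (the GLS phylogenetic mean).
#' @export
ancestral_states <- function(tree, tip_shapes) {
  tip_shapes <- as.matrix(tip_shapes)
  n <- ape::Ntip(tree)
  if (nrow(tip_shapes) != n) stop("one row per tip required")
  if (!is.null(rownames(tip_shapes)))
    tip_shapes <- tip_shapes[match_names(tree$tip.label,
                                         rownames(tip_shapes),
                                         "tip shapes"), , drop = FALSE]
  el <- tree$edge.length
  if (any(el[tree$edge[, 2L] > n] <= 0)) {
    eps <- 1e-8 * max(el)
    tree$edge.length[tree$edge[, 2L] > n & el <= 0] <- eps
    message("zero-length internal branches padded by ", signif(eps, 3))
  }
  nn <- tree$Nnode
  depths <- ape::node.depth.edgelength(tree)
  mr <- ape::mrca(tree, full = TRUE)
  c_full <- matrix(depths[mr], nrow(mr), ncol(mr))
  tips <- seq_len(n)
  nodes <- n + seq_len(nn)
  c_tt <- c_full[tips, tips]
  c_nt <- c_full[nodes, tips, drop = FALSE]
  invc <- solve(c_tt)
  one <- rep(1, n)
  denom <- drop(crossprod(one, invc %*% one))
  mu <- drop(crossprod(one, invc %*% tip_shapes)) / denom
  dev <- sweep(tip_shapes, 2L, mu)
  node_coords <- c_nt %*% invc %*% dev
  node_coords <- sweep(node_coords, 2L, mu, "+")
  rownames(node_coords) <- nodes
  structure(list(node_coords = node_coords, root = mu), class = "ancestral_states")
}

#' Warp the consensus shape along a PCA axis
#'
#' Returns `mean + score * loading` reshaped to an `n_points x 3`
#' configuration; used to visualise end-member shapes of an axis.
#'
#' @param pca a [shape_pca].
#' @param axis axis index.
#' @param score position along the axis in score units.
#' @return `n_points x 3` matrix.
#' @export
warp_along_axis <- function(pca, axis, score) {
  if (axis < 1L || axis > ncol(pca$vectors)) stop("axis out of range")
  unflatten_shape(pca$mean + score * pca$vectors[, axis])
}

#' Phylomorphospace coordinates (tips, ancestral nodes, branch segments)
#'
#' Projects tip shapes and Brownian ancestral-state estimates onto the
#' same PCA axes (no re-centering of nodes) and returns plotting-ready
#' coordinates: one table of points and one of branch segments.
#'
#' @param pca a [shape_pca] fitted to the tip shapes.
#' @param tree the phylogeny used for [ancestral_states].
#' @param tip_shapes the flattened tip shape matrix the PCA was fitted to.
#' @param axes which axes to project (default first two).
#' @return list of data.frames `points` (label, type, scores) and
#'   `segments` (from/to scores per tree edge).
#' @export
phylomorphospace_coords <- function(pca, tree, tip_shapes,
                                    axes = c(1L, 2L)) {
  anc <- ancestral_states(tree, tip_shapes)
  project <- function(m)
    sweep(as.matrix(m), 2L, pca$mean) %*% pca$vectors[, axes, drop = FALSE]
  tip_sc <- project(tip_shapes[match_names(tree$tip.label,
                                           rownames(tip_shapes),
                                           "tip shapes"), , drop = FALSE])
  node_sc <- project(anc$node_coords)
  all_sc <- rbind(tip_sc, node_sc)
  pts <- data.frame(label = c(tree$tip.label, rownames(anc$node_coords)),
                    type = rep(c("tip", "node"),
                               c(nrow(tip_sc), nrow(node_sc))))
  pts <- cbind(pts, as.data.frame(all_sc))
  seg <- data.frame(parent = tree$edge[, 1L], child = tree$edge[, 2L])
  for (j in seq_along(axes)) {
    seg[[paste0("from_", colnames(tip_sc)[j])]] <- all_sc[seg$parent, j]
    seg[[paste0("to_", colnames(tip_sc)[j])]] <- all_sc[seg$child, j]
  }
  list(points = pts, segments = seg)
}
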