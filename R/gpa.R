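#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of all points from their
#' centroid; the standard size measure in geometric morphometrics.
#'
#' @param config numeric `n_points x k` matrix.
#' @return positive scalar.
#' @export
centroid_size <- function(config) {
  config <- as.matrix(config)
  if (nrow(config) < 2L) stop("need at least 2 points")
  cen <- sweep(config, 2L, colMeans(config))
  cs <- sqrt(sum(cen^2))
  if (cs <= 0) stop("degenerate configuration: all points identical")
  cs
}

center_config <- function(config) sweep(config, 2L, colMeans(config))

# Optimal rotation (no reflection) taking `config` onto `target`:
# returns config %*% R with R in SO(k).
rotate_onto <- function(config, target) {
  s <- svd(crossprod(config, target))
  r <- tcrossprod(s$u, s$v)
  if (det(r) < 0) {
    u <- s$u
    u[, ncol(u)] <- -u[, ncol(u)]
    r <- tcrossprod(u, s$v)
  }
  config %*% r
}

# Rotate the whole aligned sample to a canonical orientation (principal
# axes of the consensus, signs fixed by third moments) so the GPA result
# does not depend on specimen input order.
canonical_orientation <- function(configs, consensus) {
  cen <- center_config(consensus)
  ev <- eigen(crossprod(cen), symmetric = TRUE)$vectors
  p <- cen %*% ev
  sgn <- apply(p, 2L, function(v) {
    s3 <- sum(v^3)
    if (abs(s3) < 1e-12) s3 <- v[which.max(abs(v))]
    if (s3 < 0) -1 else 1
  })
  ev <- sweep(ev, 2L, sgn, "*")
  if (det(ev) < 0) {
    j <- which.min(abs(apply(cen %*% ev, 2L, function(v) sum(v^3))))
    ev[, j] <- -ev[, j]
  }
  list(configs = lapply(configs, function(x) x %*% ev),
       consensus = cen %*% ev)
}

#' Generalized Procrustes analysis
#'
#' Removes translation (centering), size (scaling to unit centroid size)
#' and orientation (optimal rotations, reflections disallowed) from a set
#' of configurations, iterating rotation against the re-estimated mean
#' shape until the consensus stabilises, then projects the aligned shapes
#' orthogonally into the tangent space at the consensus.
#'
#' @param shapes a [landmark_set], or an `n_points x 3 x n` array.
#' @param tol convergence tolerance on the root-mean-square change of the
#'   consensus between iterations.
#' @param max_iter maximum number of alignment iterations.
#' @param project_tangent project aligned shapes into the tangent space at
#'   the consensus (default `TRUE`).
#' @return an object of class `aligned_shapes`: list with `coords`
#'   (`n_points x 3 x n` Procrustes coordinates), `centroid_size` (original
#'   units), `consensus` (`n_points x 3`), and `flattened`
#'   (`n x 3 n_points` matrix, coordinates interleaved x1 y1 z1 x2 ...).
#' @export
gpa <- function(shapes, tol = 1e-10, max_iter = 200L,
                project_tangent = TRUE) {
  coords <- if (inherits(shapes, "landmark_set")) shapes$coords else shapes
  ids <- if (inherits(shapes, "landmark_set")) shapes$specimen_ids else
    dimnames(coords)[[3]]
  n <- dim(coords)[3]
  if (is.null(n) || n < 2L) stop("need at least 2 specimens")
  if (is.null(ids)) ids <- paste0("spec", seq_len(n))
  cs <- numeric(n)
  configs <- vector("list", n)
  for (i in seq_len(n)) {
    x <- center_config(coords[, , i])
    cs[i] <- centroid_size(coords[, , i])
    configs[[i]] <- x / cs[i]
  }
  consensus <- configs[[1L]]
  for (it in seq_len(max_iter)) {
    configs <- lapply(configs, rotate_onto, target = consensus)
    new_cons <- Reduce(`+`, configs) / n
    new_cons <- center_config(new_cons)
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    delta <- sqrt(mean((new_cons - consensus)^2))
    consensus <- new_cons
    if (delta < tol) break
  }
  if (it == max_iter && delta >= tol)
    stop(sprintf("GPA failed to converge in %d iterations (last change %.3e)",
                 max_iter, delta))
  can <- canonical_orientation(configs, consensus)
  configs <- can$configs
  consensus <- can$consensus
  if (project_tangent) {
    cvec <- as.numeric(t(consensus))
    configs <- lapply(configs, function(x) {
      v <- as.numeric(t(x)) - cvec
      v <- v - sum(v * cvec) * cvec
      matrix(cvec + v, ncol = 3L, byrow = TRUE)
    })
  }
  out_coords <- array(unlist(lapply(configs, t)),
                      dim = c(3L, nrow(consensus), n))
  out_coords <- aperm(out_coords, c(2L, 1L, 3L))
  dimnames(out_coords) <- list(NULL, c("x", "y", "z"), ids)
  flat <- t(apply(out_coords, 3L, function(m) as.numeric(t(m))))
  rownames(flat) <- ids
  structure(list(coords = out_coords, centroid_size = stats::setNames(cs, ids),
                 consensus = consensus, flattened = flat,
                 iterations = it),
            class = "aligned_shapes")
}

#' @export
print.aligned_shapes <- function(x, ...) {
  cat(sprintf("aligned_shapes: %d specimens x %d points (GPA, %d iterations)\n",
              dim(x$coords)[3], dim(x$coords)[1], x$iterations))
  invisible(x)
}

#' Flatten a configuration array to a specimen x coordinate matrix
#' @param coords `n_points x 3 x n` array or `aligned_shapes`.
#' @return `n x 3*n_points` matrix (x1 y1 z1 x2 y2 z2 ...).
#' @export
flatten_shapes <- function(coords) {
  if (inherits(coords, "aligned_shapes")) return(coords$flattened)
  t(apply(coords, 3L, function(m) as.numeric(t(m))))
}

#' Restore a flattened shape vector to an `n_points x 3` configuration
#' @param v numeric vector of length `3*n_points`.
#' @return `n_points x 3` matrix.
#' @export
unflatten_shape <- function(v) matrix(v, ncol = 3L, byrow = TRUE)

#' Full Procrustes distance between two configurations
#'
#' Both configurations are centered and scaled to unit centroid size, the
#' second is optimally rotated onto the first (no reflection), and the
#' root-summed-squared coordinate difference is returned.
#'
#' @param a,b `n_points x k` matrices.
#' @return non-negative scalar.
#' @export
procrustes_distance <- function(a, b) {
  a <- center_config(as.matrix(a)); a <- a / sqrt(sum(a^2))
  b <- center_config(as.matrix(b)); b <- b / sqrt(sum(b^2))
  b <- rotate_onto(b, a)
  sqrt(sum((a - b)^2))
}
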