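#' Thin-plate-spline bending-energy model of a reference configuration
#'
#' Builds the TPS kernel and bending-energy matrix of a reference
#' configuration. For 3D configurations the radial kernel is
#' `U(r) = -r` (the biharmonic Green's function up to a constant); the
#' bending-energy matrix is the upper-left `n x n` block of the inverse of
#' the bordered system `[[K, Q], [Q', 0]]` with `Q = [1, X]`. Any affine
#' displacement field has zero bending energy, and the matrix is symmetric
#' positive semi-definite on the non-affine complement.
#'
#' @param reference `n_points x 3` matrix.
#' @param ridge small diagonal stabiliser added to `K` if the bordered
#'   system is numerically singular (collinear references).
#' @return list with `reference`, `kernel_matrix` (`n x n`) and
#'   `bending_energy` (`n x n` matrix).
#' @export
bending_energy_model <- function(reference, ridge = 1e-10) {
  x <- as.matrix(reference)
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  k <- -d
  q <- cbind(1, x)
  l <- rbind(cbind(k, q), cbind(t(q), matrix(0, ncol(q), ncol(q))))
  li <- tryCatch(solve(l), error = function(e) {
    solve(l + diag(c(rep(ridge, n), rep(0, ncol(q))), nrow(l)))
  })
  be <- li[seq_len(n), seq_len(n), drop = FALSE]
  be <- (be + t(be)) / 2
  list(reference = x, kernel_matrix = k, bending_energy = be)
}

#' Bending energy of a target configuration relative to a reference
#'
#' Sum over coordinate axes of the quadratic form of the target
#' coordinates in the reference's bending-energy matrix. Zero for the
#' reference itself and for any affine transform of it.
#'
#' @param model a [bending_energy_model].
#' @param target `n_points x 3` matrix.
#' @return non-negative scalar (up to numerical tolerance).
#' @export
bending_energy <- function(model, target) {
  y <- as.matrix(target)
  sum(vapply(seq_len(ncol(y)),
             function(j) drop(crossprod(y[, j], model$bending_energy %*% y[, j])),
             numeric(1)))
}

# Minimise bending energy of one specimen against the reference over the
# tangent displacements of its semilandmarks. `tangents` is m x 3 (unit
# chord directions), `slide_idx` the m point indices being slid.
slide_one <- function(config, model, slide_idx, tangents, ridge = 1e-10) {
  be <- model$bending_energy
  m <- length(slide_idx)
  # A[j,l] = sum_d u_jd u_ld Be[s_j, s_l];  b[j] = -sum_d u_jd (Be y_d)[s_j]
  be_ss <- be[slide_idx, slide_idx, drop = FALSE]
  a <- (tangents %*% t(tangents)) * be_ss
  bey <- be %*% config                      # n x 3
  b <- -rowSums(tangents * bey[slide_idx, , drop = FALSE])
  t_hat <- tryCatch(solve(a, b), error = function(e)
    solve(a + diag(ridge, m), b))
  out <- config
  out[slide_idx, ] <- out[slide_idx, ] + t_hat * tangents
  out
}

chord_tangents <- function(config, sliders) {
  diff <- config[sliders[, "after"], , drop = FALSE] -
    config[sliders[, "before"], , drop = FALSE]
  len <- sqrt(rowSums(diff^2))
  if (any(len <= 0)) stop("slider neighbours coincide; tangent undefined")
  diff / len
}

#' Slide semilandmarks to minimise thin-plate-spline bending energy
#'
#' Iterates: estimate the Procrustes consensus, build its bending-energy
#' matrix, displace each specimen's semilandmarks along the chord between
#' their curve neighbours so as to minimise that specimen's bending energy
#' against the consensus, re-superimpose, and repeat. Stops after
#' `max_pass` passes or when the consensus change drops below `tol`.
#'
#' @param shapes a [landmark_set].
#' @param sliders a [slider_definition].
#' @param max_pass maximum slide/superimpose passes.
#' @param tol consensus-change convergence tolerance.
#' @return a [landmark_set] with slid coordinates (same scale/orientation
#'   handling as the input: coordinates are returned aligned and unit-size
#'   from the internal GPA, with original centroid sizes recorded in
#'   attribute `centroid_size`), plus attribute `bending_energy_trace`, a
#'   per-pass matrix of total bending energy against that pass's reference
#'   before and after sliding (the slide solves the minimum exactly, so
#'   `post_slide <= pre_slide` in every pass).
#' @export
slide_semilandmarks <- function(shapes, sliders, max_pass = 5L, tol = 1e-6) {
  stopifnot(inherits(shapes, "landmark_set"))
  sliders <- slider_definition(sliders, roles = shapes$point_roles,
                               n_points = n_points(shapes))
  al <- gpa(shapes, project_tangent = FALSE)
  configs <- lapply(seq_len(n_specimens(shapes)),
                    function(i) al$coords[, , i])
  consensus <- al$consensus
  slide_idx <- sliders[, "slide"]
  trace_pre <- trace_post <- numeric(0)
  for (pass in seq_len(max_pass)) {
    model <- bending_energy_model(consensus)
    trace_pre <- c(trace_pre,
                   sum(vapply(configs, bending_energy, numeric(1),
                              model = model)))
    configs <- lapply(configs, function(x) {
      tang <- chord_tangents(x, sliders)
      slide_one(x, model, slide_idx, tang)
    })
    trace_post <- c(trace_post,
                    sum(vapply(configs, bending_energy, numeric(1),
                               model = model)))
    arr <- array(unlist(lapply(configs, t)),
                 dim = c(3L, nrow(consensus), length(configs)))
    arr <- aperm(arr, c(2L, 1L, 3L))
    al <- gpa(arr, project_tangent = FALSE)
    configs <- lapply(seq_along(configs), function(i) al$coords[, , i])
    delta <- sqrt(mean((al$consensus - consensus)^2))
    consensus <- al$consensus
    if (delta < tol) break
  }
  arr <- array(unlist(lapply(configs, t)),
               dim = c(3L, nrow(consensus), length(configs)))
  arr <- aperm(arr, c(2L, 1L, 3L))
  dimnames(arr) <- list(NULL, c("x", "y", "z"), shapes$specimen_ids)
  out <- landmark_set(arr, shapes$specimen_ids, shapes$point_roles,
                      shapes$curve_membership)
  attr(out, "centroid_size") <- al$centroid_size * 0 +
    vapply(seq_len(n_specimens(shapes)),
           function(i) centroid_size(shapes$coords[, , i]), numeric(1))
  attr(out, "bending_energy_trace") <-
    cbind(pre_slide = trace_pre, post_slide = trace_post)
  out
}
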