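#' Symmetric component of shape variation (object symmetry)
#'
#' For object-symmetric configurations each specimen is duplicated as a
#' mirror image (one coordinate axis reflected, paired left/right point
#' labels swapped), originals and mirrored copies are jointly
#' superimposed, and the symmetric shape of a specimen is the average of
#' its aligned original and its aligned mirror. The asymmetric component
#' is discarded; centroid sizes are those of the original configurations.
#'
#' @param shapes a [landmark_set] (raw or slid coordinates).
#' @param sym a [symmetry_map] covering every point.
#' @param axis reflection axis (1, 2 or 3); by default the axis of
#'   smallest variance of the midline landmarks in a preliminary
#'   Procrustes consensus. If the midline variances do not single out an
#'   axis a warning is issued and the configured/default axis is used.
#' @param centroid_sizes optional per-specimen centroid sizes to record;
#'   defaults to the attribute left by [slide_semilandmarks] or, failing
#'   that, sizes computed from `shapes`.
#' @return an `aligned_shapes` object of the symmetric shapes.
#' @export
symmetric_component <- function(shapes, sym, axis = NULL,
                                centroid_sizes = NULL) {
  stopifnot(inherits(shapes, "landmark_set"), inherits(sym, "symmetry_map"))
  npts <- n_points(shapes)
  if (sym$n_points != npts)
    stop("symmetry map covers ", sym$n_points, " points, data have ", npts)
  n <- n_specimens(shapes)
  if (is.null(centroid_sizes)) {
    centroid_sizes <- attr(shapes, "centroid_size")
    if (is.null(centroid_sizes))
      centroid_sizes <- vapply(seq_len(n), function(i)
        centroid_size(shapes$coords[, , i]), numeric(1))
  }

  pre <- gpa(shapes, project_tangent = FALSE)
  if (is.null(axis)) {
    if (length(sym$midline) >= 2L) {
      v <- apply(pre$consensus[sym$midline, , drop = FALSE], 2L, stats::var)
      axis <- which.min(v)
      if (sort(v)[2] < 2 * sort(v)[1])
        warning("reflection axis ambiguous from midline landmarks; using axis ",
                axis)
    } else {
      warning("no midline landmarks to detect a reflection plane; using axis 2")
      axis <- 2L
    }
  }

  relabel <- seq_len(npts)
  relabel[sym$pairs[, 1L]] <- sym$pairs[, 2L]
  relabel[sym$pairs[, 2L]] <- sym$pairs[, 1L]

  both <- array(NA_real_, dim = c(npts, 3L, 2L * n))
  for (i in seq_len(n)) {
    x <- shapes$coords[, , i]
    m <- x
    m[, axis] <- -m[, axis]
    m <- m[relabel, , drop = FALSE]
    both[, , i] <- x
    both[, , n + i] <- m
  }
  ids2 <- c(shapes$specimen_ids, paste0(shapes$specimen_ids, "__mirror"))
  dimnames(both) <- list(NULL, c("x", "y", "z"), ids2)
  al <- gpa(both, project_tangent = FALSE)

  symc <- array(NA_real_, dim = c(npts, 3L, n))
  for (i in seq_len(n))
    symc[, , i] <- (al$coords[, , i] + al$coords[, , n + i]) / 2
  dimnames(symc) <- list(NULL, c("x", "y", "z"), shapes$specimen_ids)
  consensus <- apply(symc, c(1L, 2L), mean)
  flat <- t(apply(symc, 3L, function(m) as.numeric(t(m))))
  rownames(flat) <- shapes$specimen_ids
  structure(list(coords = symc,
                 centroid_size = stats::setNames(centroid_sizes,
                                                 shapes$specimen_ids),
                 consensus = consensus, flattened = flat,
                 iterations = al$iterations, axis = axis),
            class = "aligned_shapes")
}
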