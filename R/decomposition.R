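#' Allometric stage: phylogenetic regression of shape on log centroid size
#'
#' Fits a PGLS of the flattened aligned shapes on log centroid size. The
#' term R-squared (in the phylogenetically whitened metric) is the
#' evolutionary-allometry fraction; the residuals, back on the original
#' coordinate scale, are the non-allometric shapes carried to the
#' integration stage.
#'
#' @param aligned an `aligned_shapes` object (must carry centroid sizes),
#'   or a list with elements `flattened` and `centroid_size`.
#' @param tree rooted [ape::phylo] tree matched to specimens.
#' @param n_perm,seed RRPP permutation settings.
#' @return list with `fit` (the `procrustes_fit`), `allometric_fraction`,
#'   and `non_allometric` (residual shape matrix, original scale).
#' @export
allometric_stage <- function(aligned, tree, n_perm = 999L, seed = NULL) {
  y <- aligned$flattened
  cs <- aligned$centroid_size
  if (is.null(cs)) stop("centroid sizes unavailable")
  ord <- match_names(tree$tip.label, rownames(y), "shape rows for tree tips")
  y <- y[ord, , drop = FALSE]
  cs <- cs[ord]
  fit <- procrustes_pgls(y, data.frame(logCS = log(cs)), tree,
                         n_perm = n_perm, seed = seed)
  non_allo <- fit$residuals
  rownames(non_allo) <- rownames(y)
  list(fit = fit,
       allometric_fraction = unname(fit$R2["logCS"]),
       non_allometric = non_allo)
}

#' Integration stage: beak-braincase covariation of non-allometric shape
#'
#' Quantifies how much of the shape variation is attributable to
#' integration between the two landmark blocks once allometry has been
#' removed. The procedure: (1) two-block phylogenetic PLS of the
#' non-allometric shapes split into the two blocks; (2) ordinary
#' regression of the first-dimension block-1 scores on the block-2
#' scores, whose fitted values are the prediction scores; (3) PGLS of the
#' non-allometric shape matrix on those prediction scores. The residuals
#' of (3) are the non-allometric, non-integrated (NANI) shapes.
#'
#' @param non_allometric residual shape matrix from [allometric_stage].
#' @param blocks list with integer vectors `block1` and `block2` giving
#'   disjoint point indices (1-based landmark numbers) of the two modules
#'   (e.g. beak and braincase). Column indices into the flattened matrix
#'   are derived from these.
#' @param tree rooted [ape::phylo] tree.
#' @param ss_total_reference total sum of squares (whitened metric) used
#'   as the denominator of `integration_fraction`. Pass the `SS_total` of
#'   the allometric-stage fit to express the fraction relative to the
#'   original shape variance (additive convention); default `NULL` uses
#'   the non-allometric variance itself.
#' @param n_perm,seed permutation settings.
#' @return list with `pls` (`phylo_pls`), `fit` (stage-3
#'   `procrustes_fit`), `integration_fraction`,
#'   `integration_fraction_non_allometric` (relative to the
#'   non-allometric variance, for audit), `prediction_scores`, and `nani`
#'   (residual shape matrix).
#' @export
integration_stage <- function(non_allometric, blocks, tree,
                              ss_total_reference = NULL,
                              n_perm = 999L, seed = NULL) {
  y <- as.matrix(non_allometric)
  cols <- block_columns(blocks, ncol(y))
  pls <- phylo_pls(y[, cols$block1, drop = FALSE],
                   y[, cols$block2, drop = FALSE],
                   tree, n_perm = n_perm, seed = seed)
  s1 <- pls$block1_scores[, 1L]
  s2 <- pls$block2_scores[, 1L]
  pred <- stats::fitted(stats::lm(s1 ~ s2))
  fit <- procrustes_pgls(y, data.frame(integration = pred), tree,
                         n_perm = n_perm, seed = seed)
  nani <- fit$residuals
  rownames(nani) <- rownames(y)
  frac_na <- unname(fit$R2["integration"])
  frac <- if (is.null(ss_total_reference)) frac_na else
    unname(fit$SS["integration"]) / ss_total_reference
  list(pls = pls, fit = fit,
       integration_fraction = frac,
       integration_fraction_non_allometric = frac_na,
       prediction_scores = pred, nani = nani)
}

# Convert 1-based landmark indices of two disjoint blocks into flattened
# column indices (x,y,z per point).
block_columns <- function(blocks, n_cols) {
  if (!all(c("block1", "block2") %in% names(blocks)))
    stop("blocks must name 'block1' and 'block2'")
  b1 <- as.integer(blocks$block1); b2 <- as.integer(blocks$block2)
  if (length(intersect(b1, b2))) stop("blocks overlap")
  to_cols <- function(idx) as.integer(t(outer(3L * (idx - 1L), 1:3, `+`)))
  c1 <- to_cols(b1); c2 <- to_cols(b2)
  if (max(c(c1, c2)) > n_cols) stop("block indices out of range")
  list(block1 = c1, block2 = c2)
}

#' Partition shape variance into allometry, integration and the remainder
#'
#' Runs the full decomposition cascade: PGLS of shape on log centroid
#' size (evolutionary allometry), two-block phylogenetic PLS of the
#' residuals plus a prediction-score PGLS (integration), then phylogenetic
#' signal (Kmult) of the non-allometric non-integrated (NANI) residuals
#' and a PGLS of NANI shape on diet. By default both fractions are
#' expressed relative to the total variance of the original aligned
#' shapes (whitened metric) so that they are additive; set
#' `fraction_basis = "stagewise"` to express the integration fraction
#' relative to the non-allometric variance instead.
#'
#' @inheritParams allometric_stage
#' @param blocks two-module landmark split, see [integration_stage].
#' @param diet optional per-specimen diet factor (names or order matching
#'   specimens) for the NANI diet test.
#' @param fraction_basis `"total"` (additive, default) or `"stagewise"`.
#' @param n_perm,seed permutation settings; the seed governs every
#'   permutation test in the cascade.
#' @return object of class `shape_decomposition`: fractions
#'   (`allometric_fraction`, `integration_fraction`, `combined_fraction`),
#'   `nani_shapes`, `residual_kmult`, `diet_fit` (or `NULL`), and
#'   `per_stage_fits` with the full audit trail.
#' @export
decompose_shape <- function(aligned, tree, blocks, diet = NULL,
                            fraction_basis = c("total", "stagewise"),
                            n_perm = 999L, seed = NULL) {
  fraction_basis <- match.arg(fraction_basis)
  stage1 <- allometric_stage(aligned, tree, n_perm = n_perm, seed = seed)
  ref <- if (fraction_basis == "total") stage1$fit$SS_total else NULL
  stage2 <- integration_stage(stage1$non_allometric, blocks, tree,
                              ss_total_reference = ref,
                              n_perm = n_perm, seed = seed)
  allo <- stage1$allometric_fraction
  integ <- stage2$integration_fraction
  res_k <- kmult(stage2$nani, tree, n_perm = n_perm, seed = seed)
  diet_fit <- NULL
  if (!is.null(diet)) {
    d <- diet
    if (!is.null(names(d)))
      d <- d[match_names(rownames(stage2$nani), names(d), "diet labels")]
    diet_fit <- procrustes_pgls(stage2$nani, data.frame(diet = d), tree,
                                n_perm = n_perm, seed = seed)
  }
  structure(list(allometric_fraction = allo,
                 integration_fraction = integ,
                 combined_fraction = allo + integ,
                 fraction_basis = fraction_basis,
                 nani_shapes = stage2$nani,
                 residual_kmult = res_k,
                 diet_fit = diet_fit,
                 per_stage_fits = list(allometric = stage1$fit,
                                       pls = stage2$pls,
                                       integration = stage2$fit)),
            class = "shape_decomposition")
}

#' @export
print.shape_decomposition <- function(x, ...) {
  cat("shape variance decomposition (basis:", x$fraction_basis, ")\n")
  cat(sprintf("  allometry:    %5.1f%%\n", 100 * x$allometric_fraction))
  cat(sprintf("  integration:  %5.1f%%\n", 100 * x$integration_fraction))
  cat(sprintf("  combined:     %5.1f%%\n", 100 * x$combined_fraction))
  cat(sprintf("  residual Kmult: %.3f (p = %.4g)\n",
              x$residual_kmult$observed, x$residual_kmult$p))
  if (!is.null(x$diet_fit))
    cat(sprintf("  NANI ~ diet: R2 = %.4f, p = %.4g\n",
                x$diet_fit$R2["diet"], x$diet_fit$p_perm["diet"]))
  invisible(x)
}
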