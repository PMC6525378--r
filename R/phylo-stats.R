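#' Brownian phylogenetic covariance matrix of a rooted tree
#'
#' `C[i, j]` is the shared root-to-MRCA path length of tips i and j;
#' `C[i, i]` the root-to-tip distance. This is the expected trait
#' covariance under Brownian motion with unit rate.
#'
#' @param tree an [ape::phylo] tree with branch lengths. A basal
#'   polytomy (including star trees) is treated as simultaneous
#'   divergence from the root.
#' @return tip x tip covariance matrix, rows/columns in `tree$tip.label`
#'   order.
#' @export
phylo_cov <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  ape::vcv.phylo(tree)
}

#' Inverse-square-root (whitening) transform of a covariance matrix
#'
#' Returns the symmetric matrix `P` with `P %*% C %*% t(P) = I`, via
#' eigen-decomposition. Applying `P` to data and design converts a GLS
#' problem with covariance `C` into ordinary least squares.
#'
#' @param C symmetric positive-definite matrix.
#' @return the whitening matrix `P`.
#' @export
phylo_transform <- function(C) {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  if (min(e$values) <= 0)
    stop("covariance not positive definite (smallest eigenvalue ",
         signif(min(e$values), 4), ")")
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

# Reorder a matrix of per-tip rows into tree tip order (hard error on
# missing tips).
align_to_tree <- function(x, tree) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) {
    if (nrow(x) != ape::Ntip(tree))
      stop("rows do not match tree tips and carry no names")
    return(x)
  }
  x[match_names(tree$tip.label, rownames(x), "data rows for tree tips"),
    , drop = FALSE]
}

gls_mean <- function(y, invC) {
  one <- rep(1, nrow(y))
  drop(crossprod(one, invC %*% y)) / drop(crossprod(one, invC %*% one))
}

#' Multivariate phylogenetic signal (Kmult)
#'
#' The multivariate generalisation of Blomberg's K: the ratio of the mean
#' squared Euclidean deviation of tips from the phylogenetic (GLS) mean to
#' the phylogenetically corrected mean squared deviation, divided by its
#' expectation under Brownian motion,
#' `(tr(C) - n / (1' C^-1 1)) / (n - 1)`. K is about 1 for data evolved by
#' Brownian motion on the tree, below 1 when relatives resemble each other
#' less than Brownian motion predicts. Significance is assessed by
#' permuting tip identities.
#'
#' @param shapes tip x trait matrix (rownames matched to tip labels).
#' @param tree rooted [ape::phylo] tree.
#' @param n_perm number of permutations (observed arrangement counted in
#'   the denominator as the +1).
#' @param seed integer seed for the permutations.
#' @return object of class `perm_test`: list with `observed` (K),
#'   `null_values`, `p`, `n_perm`, `seed`.
#' @export
kmult <- function(shapes, tree, n_perm = 999L, seed = NULL) {
  y <- align_to_tree(shapes, tree)
  n <- nrow(y)
  if (n < 3L) stop("need at least 3 tips")
  C <- phylo_cov(tree)
  invC <- solve(C)
  expect <- (sum(diag(C)) - n / sum(invC)) / (n - 1)
  k_stat <- function(y) {
    a <- gls_mean(y, invC)
    dev <- sweep(y, 2L, a)
    num <- sum(dev^2)
    den <- sum(dev * (invC %*% dev))
    (num / den) / expect
  }
  obs <- k_stat(y)
  restore_rng <- local_seed(seed)
  on.exit(restore_rng(), add = TRUE)
  nulls <- vapply(seq_len(n_perm),
                  function(i) k_stat(y[sample(n), , drop = FALSE]),
                  numeric(1))
  new_perm_test(obs, nulls, seed, statistic = "Kmult")
}

new_perm_test <- function(observed, null_values, seed, statistic = "stat") {
  p <- (sum(null_values >= observed) + 1) / (length(null_values) + 1)
  structure(list(observed = observed, null_values = null_values, p = p,
                 n_perm = length(null_values), seed = seed,
                 statistic = statistic),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("%s = %.4f, p = %.4g (%d permutations)\n",
              x$statistic, x$observed, x$p, x$n_perm))
  invisible(x)
}

# Expand a predictor data.frame into ordered design-term blocks.
# Factors use treatment contrasts with the alphabetically first level as
# reference.
build_design <- function(predictors, n) {
  if (is.null(predictors) || ncol(as.data.frame(predictors)) == 0L)
    stop("no predictors supplied")
  predictors <- as.data.frame(predictors)
  if (nrow(predictors) != n) stop("predictor rows must match specimens")
  terms <- names(predictors)
  blocks <- vector("list", length(terms))
  for (i in seq_along(terms)) {
    v <- predictors[[i]]
    if (is.character(v)) v <- factor(v, levels = sort(unique(v)))
    if (is.factor(v)) {
      v <- droplevels(v)
      mm <- stats::model.matrix(~v)[, -1L, drop = FALSE]
      colnames(mm) <- paste0(terms[i], levels(v)[-1L])
      blocks[[i]] <- mm
    } else {
      blocks[[i]] <- matrix(as.numeric(v), ncol = 1L,
                            dimnames = list(NULL, terms[i]))
    }
  }
  names(blocks) <- terms
  x_full <- cbind(`(Intercept)` = 1, do.call(cbind, blocks))
  if (qr(x_full)$rank < ncol(x_full)) {
    drop_rank <- vapply(seq_along(blocks), function(i) {
      qr(x_full[, setdiff(colnames(x_full), colnames(blocks[[i]])),
                drop = FALSE])$rank == qr(x_full)$rank
    }, logical(1))
    stop("rank-deficient design; aliased term(s): ",
         paste(terms[drop_rank], collapse = ", "))
  }
  list(terms = terms, blocks = blocks, x_full = x_full)
}

# Shared engine for Procrustes OLS / PGLS regression with sequential
# (type I) sums of squares and residual-randomization permutation (RRPP):
# for each term the residuals of the reduced model (all earlier terms) are
# permuted across specimens, added back to the reduced fitted values, and
# the term's F recomputed.
rrpp_engine <- function(y, design, n_perm, seed, P = NULL) {
  n <- nrow(y)
  yt <- if (is.null(P)) y else P %*% y
  one_t <- if (is.null(P)) matrix(1, n, 1) else P %*% matrix(1, n, 1)
  xt_blocks <- lapply(design$blocks, function(b) if (is.null(P)) b else P %*% b)
  k <- length(design$terms)
  # cumulative designs: 0 = intercept only, i = intercept + terms 1..i
  x_cum <- vector("list", k + 1L)
  x_cum[[1L]] <- one_t
  for (i in seq_len(k)) x_cum[[i + 1L]] <- cbind(x_cum[[i]], xt_blocks[[i]])
  qr_cum <- lapply(x_cum, qr)
  rss <- function(q, y) sum(qr.resid(q, y)^2)
  rss_cum <- vapply(qr_cum, rss, numeric(1), y = yt)
  ss_total <- rss_cum[1L]
  if (ss_total <= 1e-12 * max(sum(yt^2), 1e-300))
    stop("zero total variance in the response")
  ss_terms <- rss_cum[seq_len(k)] - rss_cum[-1L]
  df_terms <- vapply(design$blocks, ncol, integer(1))
  df_res <- n - ncol(x_cum[[k + 1L]])
  ms_res <- rss_cum[k + 1L] / df_res
  f_obs <- (ss_terms / df_terms) / ms_res
  r2 <- ss_terms / ss_total

  restore_rng <- local_seed(seed)
  on.exit(restore_rng(), add = TRUE)
  f_null <- matrix(NA_real_, n_perm, k)
  perms <- lapply(seq_len(n_perm), function(i) sample.int(n))
  for (i in seq_len(k)) {
    fit_red <- qr.fitted(qr_cum[[i]], yt)
    res_red <- yt - fit_red
    for (b in seq_len(n_perm)) {
      ystar <- fit_red + res_red[perms[[b]], , drop = FALSE]
      rss_red <- rss(qr_cum[[i]], ystar)
      rss_fullterm <- rss(qr_cum[[i + 1L]], ystar)
      rss_full <- rss(qr_cum[[k + 1L]], ystar)
      f_null[b, i] <- ((rss_red - rss_fullterm) / df_terms[i]) /
        (rss_full / df_res)
    }
  }
  p_perm <- (colSums(sweep(f_null, 2L, f_obs, `>=`)) + 1) / (n_perm + 1)
  z <- (f_obs - colMeans(f_null)) / apply(f_null, 2L, stats::sd)

  beta <- qr.coef(qr_cum[[k + 1L]], yt)
  x_orig <- design$x_full
  fitted_orig <- x_orig %*% beta
  resid_orig <- y - fitted_orig
  structure(list(terms = design$terms, df = df_terms,
                 SS = stats::setNames(ss_terms, design$terms),
                 F = stats::setNames(f_obs, design$terms),
                 R2 = stats::setNames(r2, design$terms),
                 p_perm = stats::setNames(p_perm, design$terms),
                 Z = stats::setNames(z, design$terms),
                 SS_total = ss_total, SS_residual = rss_cum[k + 1L],
                 df_residual = df_res, coefficients = beta,
                 fitted = fitted_orig, residuals = resid_orig,
                 residuals_transformed = yt - x_cum[[k + 1L]] %*% beta,
                 n_perm = n_perm, seed = seed),
            class = "procrustes_fit")
}

#' @export
print.procrustes_fit <- function(x, ...) {
  tab <- data.frame(term = x$terms, df = x$df, SS = x$SS, F = x$F,
                    R2 = x$R2, Z = x$Z, p = x$p_perm)
  cat("Procrustes regression (sequential SS, RRPP with",
      x$n_perm, "permutations)\n")
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Procrustes linear regression of shape with permutation tests
#'
#' Ordinary multivariate regression of a flattened shape matrix on one or
#' more predictors, with sequential (type I) sums of squares in the trace
#' form and significance by residual randomization (RRPP): for each term,
#' residuals of the reduced model containing all earlier terms are
#' permuted across specimens and the term's F recomputed.
#'
#' @param shapes `aligned_shapes` or specimen x coordinate matrix.
#' @param predictors data.frame of predictors in the order they enter the
#'   model (numeric columns as-is; character/factor columns expanded with
#'   treatment contrasts, alphabetical reference level).
#' @param n_perm number of RRPP permutations.
#' @param seed integer seed for reproducible permutations.
#' @return a `procrustes_fit`: per-term df, SS, F, R-squared (term SS over
#'   total SS), permutation p, effect size Z, plus coefficients, fitted
#'   values and residuals (original scale).
#' @export
procrustes_lm <- function(shapes, predictors, n_perm = 999L, seed = NULL) {
  y <- if (inherits(shapes, "aligned_shapes")) shapes$flattened else
    as.matrix(shapes)
  design <- build_design(predictors, nrow(y))
  rrpp_engine(y, design, n_perm = n_perm, seed = seed, P = NULL)
}

#' Procrustes phylogenetic generalized least squares regression
#'
#' Identical to [procrustes_lm] after whitening the response and the
#' design (including the intercept column) by the inverse square root of
#' the Brownian phylogenetic covariance of the tree; permutations act on
#' transformed-scale residuals. On a star phylogeny with equal tip branch
#' lengths this reduces exactly to the ordinary regression.
#'
#' @inheritParams procrustes_lm
#' @param tree rooted [ape::phylo] tree; tips matched to the rownames of
#'   the shape matrix.
#' @return a `procrustes_fit` (see [procrustes_lm]); `residuals` are on
#'   the original (untransformed) scale.
#' @export
procrustes_pgls <- function(shapes, predictors, tree, n_perm = 999L,
                            seed = NULL) {
  y <- if (inherits(shapes, "aligned_shapes")) shapes$flattened else
    as.matrix(shapes)
  predictors <- as.data.frame(predictors)
  if (!is.null(rownames(y))) {
    ord <- match_names(tree$tip.label, rownames(y), "shape rows for tree tips")
    y <- y[ord, , drop = FALSE]
    predictors <- predictors[ord, , drop = FALSE]
  } else if (nrow(y) != ape::Ntip(tree))
    stop("shape rows do not match tree tips")
  design <- build_design(predictors, nrow(y))
  P <- phylo_transform(phylo_cov(tree))
  rrpp_engine(y, design, n_perm = n_perm, seed = seed, P = P)
}

#' Two-block (phylogenetic) partial least squares of shape blocks
#'
#' Measures integration between two landmark blocks of one aligned
#' configuration. Both blocks are centered on the phylogenetic GLS mean
#' and whitened by the phylogenetic transform; the singular value
#' decomposition of their evolutionary cross-covariance yields paired
#' axes. Scores are the centered (untransformed) block data projected on
#' those axes, and `rPLS` is the Pearson correlation of the paired
#' first-dimension scores. Significance is assessed by permuting the tip
#' rows of block 2. With `tree = NULL` the ordinary (non-phylogenetic)
#' two-block PLS is computed.
#'
#' @param block1,block2 specimen x coordinate matrices (disjoint column
#'   subsets of one aligned shape matrix).
#' @param tree rooted [ape::phylo] tree or `NULL`.
#' @param n_perm permutations for the rPLS test.
#' @param seed integer seed.
#' @return object of class `phylo_pls`: `singular_values`,
#'   `block1_scores`, `block2_scores` (all dimensions), `left_vectors`,
#'   `right_vectors`, `rPLS`, `p_perm`, `null_values`.
#' @export
phylo_pls <- function(block1, block2, tree = NULL, n_perm = 999L,
                      seed = NULL) {
  y1 <- as.matrix(block1); y2 <- as.matrix(block2)
  if (ncol(y1) < 2L || ncol(y2) < 2L)
    stop("each block needs at least 2 columns")
  if (nrow(y1) != nrow(y2)) stop("blocks must have the same specimens")
  n <- nrow(y1)
  if (!is.null(tree)) {
    y1 <- align_to_tree(y1, tree)
    y2 <- align_to_tree(y2, tree)
    C <- phylo_cov(tree)
    invC <- solve(C)
    P <- phylo_transform(C)
  } else {
    invC <- diag(n)
    P <- diag(n)
  }
  pls_stat <- function(y1, y2, full = FALSE) {
    a1 <- gls_mean(y1, invC); a2 <- gls_mean(y2, invC)
    y1c <- sweep(y1, 2L, a1); y2c <- sweep(y2, 2L, a2)
    s12 <- crossprod(P %*% y1c, P %*% y2c) / (n - 1)
    sv <- svd(s12)
    s1 <- y1c %*% sv$u
    s2 <- y2c %*% sv$v
    r <- stats::cor(s1[, 1L], s2[, 1L])
    if (!full) return(r)
    list(r = r, d = sv$d, u = sv$u, v = sv$v, s1 = s1, s2 = s2)
  }
  obs <- pls_stat(y1, y2, full = TRUE)
  if (is.na(obs$r)) stop("rPLS undefined (constant PLS scores)")
  restore_rng <- local_seed(seed)
  on.exit(restore_rng(), add = TRUE)
  nulls <- vapply(seq_len(n_perm),
                  function(i) pls_stat(y1, y2[sample(n), , drop = FALSE]),
                  numeric(1))
  p <- (sum(nulls >= obs$r) + 1) / (n_perm + 1)
  structure(list(singular_values = obs$d,
                 block1_scores = obs$s1, block2_scores = obs$s2,
                 left_vectors = obs$u, right_vectors = obs$v,
                 rPLS = obs$r, p_perm = p, null_values = nulls,
                 n_perm = n_perm, seed = seed),
            class = "phylo_pls")
}

#' @export
print.phylo_pls <- function(x, ...) {
  cat(sprintf("two-block PLS: rPLS = %.4f, p = %.4g (%d permutations)\n",
              x$rPLS, x$p_perm, x$n_perm))
  invisible(x)
}
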