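#' One-way PERMANOVA on Euclidean distances
#'
#' Partitions the total squared Euclidean distance among specimens into
#' between- and within-group components and tests the pseudo-F by
#' permuting group labels. On a Euclidean embedding (such as PC scores)
#' this equals the classical multivariate one-way decomposition, so the
#' sums of squares are computed directly from group centroids.
#'
#' @param scores specimen x axis numeric matrix (e.g. PC scores).
#' @param groups group labels, one per specimen; every group needs at
#'   least 2 members.
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @return list with `pseudo_F`, `R2` (between-group SS over total SS),
#'   `p`, `df`, `n_perm`, `seed`.
#' @export
permanova <- function(scores, groups, n_perm = 999L, seed = NULL) {
  x <- as.matrix(scores)
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  sizes <- table(g)
  if (any(sizes < 2L))
    stop("group(s) with fewer than 2 members: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  n <- nrow(x)
  stat <- function(g) {
    grand <- colMeans(x)
    ss_total <- sum(sweep(x, 2L, grand)^2)
    ss_within <- 0
    for (lev in levels(g)) {
      xi <- x[g == lev, , drop = FALSE]
      ss_within <- ss_within + sum(sweep(xi, 2L, colMeans(xi))^2)
    }
    ss_between <- ss_total - ss_within
    f <- (ss_between / (nlevels(g) - 1)) / (ss_within / (n - nlevels(g)))
    c(f = f, r2 = ss_between / ss_total)
  }
  obs <- stat(g)
  restore_rng <- local_seed(seed)
  on.exit(restore_rng(), add = TRUE)
  nulls <- vapply(seq_len(n_perm), function(i) stat(g[sample(n)])["f"],
                  numeric(1))
  p <- (sum(nulls >= obs["f"]) + 1) / (n_perm + 1)
  list(pseudo_F = unname(obs["f"]), R2 = unname(obs["r2"]), p = p,
       df = c(between = nlevels(g) - 1L, within = n - nlevels(g)),
       n_perm = n_perm, seed = seed)
}

#' Pairwise PERMANOVA with multiplicity correction
#'
#' Runs [permanova] on every unordered pair of groups and adjusts the
#' p-values across pairs (Bonferroni by default, Holm available). At the
#' permutation floor `1/(n_perm + 1)` Bonferroni gives adjusted floors of
#' `3/(n_perm + 1)` for three groups and `6/(n_perm + 1)` for four.
#'
#' @inheritParams permanova
#' @param correction `"bonferroni"` (default) or `"holm"`.
#' @return data.frame of class `pairwise_permanova` with columns
#'   `group_a`, `group_b`, `pseudo_F`, `R2`, `p_raw`, `p_adjusted`,
#'   `n_perm`.
#' @export
pairwise_permanova <- function(scores, groups, n_perm = 999L, seed = NULL,
                               correction = c("bonferroni", "holm")) {
  correction <- match.arg(correction)
  g <- factor(groups)
  levs <- levels(g)
  if (length(levs) < 2L) stop("need at least 2 groups")
  pairs <- utils::combn(levs, 2L)
  rows <- vector("list", ncol(pairs))
  x <- as.matrix(scores)
  for (i in seq_len(ncol(pairs))) {
    keep <- g %in% pairs[, i]
    res <- permanova(x[keep, , drop = FALSE], droplevels(g[keep]),
                     n_perm = n_perm, seed = seed)
    rows[[i]] <- data.frame(group_a = pairs[1L, i], group_b = pairs[2L, i],
                            pseudo_F = res$pseudo_F, R2 = res$R2,
                            p_raw = res$p, n_perm = n_perm)
  }
  tab <- do.call(rbind, rows)
  tab$p_adjusted <- pmin(1, stats::p.adjust(tab$p_raw, method = correction))
  tab <- tab[, c("group_a", "group_b", "pseudo_F", "R2", "p_raw",
                 "p_adjusted", "n_perm")]
  class(tab) <- c("pairwise_permanova", "data.frame")
  tab
}

#' Re-run pairwise PERMANOVA with one group of specimens excluded
#'
#' Drops every specimen belonging to `exclude` under `exclude_by` (which
#' may be a different grouping than the one tested, e.g. drop one clade
#' and re-test diet) and reruns [pairwise_permanova] on the remainder.
#'
#' @inheritParams pairwise_permanova
#' @param exclude label of the group to drop.
#' @param exclude_by grouping vector the exclusion refers to; defaults to
#'   `groups`.
#' @return a `pairwise_permanova` table for the remaining specimens.
#' @export
subset_rerun <- function(scores, groups, exclude, exclude_by = NULL,
                         n_perm = 999L, seed = NULL,
                         correction = "bonferroni") {
  if (is.null(exclude_by)) exclude_by <- groups
  if (!exclude %in% exclude_by)
    stop("group to exclude not present: ", exclude)
  keep <- exclude_by != exclude
  g <- factor(groups[keep])
  g <- droplevels(g)
  if (nlevels(g) < 2L || any(table(g) < 2L))
    stop("exclusion leaves too few specimens in some remaining group")
  pairwise_permanova(as.matrix(scores)[keep, , drop = FALSE], g,
                     n_perm = n_perm, seed = seed, correction = correction)
}
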