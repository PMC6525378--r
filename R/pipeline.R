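#' Read a pipeline configuration file
#'
#' The configuration is a flat JSON object with input paths (relative to
#' the config file's directory unless absolute), landmark counts, and
#' analysis settings (`n_perm`, `seed`, `fraction_basis`, `min_group`).
#' [make_fixture] writes a valid configuration for every fixture.
#'
#' @param path JSON config file.
#' @return named list with absolute paths and validated settings.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  for (key in c("landmarks", "tree", "sliders", "pairs", "metadata",
                "blocks")) {
    if (is.null(cfg[[key]])) stop("config missing '", key, "'")
    p <- cfg[[key]]
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
    if (!file.exists(p)) stop("config path does not exist: ", p)
    cfg[[key]] <- p
  }
  cfg$n_perm <- as.integer(cfg$n_perm %||% 999L)
  if (cfg$n_perm < 99L) stop("n_perm must be >= 99")
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$fraction_basis <- cfg$fraction_basis %||% "total"
  cfg$min_group <- as.integer(cfg$min_group %||% 3L)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full shape-decomposition pipeline
#'
#' Executes every stage in order: read and validate inputs; slide
#' semilandmarks against the consensus by minimum bending energy; extract
#' the symmetric component of shape; PCA and phylomorphospace; Kmult;
#' ordinary and phylogenetic Procrustes regressions of
#' shape ~ logCS + diet; two-block phylogenetic PLS of the full shapes;
#' the allometry/integration/NANI decomposition; and pairwise PERMANOVA
#' of the PC scores by clade and by diet (clades smaller than `min_group`
#' are excluded from the pairwise clade tests). Writes a JSON summary and
#' per-stage CSV matrices under `out_dir` and returns the summary.
#'
#' @param config path to a config file, or the list from
#'   [read_pipeline_config].
#' @param out_dir output directory (created); `NULL` skips file output.
#' @return the summary list, invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else config
  stage <- "data_io"
  res <- tryCatch({
    lms <- read_landmarks(cfg$landmarks, cfg$n_fixed, cfg$n_semi)
    sliders <- read_sliders(cfg$sliders, roles = lms$point_roles,
                            n_points = n_points(lms))
    sym <- read_landmark_pairs(cfg$pairs, n_points(lms))
    meta <- read_metadata(cfg$metadata)
    blocks <- jsonlite::read_json(cfg$blocks, simplifyVector = TRUE)
    ord <- match_names(lms$specimen_ids, meta$species, "metadata species")
    meta <- meta[ord, ]
    tree <- read_tree(cfg$tree, lms$specimen_ids)

    stage <- "superimposition"
    slid <- slide_semilandmarks(lms, sliders)
    aligned <- symmetric_component(slid, sym)

    stage <- "ordination"
    pca <- shape_pca(aligned)
    pms <- phylomorphospace_coords(pca, tree, aligned$flattened)

    stage <- "phylo_stats"
    k_sym <- kmult(aligned$flattened, tree, cfg$n_perm, cfg$seed)
    preds <- data.frame(logCS = log(aligned$centroid_size),
                        diet = meta$diet)
    fit_ols <- procrustes_lm(aligned, preds, cfg$n_perm, cfg$seed)
    fit_pgls <- procrustes_pgls(aligned, preds, tree, cfg$n_perm, cfg$seed)
    cols <- block_columns(blocks, ncol(aligned$flattened))
    y <- aligned$flattened[match_names(tree$tip.label,
                                       rownames(aligned$flattened),
                                       "aligned rows"), , drop = FALSE]
    pls_full <- phylo_pls(y[, cols$block1], y[, cols$block2], tree,
                          cfg$n_perm, cfg$seed)

    stage <- "decomposition"
    diet <- stats::setNames(meta$diet, meta$species)
    dec <- decompose_shape(aligned, tree, blocks, diet = diet,
                           fraction_basis = cfg$fraction_basis,
                           n_perm = cfg$n_perm, seed = cfg$seed)

    stage <- "group_tests"
    clade <- meta$clade
    big <- names(which(table(clade) >= cfg$min_group))
    keep <- clade %in% big
    clade_tab <- if (length(big) >= 2L)
      pairwise_permanova(pca$scores[keep, , drop = FALSE], clade[keep],
                         cfg$n_perm, cfg$seed) else NULL
    diet_tab <- if (length(unique(meta$diet)) >= 2L &&
                    all(table(meta$diet) >= 2L))
      pairwise_permanova(pca$scores, meta$diet, cfg$n_perm, cfg$seed)
      else NULL

    summary <- list(
      package_version = as.character(utils::packageVersion("craniomorph")),
      n_specimens = n_specimens(lms), n_points = n_points(lms),
      n_perm = cfg$n_perm, seed = cfg$seed,
      fraction_basis = cfg$fraction_basis,
      pca_percent_variance = unname(pca$percent_variance[
        seq_len(min(5L, length(pca$percent_variance)))]),
      kmult_symmetric = list(K = k_sym$observed, p = k_sym$p),
      lm = list(terms = fit_ols$terms, F = unname(fit_ols$F),
                R2 = unname(fit_ols$R2), p = unname(fit_ols$p_perm)),
      pgls = list(terms = fit_pgls$terms, F = unname(fit_pgls$F),
                  R2 = unname(fit_pgls$R2), p = unname(fit_pgls$p_perm)),
      pls_full = list(rPLS = pls_full$rPLS, p = pls_full$p_perm),
      decomposition = list(
        allometric_fraction = dec$allometric_fraction,
        integration_fraction = dec$integration_fraction,
        combined_fraction = dec$combined_fraction,
        rPLS_non_allometric = dec$per_stage_fits$pls$rPLS,
        rPLS_non_allometric_p = dec$per_stage_fits$pls$p_perm,
        nani_kmult = dec$residual_kmult$observed,
        nani_kmult_p = dec$residual_kmult$p,
        nani_diet_R2 = if (!is.null(dec$diet_fit))
          unname(dec$diet_fit$R2["diet"]) else NULL,
        nani_diet_p = if (!is.null(dec$diet_fit))
          unname(dec$diet_fit$p_perm["diet"]) else NULL),
      permanova_clade = if (!is.null(clade_tab))
        as.list(clade_tab) else NULL,
      permanova_diet = if (!is.null(diet_tab))
        as.list(diet_tab) else NULL)

    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      utils::write.csv(data.frame(specimen = rownames(pca$scores),
                                  pca$scores),
                       file.path(out_dir, "pc_scores.csv"),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(aligned$flattened),
                       file.path(out_dir, "aligned_shapes.csv"))
      utils::write.csv(as.data.frame(dec$nani_shapes),
                       file.path(out_dir, "nani_shapes.csv"))
      utils::write.csv(pms$points,
                       file.path(out_dir, "phylomorphospace_points.csv"),
                       row.names = FALSE)
      utils::write.csv(pms$segments,
                       file.path(out_dir, "phylomorphospace_segments.csv"),
                       row.names = FALSE)
    }
    summary
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (is.null(out_dir)) res else invisible(res)
}
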