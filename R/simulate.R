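#' Simulate an ultrametric pure-birth tree scaled to unit depth
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer seed (reproducible topologies and branch lengths).
#' @return an [ape::phylo] tree with root-to-tip depth exactly 1 and tip
#'   labels `t1..tn`.
#' @export
simulate_tree <- function(n_tips, seed = NULL) {
  if (n_tips < 2L) stop("need at least 2 tips")
  restore_rng <- local_seed(seed)
  on.exit(restore_rng(), add = TRUE)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree)[seq_len(n_tips)])
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- paste0("t", seq_len(n_tips))
  tree
}

#' Skull-like landmark template for synthetic data
#'
#' A bilaterally symmetric 3D configuration with fixed landmarks,
#' open semilandmark curves flanked by fixed landmarks, slider triples,
#' left/right symmetry pairs, and a beak/braincase block split. Two sizes:
#' `"tiny"` (12 points: 6 fixed + one 6-point midline curve) and `"full"`
#' (60 points: 20 fixed + four 10-point curves, two midline profile
#' curves and one bilateral curve pair), mimicking the statistical layout
#' of an avian skull digitisation without any attempt at anatomical
#' realism. The bilateral axis is y.
#'
#' @param size `"tiny"` or `"full"`.
#' @return list with `coords` (n_points x 3), `point_roles`,
#'   `curve_membership`, `sliders` (before/slide/after matrix), `pairs`
#'   (left/right matrix), and `blocks` (point-index lists `block1` = beak,
#'   `block2` = braincase).
#' @export
skull_template <- function(size = c("tiny", "full")) {
  size <- match.arg(size)
  arc <- function(from, to, k, bulge = 0.25) {
    # open arc between two 3D points, bulging along +z, interior only
    tt <- seq(0, 1, length.out = k + 2L)[-c(1L, k + 2L)]
    base <- outer(1 - tt, from) + outer(tt, to)
    base[, 3L] <- base[, 3L] + bulge * sin(pi * tt)
    base
  }
  if (size == "tiny") {
    tip <- c(1.2, 0, 0); rear <- c(-1, 0, 0.2)
    fixed <- rbind(tip, rear,
                   c(0.7, 0.35, -0.1), c(0.7, -0.35, -0.1),
                   c(-0.4, 0.45, 0.1), c(-0.4, -0.45, 0.1))
    semis <- arc(tip, rear, 6L, bulge = 0.4)
    coords <- rbind(fixed, semis)
    roles <- rep(c("fixed", "semilandmark"), c(6L, 6L))
    curve <- c(rep(NA_integer_, 6L), rep(1L, 6L))
    sliders <- cbind(before = c(1L, 7:11), slide = 7:12,
                     after = c(8:12, 2L))
    pairs <- cbind(left = c(3L, 5L), right = c(4L, 6L))
    blocks <- list(block1 = c(1L, 3L, 4L, 7:9),
                   block2 = c(2L, 5L, 6L, 10:12))
  } else {
    # 8 midline fixed + 6 bilateral fixed pairs = 20 fixed
    tip <- c(1.6, 0, 0.05)
    hinge <- c(0.55, 0, 0.45)
    vault <- c(-0.35, 0, 0.6)
    occ_top <- c(-1.05, 0, 0.35)
    occ_bot <- c(-1.1, 0, -0.15)
    palate <- c(0.15, 0, -0.3)
    beak_ventral <- c(1.15, 0, -0.25)
    naris <- c(1.0, 0, 0.3)
    midline_fixed <- rbind(tip, hinge, vault, occ_top, occ_bot, palate,
                           beak_ventral, naris)
    pair_pos <- rbind(c(1.05, 0.3, -0.05),   # lateral beak
                      c(0.75, 0.4, 0.1),     # beak base
                      c(0.1, 0.55, -0.1),    # jugal
                      c(-0.2, 0.5, 0.3),     # postorbital
                      c(-0.7, 0.45, -0.05),  # quadrate region
                      c(-0.8, 0.4, 0.3))     # braincase side
    paired <- do.call(rbind, lapply(seq_len(nrow(pair_pos)), function(i) {
      p <- pair_pos[i, ]
      rbind(p, p * c(1, -1, 1))
    }))
    fixed <- rbind(midline_fixed, paired)           # points 1..20
    c1 <- arc(tip, hinge, 10L, bulge = 0.18)        # dorsal beak profile
    c2 <- arc(hinge, occ_top, 10L, bulge = 0.22)    # braincase profile
    toml <- arc(tip, c(1.05, 0.3, -0.05), 10L, bulge = -0.08)
    toml[, 2L] <- seq(0.03, 0.27, length.out = 10L) # left tomial edge
    tomr <- toml * rep(c(1, -1, 1), each = 10L)     # right tomial edge
    coords <- rbind(fixed, c1, c2, toml, tomr)
    roles <- rep(c("fixed", "semilandmark"), c(20L, 40L))
    curve <- c(rep(NA_integer_, 20L), rep(1:4, each = 10L))
    chain <- function(first, last, idx)
      cbind(before = c(first, idx[-length(idx)]), slide = idx,
            after = c(idx[-1L], last))
    sliders <- rbind(chain(1L, 2L, 21:30),    # c1: tip -> hinge
                     chain(2L, 4L, 31:40),    # c2: hinge -> occiput top
                     chain(1L, 9L, 41:50),    # left tomial: tip -> lat beak L
                     chain(1L, 10L, 51:60))   # right tomial
    pairs <- cbind(left = c(9L, 11L, 13L, 15L, 17L, 19L, 41:50),
                   right = c(10L, 12L, 14L, 16L, 18L, 20L, 51:60))
    blocks <- list(block1 = c(1L, 7L, 8L, 9L, 10L, 11L, 12L, 21:30, 41:60),
                   block2 = c(2L, 3L, 4L, 5L, 6L, 13:20, 31:40))
  }
  rownames(coords) <- NULL
  list(coords = coords, point_roles = roles, curve_membership = curve,
       sliders = sliders, pairs = pairs, blocks = blocks)
}

# whitened, GLS-centered sum-of-squares weight of a trait covariance:
# tr(M' C^-1 M Sigma) with M the GLS-mean centering operator.
gls_ss_weight <- function(invC, Sigma) {
  n <- nrow(invC)
  w <- invC %*% rep(1, n) / sum(invC)
  m <- diag(n) - tcrossprod(rep(1, n), w)
  sum(diag(crossprod(m, invC %*% m %*% Sigma)))
}

#' Ground-truth parameters for the shape generator
#'
#' Calibrates component scales so that the allometric and integration
#' components carry prescribed expected variance fractions. Fractions are
#' defined in the phylogenetically whitened, GLS-centered metric -- the
#' metric in which the PGLS stages of [decompose_shape] measure their
#' R-squared -- so recovery of the injected fractions is a well-posed
#' check. The allometric direction, latent-factor loadings and diet
#' offsets are drawn as mutually orthogonal unit directions and scaled.
#'
#' @param tree the phylogeny the shapes will be simulated on.
#' @param template a [skull_template] (defines point count and blocks).
#' @param allometric_fraction,integration_fraction target expected
#'   fractions (each in `[0, 1)`, summing to `< 1`).
#' @param diet_scale scale of per-diet mean shape offsets (same per-
#'   coordinate units as `total_scale`; 0 disables diet structure).
#' @param sigma_noise independent per-coordinate noise SD (0 disables).
#' @param size_jitter SD of the non-phylogenetic component of the
#'   standardized size trait (the phylogenetic component has SD 1 at unit
#'   tree depth).
#' @param logcs_mean,logcs_sd location/scale mapping the standardized size
#'   trait to log centroid size.
#' @param total_scale per-coordinate SD of the Brownian shape background;
#'   sets the small-variation regime relative to the template.
#' @param symmetric_effects project the injected effect directions onto
#'   the bilaterally symmetric subspace of the template so that the
#'   symmetric component of shape retains them.
#' @param seed integer seed for the effect directions.
#' @return object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(tree, template,
                            allometric_fraction = 0.30,
                            integration_fraction = 0.25,
                            diet_scale = 0, sigma_noise = 0,
                            size_jitter = 0.05,
                            logcs_mean = 0, logcs_sd = 0.5,
                            total_scale = 0.02,
                            symmetric_effects = TRUE,
                            seed = NULL) {
  fa <- allometric_fraction; fb <- integration_fraction
  if (fa < 0 || fb < 0 || fa + fb >= 1)
    stop("fractions must be non-negative and sum to < 1")
  npts <- nrow(template$coords)
  p <- 3L * npts
  n <- ape::Ntip(tree)
  C <- phylo_cov(tree)
  invC <- solve(C)
  q_bm <- gls_ss_weight(invC, C)
  q_s <- gls_ss_weight(invC, C + size_jitter^2 * diag(n))
  q_e <- gls_ss_weight(invC, diag(n))

  restore_rng <- local_seed(seed)
  on.exit(restore_rng(), add = TRUE)
  mirror <- mirror_operator(template)
  rand_dir <- function() {
    v <- stats::rnorm(p)
    if (symmetric_effects) v <- (v + mirror(v)) / 2
    v / sqrt(sum(v^2))
  }
  orthogonalize <- function(v, basis) {
    for (b in basis) v <- v - sum(v * b) * b
    v / sqrt(sum(v^2))
  }
  beta_dir <- rand_dir()
  load_dir <- latent_direction(template, rand_dir, beta_dir)
  diet_dirs <- list()
  basis <- list(beta_dir, load_dir)
  for (i in 1:2) {
    d <- orthogonalize(rand_dir(), basis)
    diet_dirs[[i]] <- d
    basis <- c(basis, list(d))
  }

  # solve scales: base (BM + noise + diet) fixed, then a, b for targets
  diet_probs <- c(MMR = 0.424, mixed = 0.235, LMR = 0.341)
  if (total_scale > 0) {
    base <- p * q_bm + p * (sigma_noise / total_scale)^2 * q_e
    # diet contributes to the residual share; its exact whitened SS depends
    # on the realized assignment and is recorded post-hoc, approximated
    # here by its raw scale for the expectation bookkeeping
    base <- base + 2 * (diet_scale / total_scale)^2 * q_e
    r <- 1 - fa - fb
    total <- base / r
    a2 <- fa * total / q_s
    b2 <- fb * total / q_bm
  } else {
    if (sigma_noise > 0 || diet_scale > 0 || fa > 0 || fb > 0)
      stop("total_scale = 0 requires all other component scales to be 0")
    r <- 1; a2 <- 0; b2 <- 0
  }

  structure(list(
    beta_size = total_scale * sqrt(a2) * beta_dir,
    latent_loadings = total_scale * sqrt(b2) * load_dir,
    diet_effects = build_diet_effects(diet_scale, diet_dirs),
    diet_probs = diet_probs,
    sigma_bm = total_scale, sigma_noise = sigma_noise,
    size_jitter = size_jitter,
    logcs_mean = logcs_mean, logcs_sd = logcs_sd,
    expected_fractions = c(allometric = fa, integration = fb,
                           residual = r),
    template = template, seed = seed), class = "synthetic_truth")
}

# latent integration direction: a symmetric-subspace direction with equal
# energy in both blocks, orthogonal to the allometric direction
latent_direction <- function(template, rand_dir, beta_dir) {
  cols <- block_columns(template$blocks, 3L * nrow(template$coords))
  v <- rand_dir()
  v <- v - sum(v * beta_dir) * beta_dir
  v1 <- v; v1[-cols$block1] <- 0
  v2 <- v; v2[-cols$block2] <- 0
  v1 <- v1 / sqrt(sum(v1^2)); v2 <- v2 / sqrt(sum(v2^2))
  out <- (v1 + v2) / sqrt(2)
  out / sqrt(sum(out^2))
}

build_diet_effects <- function(diet_scale, diet_dirs) {
  if (diet_scale <= 0)
    return(NULL)
  # three offsets with zero mean spanned by two orthogonal directions
  d1 <- diet_dirs[[1]]; d2 <- diet_dirs[[2]]
  list(MMR = diet_scale * d1,
       mixed = diet_scale * (-0.5 * d1 + sqrt(3) / 2 * d2),
       LMR = diet_scale * (-0.5 * d1 - sqrt(3) / 2 * d2))
}

# mirror a flattened shape vector: swap paired point rows, negate y
mirror_operator <- function(template) {
  npts <- nrow(template$coords)
  relabel <- seq_len(npts)
  relabel[template$pairs[, 1L]] <- template$pairs[, 2L]
  relabel[template$pairs[, 2L]] <- template$pairs[, 1L]
  function(v) {
    m <- unflatten_shape(v)
    m[, 2L] <- -m[, 2L]
    as.numeric(t(m[relabel, , drop = FALSE]))
  }
}

bm_draws <- function(chol_lower, n_traits, sigma = 1) {
  n <- nrow(chol_lower)
  chol_lower %*% matrix(stats::rnorm(n * n_traits), n, n_traits) * sigma
}

#' Simulate tip shapes with known allometric / integration structure
#'
#' Tip shape deviations are the sum of (i) per-coordinate Brownian motion
#' on the tree, (ii) an allometric shape vector scaled by a standardized
#' size trait (itself Brownian plus independent jitter), (iii) a shared
#' latent factor (Brownian on the tree, so integration survives
#' phylogenetic correction) loading on both landmark blocks, (iv)
#' optional per-diet mean offsets, and (v) optional independent noise.
#' Deviations are added to the template and each configuration is scaled
#' by its centroid size (`exp(logCS)`); optional random rigid motions make
#' the raw landmark data exercise the full superimposition machinery.
#'
#' @param tree phylogeny from [simulate_tree] (or any rooted ultrametric
#'   tree).
#' @param truth a [synthetic_truth].
#' @param seed integer seed for the trait draws.
#' @param rigid_motion apply a random rotation and translation to each
#'   raw configuration (default `TRUE`).
#' @return list with `landmarks` (a [landmark_set] of raw configurations),
#'   `shapes` (n x 3*n_points matrix of tangent-scale shape deviations
#'   about the template, rownames = tips), `aligned` (an `aligned_shapes`-
#'   like object built directly from `shapes` for decomposition tests),
#'   `metadata` (species/clade/diet data.frame), `logCS`, and `truth`
#'   (with realized variance fractions appended).
#' @export
simulate_shapes <- function(tree, truth, seed = NULL, rigid_motion = TRUE) {
  stopifnot(inherits(truth, "synthetic_truth"))
  restore_rng <- local_seed(seed)
  on.exit(restore_rng(), add = TRUE)
  template <- truth$template
  npts <- nrow(template$coords)
  p <- 3L * npts
  n <- ape::Ntip(tree)
  C <- phylo_cov(tree)
  L <- t(chol(C))

  bm <- bm_draws(L, p, truth$sigma_bm)
  s_raw <- drop(bm_draws(L, 1L)) + stats::rnorm(n, 0, truth$size_jitter)
  f <- drop(bm_draws(L, 1L))
  allo <- tcrossprod(s_raw, truth$beta_size)
  integ <- tcrossprod(f, truth$latent_loadings)
  diet <- sample(names(truth$diet_probs), n, replace = TRUE,
                 prob = truth$diet_probs)
  dieteff <- matrix(0, n, p)
  if (!is.null(truth$diet_effects))
    dieteff <- do.call(rbind, truth$diet_effects[diet])
  noise <- matrix(stats::rnorm(n * p, 0, truth$sigma_noise), n, p)
  dev <- bm + allo + integ + dieteff + noise
  rownames(dev) <- tree$tip.label

  logcs <- truth$logcs_mean + truth$logcs_sd * s_raw
  tmpl_flat <- as.numeric(t(template$coords))
  shapes <- sweep(dev, 2L, tmpl_flat, "+")

  coords <- array(NA_real_, c(npts, 3L, n))
  for (i in seq_len(n)) {
    m <- unflatten_shape(shapes[i, ]) * exp(logcs[i])
    if (rigid_motion) {
      r <- qr.Q(qr(matrix(stats::rnorm(9L), 3L)))
      if (det(r) < 0) r[, 1L] <- -r[, 1L]
      m <- m %*% r
      m <- sweep(m, 2L, stats::rnorm(3L, 0, 1), "+")
    }
    coords[, , i] <- m
  }
  lms <- landmark_set(coords, tree$tip.label, template$point_roles,
                      template$curve_membership)

  clade <- clade_groups(tree, k = 3L)
  metadata <- data.frame(species = tree$tip.label, clade = clade,
                         diet = diet, stringsAsFactors = FALSE)

  invC <- solve(C)
  realized <- realized_fractions(list(allometric = allo, integration = integ,
                                      bm = bm, diet = dieteff,
                                      noise = noise), dev, invC)
  truth$realized_fractions <- realized
  cs <- vapply(seq_len(n), function(i) centroid_size(coords[, , i]),
               numeric(1))
  aligned <- structure(list(
    coords = NULL,
    centroid_size = stats::setNames(exp(logcs), tree$tip.label),
    consensus = template$coords,
    flattened = shapes), class = "aligned_shapes")
  list(landmarks = lms, shapes = shapes, aligned = aligned,
       metadata = metadata, logCS = stats::setNames(logcs, tree$tip.label),
       centroid_size_raw = stats::setNames(cs, tree$tip.label),
       truth = truth)
}

realized_fractions <- function(components, dev, invC) {
  n <- nrow(invC)
  w <- invC %*% rep(1, n) / sum(invC)
  m <- diag(n) - tcrossprod(rep(1, n), w)
  P <- phylo_transform(solve(invC))
  wss <- function(x) sum((P %*% (m %*% x))^2)
  tot <- wss(dev)
  vapply(components, function(x) wss(x) / tot, numeric(1))
}

# coarse clade labels from the tree: cut the cophenetic dendrogram
clade_groups <- function(tree, k = 3L) {
  d <- stats::as.dist(ape::cophenetic.phylo(tree))
  cl <- stats::cutree(stats::hclust(d, method = "average"),
                      k = min(k, ape::Ntip(tree) - 1L))
  paste0("clade", cl)
}

#' Write a named synthetic fixture to disk
#'
#' Generates a complete synthetic dataset (landmarks, tree, sliders,
#' symmetry pairs, metadata, block definition, ground truth) in exactly
#' the plain-text formats the readers accept. Presets:
#' \describe{
#'   \item{tiny}{8 tips x 12 points; exercises every pipeline stage fast.}
#'   \item{null}{150 tips, no allometry / integration / diet structure.}
#'   \item{allometric}{150 tips, allometric fraction 0.40, no integration.}
#'   \item{integrated}{150 tips, integration fraction 0.40, no allometry.}
#'   \item{full}{150 tips x 60 points, allometric 0.30 + integration 0.25
#'     + diet offsets + noise.}
#' }
#'
#' @param name preset name.
#' @param dir output directory (created if needed).
#' @param seed integer seed; identical seeds give byte-identical fixtures.
#' @return invisibly, a list with the file paths and the simulation
#'   objects.
#' @export
make_fixture <- function(name = c("tiny", "null", "allometric",
                                  "integrated", "full"),
                         dir, seed = 1L) {
  name <- match.arg(name)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- switch(name,
    tiny = list(n = 8L, size = "tiny", fa = 0.30, fb = 0.25,
                diet = 0, noise = 0),
    null = list(n = 150L, size = "tiny", fa = 0, fb = 0,
                diet = 0, noise = 0),
    allometric = list(n = 150L, size = "tiny", fa = 0.40, fb = 0,
                      diet = 0, noise = 0),
    integrated = list(n = 150L, size = "tiny", fa = 0, fb = 0.40,
                      diet = 0, noise = 0),
    full = list(n = 150L, size = "full", fa = 0.30, fb = 0.25,
                diet = 0.004, noise = 0.002))
  tree <- simulate_tree(cfg$n, seed = seed)
  template <- skull_template(cfg$size)
  truth <- synthetic_truth(tree, template,
                           allometric_fraction = cfg$fa,
                           integration_fraction = cfg$fb,
                           diet_scale = cfg$diet, sigma_noise = cfg$noise,
                           seed = seed + 1L)
  sim <- simulate_shapes(tree, truth, seed = seed + 2L)

  paths <- list(
    landmarks = file.path(dir, "landmarks.txt"),
    tree = file.path(dir, "tree.nwk"),
    sliders = file.path(dir, "sliders.txt"),
    pairs = file.path(dir, "landpairs.txt"),
    metadata = file.path(dir, "metadata.csv"),
    blocks = file.path(dir, "blocks.json"),
    truth = file.path(dir, "truth.json"),
    config = file.path(dir, "config.json"))
  write_landmarks(sim$landmarks, paths$landmarks)
  ape::write.tree(tree, paths$tree)
  utils::write.table(template$sliders, paths$sliders, row.names = FALSE,
                     quote = FALSE)
  utils::write.table(template$pairs, paths$pairs, row.names = FALSE,
                     quote = FALSE)
  utils::write.csv(sim$metadata, paths$metadata, row.names = FALSE)
  jsonlite::write_json(template$blocks, paths$blocks)
  jsonlite::write_json(list(
    name = name, seed = seed,
    expected_fractions = as.list(truth$expected_fractions),
    realized_fractions = as.list(truth$realized_fractions),
    sigma_bm = truth$sigma_bm, sigma_noise = truth$sigma_noise,
    logcs_sd = truth$logcs_sd, size_jitter = truth$size_jitter,
    beta_size = truth$beta_size,
    latent_loadings = truth$latent_loadings),
    paths$truth, auto_unbox = TRUE, digits = NA)
  n_fixed <- sum(template$point_roles == "fixed")
  n_semi <- sum(template$point_roles == "semilandmark")
  jsonlite::write_json(list(
    landmarks = "landmarks.txt", tree = "tree.nwk",
    sliders = "sliders.txt", pairs = "landpairs.txt",
    metadata = "metadata.csv", blocks = "blocks.json",
    n_fixed = n_fixed, n_semi = n_semi,
    n_perm = 99L, seed = seed, fraction_basis = "total",
    min_group = 3L),
    paths$config, auto_unbox = TRUE, digits = NA)
  invisible(list(paths = paths, tree = tree, truth = truth, sim = sim,
                 template = template))
}
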