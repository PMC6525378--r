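#' Landmark configuration sets
#'
#' A `landmark_set` holds per-specimen 3D landmark configurations together
#' with the role of each point (`"fixed"` or `"semilandmark"`) and, for
#' semilandmarks, the curve each belongs to. All specimens must share the
#' same number of points and the same role assignment.
#'
#' @param coords numeric array of dimension `n_points x 3 x n_specimens`.
#' @param specimen_ids character vector of unique specimen labels.
#' @param point_roles character vector, one of `"fixed"`/`"semilandmark"`
#'   per point. Defaults to all fixed.
#' @param curve_membership integer/character vector with one entry per point;
#'   `NA` for fixed landmarks.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(coords, specimen_ids = NULL, point_roles = NULL,
                         curve_membership = NULL) {
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L)
    stop("`coords` must be an n_points x 3 x n_specimens array")
  n_pts <- dim(coords)[1]
  n_spec <- dim(coords)[3]
  if (n_spec < 1L) stop("no specimens")
  if (is.null(specimen_ids)) specimen_ids <- paste0("spec", seq_len(n_spec))
  if (anyDuplicated(specimen_ids)) stop("specimen ids must be unique")
  if (length(specimen_ids) != n_spec)
    stop("length(specimen_ids) must equal the number of specimens")
  if (is.null(point_roles)) point_roles <- rep("fixed", n_pts)
  if (length(point_roles) != n_pts ||
      !all(point_roles %in% c("fixed", "semilandmark")))
    stop("`point_roles` must tag every point as 'fixed' or 'semilandmark'")
  if (is.null(curve_membership)) curve_membership <- rep(NA_integer_, n_pts)
  if (length(curve_membership) != n_pts)
    stop("`curve_membership` must have one entry per point")
  if (!all(is.finite(coords)))
    stop("non-finite coordinates in landmark data")
  dimnames(coords) <- list(NULL, c("x", "y", "z"), specimen_ids)
  structure(list(coords = coords, specimen_ids = specimen_ids,
                 point_roles = point_roles,
                 curve_membership = curve_membership),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("landmark_set: %d specimens x %d points (%d fixed, %d semi)\n",
              length(x$specimen_ids), dim(x$coords)[1],
              sum(x$point_roles == "fixed"),
              sum(x$point_roles == "semilandmark")))
  invisible(x)
}

#' Number of points / specimens in a landmark set
#' @param x a `landmark_set`
#' @return integer count
#' @export
n_points <- function(x) dim(x$coords)[1]

#' @rdname n_points
#' @export
n_specimens <- function(x) dim(x$coords)[3]

#' Read landmark configurations from plain text
#'
#' Reads either a plain whitespace-delimited matrix of coordinates
#' (`n_points` rows x 3 columns per specimen, blocks stacked vertically,
#' blank lines and `#` comments ignored, an optional leading `ID=`/`>`
#' label per block) or TPS-dialect files with `LM3=` records and `ID=`
#' labels. The format is auto-detected from the first non-blank line.
#'
#' @param path file path.
#' @param n_fixed,n_semi number of fixed landmarks and semilandmarks per
#'   specimen. Fixed landmarks are assumed to occupy the first `n_fixed`
#'   rows of each block (1-based file numbering).
#' @param curve_membership optional per-point curve ids for the
#'   semilandmark rows (length `n_fixed + n_semi`, `NA` on fixed rows).
#' @return a [landmark_set].
#' @export
read_landmarks <- function(path, n_fixed, n_semi = 0L,
                           curve_membership = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  nonblank <- trimws(lines[trimws(lines) != ""])
  if (length(nonblank) == 0L) stop("no specimens in ", path)
  n_pts <- as.integer(n_fixed + n_semi)
  if (any(grepl("^LM3?\\s*=", nonblank, ignore.case = TRUE))) {
    parsed <- parse_tps_blocks(nonblank, n_pts)
  } else {
    parsed <- parse_plain_blocks(nonblank, n_pts)
  }
  roles <- rep(c("fixed", "semilandmark"), c(n_fixed, n_semi))
  landmark_set(parsed$coords, parsed$ids, roles, curve_membership)
}

parse_plain_blocks <- function(nonblank, n_pts) {
  is_label <- grepl("^(>|ID\\s*=)", nonblank, ignore.case = TRUE)
  ids <- character()
  rows <- list()
  cur_id <- NA_character_
  cur <- list()
  flush <- function(cur, cur_id, rows, ids) {
    if (length(cur) == 0L) return(list(rows = rows, ids = ids))
    m <- do.call(rbind, cur)
    if (nrow(m) != n_pts)
      stop(sprintf("specimen %d ('%s') has %d coordinate rows, expected %d",
                   length(rows) + 1L,
                   ifelse(is.na(cur_id), "?", cur_id), nrow(m), n_pts))
    rows[[length(rows) + 1L]] <- m
    ids <- c(ids, cur_id)
    list(rows = rows, ids = ids)
  }
  for (i in seq_along(nonblank)) {
    ln <- nonblank[i]
    if (is_label[i]) {
      st <- flush(cur, cur_id, rows, ids); rows <- st$rows; ids <- st$ids
      cur <- list()
      cur_id <- trimws(sub("^(>|ID\\s*=)", "", ln, ignore.case = TRUE))
    } else {
      tok <- strsplit(ln, "\\s+|,")[[1]]
      tok <- tok[tok != ""]
      val <- suppressWarnings(as.numeric(tok))
      if (anyNA(val))
        stop(sprintf("non-numeric token '%s' in landmark file (line content: '%s')",
                     tok[which(is.na(val))[1]], ln))
      if (length(val) %% 3L != 0L)
        stop("coordinate rows must have 3 (or a multiple of 3) values: '",
             ln, "'")
      for (r in seq_len(length(val) / 3L))
        cur[[length(cur) + 1L]] <- val[(3L * r - 2L):(3L * r)]
      if (length(cur) > n_pts)
        stop(sprintf("specimen %d has more than %d coordinate rows",
                     length(rows) + 1L, n_pts))
      if (length(cur) == n_pts) {
        st <- flush(cur, cur_id, rows, ids); rows <- st$rows; ids <- st$ids
        cur <- list(); cur_id <- NA_character_
      }
    }
  }
  if (length(cur) > 0L)
    stop(sprintf("specimen %d has %d coordinate rows, expected %d",
                 length(rows) + 1L, length(cur), n_pts))
  if (length(rows) == 0L) stop("no specimens")
  ids[is.na(ids)] <- paste0("spec", which(is.na(ids)))
  coords <- array(unlist(lapply(rows, t)), dim = c(3, n_pts, length(rows)))
  coords <- aperm(coords, c(2, 1, 3))
  list(coords = coords, ids = ids)
}

parse_tps_blocks <- function(nonblank, n_pts) {
  starts <- grep("^LM3?\\s*=", nonblank, ignore.case = TRUE)
  if (length(starts) == 0L) stop("no LM/LM3 records found")
  ends <- c(starts[-1] - 1L, length(nonblank))
  rows <- list(); ids <- character()
  for (b in seq_along(starts)) {
    blk <- nonblank[starts[b]:ends[b]]
    declared <- as.integer(sub("^LM3?\\s*=\\s*", "", blk[1], ignore.case = TRUE))
    id_ln <- grep("^ID\\s*=", blk, ignore.case = TRUE)
    id <- if (length(id_ln)) trimws(sub("^ID\\s*=", "", blk[id_ln[1]],
                                        ignore.case = TRUE)) else
      paste0("spec", b)
    coord_lns <- blk[-c(1L, id_ln)]
    coord_lns <- coord_lns[!grepl("^[A-Za-z]+\\s*=", coord_lns)]
    m <- do.call(rbind, lapply(coord_lns, function(ln) {
      tok <- strsplit(trimws(ln), "\\s+")[[1]]
      val <- suppressWarnings(as.numeric(tok))
      if (anyNA(val)) stop("non-numeric token in TPS block ", b, ": '", ln, "'")
      val
    }))
    if (is.null(m) || nrow(m) != declared || ncol(m) != 3L)
      stop(sprintf("TPS block %d: found %d x %d coordinates, LM3=%d declared",
                   b, NROW(m), NCOL(m), declared))
    if (nrow(m) != n_pts)
      stop(sprintf("specimen %d ('%s') has %d landmarks, expected %d",
                   b, id, nrow(m), n_pts))
    rows[[b]] <- m; ids[b] <- id
  }
  coords <- array(unlist(lapply(rows, t)), dim = c(3, n_pts, length(rows)))
  coords <- aperm(coords, c(2, 1, 3))
  list(coords = coords, ids = ids)
}

#' Write landmark configurations to plain text or TPS dialect
#'
#' @param x a [landmark_set] (or an `n_points x 3 x n` array).
#' @param path output file.
#' @param format `"plain"` (ID= label + whitespace matrix per specimen) or
#'   `"tps"` (`LM3=` blocks).
#' @param digits significant digits written; the default round-trips
#'   doubles exactly.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(x, path, format = c("plain", "tps"),
                            digits = 17L) {
  format <- match.arg(format)
  coords <- if (inherits(x, "landmark_set")) x$coords else x
  ids <- if (inherits(x, "landmark_set")) x$specimen_ids else
    dimnames(coords)[[3]]
  if (is.null(ids)) ids <- paste0("spec", seq_len(dim(coords)[3]))
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(dim(coords)[3])) {
    m <- coords[, , i, drop = TRUE]
    body <- apply(m, 1L, function(r)
      paste(formatC(r, digits = digits, format = "g"), collapse = " "))
    if (format == "plain") {
      writeLines(c(paste0("ID=", ids[i]), body), con)
    } else {
      writeLines(c(paste0("LM3=", nrow(m)), body, paste0("ID=", ids[i])), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Resample an open polyline to equally spaced points
#'
#' Treats the input as a piecewise-linear open curve, measures cumulative
#' arc length, and returns `k` points at equal arc-length spacing with the
#' two endpoints preserved. This is the standard preparation of
#' digitised curve traces into a fixed number of semilandmarks.
#'
#' @param points numeric matrix (`m x 3`, `m >= 2`) of ordered curve points.
#' @param k number of output points (`k >= 2`).
#' @return a `k x 3` matrix of points on the input polyline.
#' @export
resample_curve <- function(points, k) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("need at least 2 input points")
  if (k < 2L) stop("k must be >= 2")
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  total <- sum(seg)
  if (total <= 0) stop("curve has zero total arc length")
  cum <- c(0, cumsum(seg))
  target <- seq(0, total, length.out = k)
  out <- matrix(NA_real_, k, ncol(points))
  for (j in seq_len(ncol(points)))
    out[, j] <- stats::approx(cum, points[, j], xout = target, ties = "ordered")$y
  out[1L, ] <- points[1L, ]
  out[k, ] <- points[nrow(points), ]
  out
}

#' Slider definitions for semilandmarks
#'
#' Each row names a semilandmark and its two curve neighbours
#' (before, slide, after), using the same point indices as the landmark
#' configurations. Files use 1-based indices (the convention of published
#' landmark tables); indices are stored 1-based in R as well.
#'
#' @param triples integer matrix / data.frame with columns before, slide,
#'   after.
#' @param roles optional point-role vector used to validate that every
#'   slid point is tagged as a semilandmark.
#' @param n_points optional total point count for bounds checking.
#' @return a `slider_definition`: a 3-column integer matrix.
#' @export
slider_definition <- function(triples, roles = NULL, n_points = NULL) {
  m <- as.matrix(triples)
  if (ncol(m) != 3L) stop("slider table must have 3 columns (before, slide, after)")
  storage.mode(m) <- "integer"
  colnames(m) <- c("before", "slide", "after")
  if (anyDuplicated(m[, "slide"])) stop("duplicate slider indices")
  if (any(m[, "slide"] == m[, "before"] | m[, "slide"] == m[, "after"]))
    stop("a semilandmark cannot neighbour itself")
  if (!is.null(n_points) && any(m > n_points | m < 1L))
    stop("slider indices out of range 1..", n_points)
  if (!is.null(roles) && !all(roles[m[, "slide"]] == "semilandmark"))
    stop("slid points must be tagged as semilandmarks")
  structure(m, class = c("slider_definition", class(m)))
}

#' Read a slider table (before / slide / after) from whitespace text
#'
#' @inheritParams slider_definition
#' @param path file with 3 whitespace-separated integer columns; an
#'   optional header line containing non-numeric tokens is skipped.
#' @return a [slider_definition].
#' @export
read_sliders <- function(path, roles = NULL, n_points = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = looks_like_header(path))
  slider_definition(tab, roles = roles, n_points = n_points)
}

looks_like_header <- function(path) {
  first <- readLines(path, n = 1L)
  tok <- strsplit(trimws(first), "\\s+|,")[[1]]
  any(is.na(suppressWarnings(as.numeric(tok))))
}

#' Bilateral symmetry map
#'
#' Pairs of (left, right) point indices plus the unpaired midline points.
#' Every point of the configuration must appear exactly once.
#'
#' @param pairs 2-column integer matrix of (left, right) indices, 1-based.
#' @param n_points total number of points; midline points are inferred as
#'   those absent from `pairs`.
#' @return a `symmetry_map`: list with `pairs` and `midline`.
#' @export
symmetry_map <- function(pairs, n_points) {
  m <- as.matrix(pairs)
  if (ncol(m) != 2L) stop("pairs must have 2 columns")
  storage.mode(m) <- "integer"
  all_idx <- as.integer(m)
  if (anyDuplicated(all_idx))
    stop("each point may appear at most once across symmetry pairs")
  if (any(all_idx < 1L | all_idx > n_points))
    stop("pair indices out of range 1..", n_points)
  midline <- setdiff(seq_len(n_points), all_idx)
  structure(list(pairs = m, midline = midline, n_points = n_points),
            class = "symmetry_map")
}

#' Read a landmark-pair table for bilateral symmetry
#'
#' @param path file with 2 whitespace-separated integer columns
#'   (left index, right index); optional header skipped.
#' @param n_points total number of points in the configurations.
#' @return a [symmetry_map].
#' @export
read_landmark_pairs <- function(path, n_points) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = looks_like_header(path))
  symmetry_map(tab, n_points)
}

#' Recode a coarse diet category into mechanical-resistance classes
#'
#' Maps the broad preferred-diet categories used in trait databases onto
#' mechanical food-resistance classes: generic plant material and seeds
#' are more mechanically resistant (`MMR`), fruit and nectar less so
#' (`LMR`), and omnivores are `mixed`.
#'
#' @param elton_category character vector in
#'   `c("plant/seed", "omnivore", "fruit/nectar")`.
#' @return character vector in `c("MMR", "mixed", "LMR")`.
#' @export
recode_diet <- function(elton_category) {
  map <- c("plant/seed" = "MMR", "omnivore" = "mixed",
           "fruit/nectar" = "LMR")
  bad <- setdiff(unique(elton_category), names(map))
  if (length(bad))
    stop("unknown diet category '", bad[1], "'; accepted: ",
         paste(names(map), collapse = ", "))
  unname(map[elton_category])
}

#' Read specimen metadata (species, clade, diet)
#'
#' Expects a CSV with header columns `species`, `clade` and either `diet`
#' (already coded MMR/mixed/LMR) or `elton` (coarse categories recoded via
#' [recode_diet]).
#'
#' @param path CSV file path.
#' @return data.frame with columns `species`, `clade`, `diet`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  if (!all(c("species", "clade") %in% names(tab)))
    stop("metadata must have 'species' and 'clade' columns")
  if (!"diet" %in% names(tab)) {
    if (!"elton" %in% names(tab))
      stop("metadata must have a 'diet' or 'elton' column")
    tab$diet <- recode_diet(tab$elton)
  }
  if (!all(tab$diet %in% c("MMR", "mixed", "LMR")))
    stop("diet must be one of MMR, mixed, LMR")
  if (anyNA(tab$clade) || any(tab$clade == ""))
    stop("clade group missing for some specimens")
  tab[, c("species", "clade", "diet")]
}

#' Canonical species-name form used to match files, metadata and tree
#'
#' Case-insensitive, with underscores equivalent to spaces.
#' @param x character vector of names.
#' @return normalized names.
#' @export
normalize_names <- function(x) tolower(gsub("_", " ", trimws(x)))

#' Match two label sets after name normalization
#'
#' Returns the index of each `needed` label in `available`; any label that
#' cannot be matched is a hard error (silent dropping of tips or specimens
#' would corrupt downstream phylogenetic covariance matrices).
#'
#' @param needed,available character vectors of labels.
#' @param what description used in the error message.
#' @return integer index vector into `available`.
#' @export
match_names <- function(needed, available, what = "labels") {
  idx <- match(normalize_names(needed), normalize_names(available))
  if (anyNA(idx))
    stop("missing ", what, ": ",
         paste(needed[is.na(idx)], collapse = ", "))
  idx
}

#' Read and prune a phylogeny for a set of tips
#'
#' Reads Newick or Nexus (auto-detected from the leading `#NEXUS` token),
#' matches the requested tips by normalized name, and prunes the tree to
#' exactly those tips. Missing tips are a hard error; zero or negative
#' branch lengths are retained with a warning.
#'
#' @param path tree file.
#' @param tip_labels specimen labels the tree must cover; `NULL` keeps all
#'   tips.
#' @return an [ape::phylo] tree (tip labels as in the file).
#' @export
read_tree <- function(path, tip_labels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- toupper(trimws(readLines(path, n = 1L)))
  tree <- if (startsWith(first, "#NEXUS")) ape::read.nexus(path) else
    ape::read.tree(path)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (!is.null(tip_labels)) {
    idx <- match_names(tip_labels, tree$tip.label, what = "tree tips")
    tree <- ape::keep.tip(tree, tree$tip.label[idx])
  }
  if (any(tree$edge.length <= 0))
    warning("tree has ", sum(tree$edge.length <= 0),
            " zero/negative branch lengths; retained as-is")
  tree
}
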