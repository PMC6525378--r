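test_that("landmark files round-trip through plain and TPS writers", {
  set.seed(10)
  arr <- array(rnorm(2 * 60 * 3), c(60, 3, 2))
  lms <- landmark_set(arr, c("Ara macao", "Strigops habroptila"),
                      rep(c("fixed", "semilandmark"), c(20, 40)))
  for (fmt in c("plain", "tps")) {
    f <- withr::local_tempfile(fileext = ".txt")
    write_landmarks(lms, f, format = fmt)
    back <- read_landmarks(f, n_fixed = 20, n_semi = 40)
    expect_equal(back$coords, lms$coords)
    expect_equal(back$specimen_ids, lms$specimen_ids)
    expect_equal(n_points(back), 60)
    expect_equal(n_specimens(back), 2)
  }
})

test_that("malformed landmark files are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), f)
  expect_error(read_landmarks(f, 2, 0), "no specimens")

  # 59 rows when 60 expected, error cites the specimen
  writeLines(apply(matrix(rnorm(59 * 3), 59), 1, paste, collapse = " "), f)
  expect_error(read_landmarks(f, 20, 40), "specimen 1")

  writeLines(c("1 2 3", "4 oops 6"), f)
  expect_error(read_landmarks(f, 2, 0), "non-numeric")
})

test_that("curve resampling yields equal arc spacing and keeps endpoints", {
  line <- cbind(0:9, 0, 0)
  out <- resample_curve(line, 10)
  expect_equal(out[, 1], 0:9)
  expect_equal(out[, 2], rep(0, 10))

  # k = 2 returns the two endpoints of any curve
  curve <- cbind(cumsum(runif(8)), sin(1:8), cos(1:8))
  expect_equal(resample_curve(curve, 2), curve[c(1, 8), ])

  # L-shaped polyline: midpoint by arc length is the corner
  ell <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(resample_curve(ell, 3)[2, ], c(1, 0, 0))

  # equal arc-length spacing property on random monotone polylines:
  # locate each output point's arc coordinate on the input curve by its
  # (monotone) x value, then check the increments are uniform
  arc_position <- function(q, pl) {
    seg <- sqrt(rowSums(diff(pl)^2))
    cum <- c(0, cumsum(seg))
    i <- max(which(pl[, 1] <= q[1] + 1e-12))
    i <- min(i, nrow(pl) - 1L)
    cum[i] + sqrt(sum((q - pl[i, ])^2))
  }
  for (s in 1:5) {
    set.seed(s)
    pl <- cbind(cumsum(runif(12, 0.1, 1)), rnorm(12), rnorm(12))
    rs <- resample_curve(pl, 10)
    arcs <- apply(rs, 1, arc_position, pl = pl)
    total <- sum(sqrt(rowSums(diff(pl)^2)))
    expect_equal(diff(arcs), rep(total / 9, 9), tolerance = 1e-9)
  }
  expect_error(resample_curve(rbind(c(0, 0, 0), c(0, 0, 0)), 5),
               "zero total arc length")
})

test_that("diet recoding is total and surjective over accepted labels", {
  expect_equal(recode_diet("plant/seed"), "MMR")
  expect_equal(recode_diet("omnivore"), "mixed")
  expect_equal(recode_diet("fruit/nectar"), "LMR")
  expect_setequal(recode_diet(c("plant/seed", "omnivore", "fruit/nectar")),
                  c("MMR", "mixed", "LMR"))
  expect_error(recode_diet("granivore"), "accepted")
})

test_that("tree reading prunes to requested tips and preserves path lengths", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:1);", f)
  tr <- read_tree(f, c("A", "B"))
  expect_equal(ape::Ntip(tr), 2)
  expect_equal(unname(ape::node.depth.edgelength(tr)[1:2]), c(1, 1))

  writeLines("((A:1,B:1):1,C:2);", f)
  tr <- read_tree(f, c("A", "C"))
  expect_equal(sort(tr$tip.label), c("A", "C"))
  # brute-force root-to-tip path sums after pruning
  expect_equal(unname(ape::node.depth.edgelength(tr)[1:2]), c(2, 2))

  expect_error(read_tree(f, c("A", "D")), "D")
})

test_that("species matching is case-insensitive with underscore/space equivalence", {
  idx <- match_names(c("Ara_macao", "NESTOR notabilis"),
                     c("nestor_notabilis", "Ara macao"))
  expect_equal(idx, c(2L, 1L))
  expect_error(match_names("Pionus", c("Ara macao")), "Pionus")
})

test_that("slider and symmetry tables validate their invariants", {
  expect_error(slider_definition(cbind(1, 2, 2)), "neighbour")
  expect_error(slider_definition(rbind(c(1, 2, 3), c(4, 2, 5))), "duplicate")
  expect_error(slider_definition(cbind(1, 99, 3), n_points = 10), "range")
  roles <- rep(c("fixed", "semilandmark"), c(2, 2))
  expect_error(slider_definition(cbind(3, 1, 4), roles = roles), "tagged")
  sd_ok <- slider_definition(cbind(1, 3, 4), roles = roles, n_points = 4)
  expect_s3_class(sd_ok, "slider_definition")

  sm <- symmetry_map(rbind(c(1, 2), c(3, 4)), n_points = 6)
  expect_equal(sm$midline, c(5L, 6L))
  expect_error(symmetry_map(rbind(c(1, 2), c(2, 3)), 6), "at most once")
})

test_that("metadata reading recodes diet and enforces required columns", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,clade,elton",
               "Ara macao,afrotropical,plant/seed",
               "Nestor notabilis,strigopoid,omnivore"), f)
  md <- read_metadata(f)
  expect_equal(md$diet, c("MMR", "mixed"))
  writeLines(c("species,diet", "x,MMR"), f)
  expect_error(read_metadata(f), "clade")
})
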