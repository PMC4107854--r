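test_that("SWC parsing handles simple trees and reports structural errors", {
  f <- swc_file(c("# comment", "1 1 0 0 0 1 -1", "2 3 1 0 0 0.5 1",
                  "3 3 2 0 0 0.5 2"))
  tree <- read_swc(f)
  expect_equal(nrow(tree$points), 3L)
  segs <- unbranched_segments(tree)
  expect_length(segs, 1L)
  expect_equal(segs[[1]], 1:3)

  # Y-shaped tree: one trunk and two branches
  fy <- swc_file(c("1 1 0 0 0 1 -1", "2 3 1 0 0 0.5 1", "3 3 2 0 0 0.5 2",
                   "4 3 3 1 0 0.4 3", "5 3 3 -1 0 0.3 3"))
  segsy <- unbranched_segments(read_swc(fy))
  expect_length(segsy, 3L)

  expect_error(read_swc(swc_file(c("1 1 0 0 0 1 -1", "2 3 1 0 0 0 1"))),
               "radius")
  expect_error(read_swc(swc_file(c("1 1 0 0 0 1 -1", "2 3 1 0 0 0.5 9"))),
               "parent")
  expect_error(read_swc(swc_file(c("1 1 0 0 0 1 -1", "2 3 1 0 0 0.5 3",
                                   "3 3 2 0 0 0.5 2"))),
               "unreachable|cycle")
  expect_error(read_swc(swc_file(c("1 1 0 0 0 1 -1", "2 1 1 0 0 1 -1"))),
               "root")
  expect_error(read_swc(swc_file("1 1 0 0 0 1")), "7 columns")
})

test_that("generated trees round-trip through SWC byte-identically", {
  tree <- taper_tree(noise_cv = 0.25)
  f1 <- tempfile(fileext = ".swc"); f2 <- tempfile(fileext = ".swc")
  write_swc(tree, f1)
  write_swc(read_swc(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("per-segment diameter CV uses the sample standard deviation", {
  mk <- function(radii) {
    lines <- c("1 1 0 0 0 1 -1",
               sprintf("%d 3 %d 0 0 %g %d", seq_along(radii) + 1,
                       seq_along(radii), radii, seq_along(radii)))
    read_swc(swc_file(lines))
  }
  cv <- diameter_cv(mk(c(0.5, 0.5, 0.5)))
  expect_equal(cv$cv, 0)
  cv <- diameter_cv(mk(c(0.4, 0.5, 0.6)))  # diameters 0.8, 1.0, 1.2
  expect_equal(cv$cv, 0.2, tolerance = 1e-12)
  expect_equal(cv$mean_diam, 1)
  # a lone non-soma point cannot have a CV
  cv <- diameter_cv(mk(0.5))
  expect_true(cv$excluded)
  expect_true(is.na(cv$cv))
})

test_that("generator recovers a target within-segment CV", {
  rec <- tree_recipe(branch_depth = 1, points_per_segment = 30,
                     segment_length = 30, taper = 1, child_ratio = c(1, 1),
                     noise_cv = 0.4, seed = 11)
  cv <- diameter_cv(generate_tree(rec))
  keep <- !cv$excluded & cv$n_points >= 10
  expect_equal(mean(cv$cv[keep]), 0.4, tolerance = 0.05)
  # noise-free tree without taper: all CVs exactly zero
  rec0 <- tree_recipe(branch_depth = 1, taper = 1, child_ratio = c(1, 1),
                      noise_cv = 0, seed = 11)
  cv0 <- diameter_cv(generate_tree(rec0))
  expect_equal(max(cv0$cv[!cv0$excluded]), 0)
})

test_that("compartmentalization preserves path length and taper structure", {
  tree <- taper_tree(taper = 0.6)
  pl <- function(tree) {
    p <- tree$points
    idx <- match(p$parent, p$id)
    keep <- !is.na(idx)
    sum(sqrt((p$x[keep] - p$x[idx[keep]])^2 + (p$y[keep] - p$y[idx[keep]])^2 +
               (p$z[keep] - p$z[idx[keep]])^2))
  }
  c1 <- compartmentalize(tree, "one_per_segment")
  c2 <- compartmentalize(tree, "per_traced_point")
  expect_equal(sum(c1$compartments$L), pl(tree), tolerance = 1e-9)
  expect_equal(sum(c2$compartments$L), pl(tree), tolerance = 1e-9)
  # per-point mode keeps the within-segment taper; per-segment collapses it
  seg1 <- c2$compartments[c2$compartments$segment == 1, ]
  expect_true(all(diff(seg1$diam) < 0))
  expect_length(unique(c1$compartments$diam[c1$compartments$segment == 1]), 1L)

  # constant-diameter unbranched tree: both modes give the same diameter
  ctree <- taper_tree(taper = 1, depth = 0)
  d1 <- compartmentalize(ctree, "one_per_segment")$compartments$diam
  d2 <- compartmentalize(ctree, "per_traced_point")$compartments$diam
  expect_equal(unique(round(d2, 12)), unique(round(d1, 12)))
})

test_that("hand-checkable taper: a 4-point linear taper averages as expected", {
  # points at x = 0,1,2,3 with diameters 1.0, 0.9, 0.8, 0.7
  f <- swc_file(c("1 1 0 0 0 0.5 -1", "2 3 1 0 0 0.45 1",
                  "3 3 2 0 0 0.4 2", "4 3 3 0 0 0.35 3"))
  tree <- read_swc(f)
  cp <- compartmentalize(tree, "per_traced_point")
  expect_equal(cp$compartments$diam, c(0.95, 0.85, 0.75), tolerance = 1e-12)
  cs <- compartmentalize(tree, "one_per_segment")
  expect_equal(cs$compartments$diam, 0.85, tolerance = 1e-12)
  expect_equal(cs$compartments$L, 3)
})

test_that("segment extraction is invariant to id permutations preserving topology", {
  tree <- taper_tree(noise_cv = 0.2)
  p <- tree$points
  # relabel ids by a fixed permutation, keep parent links consistent
  perm <- rev(seq_len(nrow(p)))
  map <- stats::setNames(perm, p$id)
  q <- p
  q$id <- unname(map[as.character(p$id)])
  q$parent <- ifelse(p$parent == -1L, -1L, unname(map[as.character(p$parent)]))
  q <- q[order(q$id), ]
  tree2 <- structure(list(points = q, path = NA_character_),
                     class = "morphology_tree")
  cv1 <- sort(diameter_cv(tree)$cv)
  cv2 <- sort(diameter_cv(tree2)$cv)
  expect_equal(cv1, cv2, tolerance = 1e-12)
})
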