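test_that("integrated calcium is the sample sum times the step", {
  tt <- seq(0, 100, by = 0.02)
  tr <- ca_trace(tt, rep(REST, length(tt)))
  v <- integrated_ca(tr, c(40, 60))
  expect_equal(v$value, REST * 20, tolerance = 1e-12)
  # linearity
  tr2 <- ca_trace(tt, 2 * rep(REST, length(tt)))
  expect_equal(integrated_ca(tr2, c(40, 60))$value, 2 * v$value,
               tolerance = 1e-12)
  expect_error(integrated_ca(tr, c(90, 120)), "outside")
})

test_that("integrated calcium of an alpha pulse matches the analytic integral", {
  dt <- 0.005; w <- 2; tt <- seq(0, 80, by = dt)
  ca <- (tt / w) * exp(1 - tt / w) * 1e-3
  tr <- ca_trace(tt, ca)
  analytic <- 1e-3 * exp(1) * w * (1 - (1 + 80 / w) * exp(-80 / w))
  expect_equal(integrated_ca(tr, c(0, 80))$value, analytic, tolerance = 1e-5)
})

test_that("first peak detection finds the first transient, not the global maximum", {
  tt <- seq(0, 100, by = 0.1)
  ca <- REST + 1e-3 * ((tt / 5) * exp(1 - tt / 5) +
                         2 * pmax(tt - 50, 0) / 5 * exp(1 - pmax(tt - 50, 0) / 5))
  tr <- ca_trace(tt, ca)
  expect_equal(first_peak_time(tr), 5, tolerance = 0.2)
  # flat trace has no peak
  expect_true(is.na(first_peak_time(ca_trace(tt, rep(REST, length(tt))))))
})

test_that("adjacent ratios are symmetric, at least one, and skip unusable pairs", {
  adj <- data.frame(a = c(1, 2, 3), b = c(2, 3, 4))
  expect_equal(as.numeric(adjacent_ratios(c(1, 1, 1, 1), adj)), c(1, 1, 1))
  r <- adjacent_ratios(c(2, 1, 0, 4), adj)
  expect_equal(as.numeric(r), 2)
  expect_equal(attr(r, "skipped"), 2L)
  h <- adjacent_ratio_histogram(c(1, 1.15, 1.15, 5), adj)
  expect_equal(sum(h$count), 3)
})

test_that("ratio maps have unit diagonal and the reported diameter structure", {
  dd <- c(0.2, 0.3, 0.4, 1, 2, 6)
  m_sp <- diameter_pair_ratio_map(dd, "SP_new", dt = 0.02)
  expect_equal(unname(diag(m_sp)), rep(1, 6), tolerance = 1e-12)
  expect_equal(m_sp, t(m_sp), tolerance = 1e-12)
  # corrected pool: ratios above 2 only with a sub-0.3-um member
  thick <- dd >= 0.4
  expect_true(all(m_sp[thick, thick] <= 2))
  expect_gt(max(m_sp[dd <= 0.3, thick]), 2)

  m_dm <- diameter_pair_ratio_map(dd, "DM", dt = 0.01)
  m_fd <- diameter_pair_ratio_map(dd, "DM_FD", dt = 0.01)
  # detailed dynamics: the >2 region reaches 1-um compartments
  expect_gt(m_dm[dd == 1, dd == 6], 2)
  expect_gt(m_fd[dd == 1, dd == 6], 2)
  # but not the thick-thick pairs
  expect_lt(m_dm[dd == 2, dd == 6], 2)
  # the two discretizations give closely matching maps
  expect_lt(max(abs(m_dm / m_fd - 1), na.rm = TRUE), 0.10)
})

test_that("detailed dynamics widen adjacent-branch ratios relative to the corrected pool", {
  comp <- compartmentalize(taper_tree(taper = 0.55, depth = 2), "one_per_segment")
  r_dm <- tree_adjacent_ratios(comp, "DM", dt = 0.02)
  r_sp <- tree_adjacent_ratios(comp, "SP_new", dt = 0.02)
  expect_gt(max(r_dm), max(r_sp))
  expect_gt(mean(r_dm), mean(r_sp))
})

test_that("coarse compartmentalization widens adjacent ratios on tapered trees", {
  tree <- taper_tree(taper = 0.55, depth = 2)
  c1 <- compartmentalize(tree, "one_per_segment")
  c2 <- compartmentalize(tree, "per_traced_point")
  r1 <- adjacent_ratios(c1$compartments$diam, c1$adjacency)
  r2 <- adjacent_ratios(c2$compartments$diam, c2$adjacency)
  expect_gt(max(r1), max(r2))
  expect_gt(mean(r1), mean(r2))
})
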