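test_that("equivalent depth follows the annular-volume correction", {
  expect_equal(equivalent_depth(0.1, 1.0), 0.09)
  expect_equal(equivalent_depth(0.1, 0.3), 0.1 - 0.01 / 0.3)
  # wide-compartment limit: correction vanishes
  expect_equal(equivalent_depth(0.1, 1e6), 0.1, tolerance = 1e-6)
  expect_lt(equivalent_depth(0.1, 1e6), 0.1)
  # always positive and below the nominal depth
  for (d in c(0.05, 0.1, 0.25)) {
    for (diam in c(0.3, 1, 6)) {
      if (d >= diam) next
      dq <- equivalent_depth(d, diam)
      expect_gt(dq, 0)
      expect_lt(dq, d)
    }
  }
  expect_error(equivalent_depth(0, 1), class = "dendroca_invalid_geometry")
  expect_error(equivalent_depth(-0.1, 1), class = "dendroca_invalid_geometry")
  expect_error(equivalent_depth(0.2, 0.2), class = "dendroca_invalid_geometry")
  expect_error(equivalent_depth(0.3, 0.2), class = "dendroca_invalid_geometry")
})

test_that("pool geometry matches the two volume conventions", {
  g <- compartment_geometry(1, 1)
  pn <- pool_geometry(g, 0.1, "SP_new")
  expect_equal(pn$Vol_s, pi * 0.1 * 0.9, tolerance = 1e-12)
  expect_equal(pn$SVR, 1 / (0.1 * 0.9), tolerance = 1e-12)
  po <- pool_geometry(g, 0.1, "SP_old")
  expect_equal(po$Vol_s, pi * 0.1, tolerance = 1e-12)
  expect_equal(po$SVR, 10)
  expect_equal(po$d_eq, 0.1)
  # legacy volume is always the larger one
  expect_gt(po$Vol_s, pn$Vol_s)
  # legacy SVR is diameter-independent; corrected SVR is not
  svr_old <- sapply(c(0.3, 1, 2, 6), function(dm)
    pool_geometry(compartment_geometry(dm, 1), 0.1, "SP_old")$SVR)
  expect_true(all(svr_old == svr_old[1]))
  svr_new <- sapply(c(0.3, 1, 2, 6), function(dm)
    pool_geometry(compartment_geometry(dm, 1), 0.1, "SP_new")$SVR)
  expect_true(all(diff(svr_new) < 0))
})

test_that("corrected shell volume equals surface area times equivalent depth", {
  # the algebraic identity motivating the equivalent depth
  for (diam in seq(0.25, 6, by = 0.37)) {
    for (d in c(0.05, 0.1, 0.169)) {
      if (d >= diam) next
      g <- compartment_geometry(diam, 2.5)
      pg <- pool_geometry(g, d, "SP_new")
      expect_equal(pg$Vol_s, g$SA * equivalent_depth(d, diam),
                   tolerance = 1e-12)
    }
  }
})

test_that("variable-depth stacks follow the shell-count and depth formulas", {
  st <- shells_variable_depth(compartment_geometry(0.6, 1), 0.1)
  expect_length(st$depths, 3L)
  expect_equal(st$d1, 0.075)
  st <- shells_variable_depth(compartment_geometry(1.0, 1), 0.1)
  expect_length(st$depths, 4L)
  expect_equal(st$d1, 1 / 12, tolerance = 1e-12)
  expect_equal(st$depths, c(1, 2, 2, 1) / 12, tolerance = 1e-12)
  st <- shells_variable_depth(compartment_geometry(2.0, 1), 0.1)
  expect_length(st$depths, 6L)
  expect_equal(st$d1, 0.1, tolerance = 1e-12)
  # too thin for two shells
  expect_error(shells_variable_depth(compartment_geometry(0.1, 1), 0.1),
               class = "dendroca_invalid_geometry")
})

test_that("fixed-depth stacks have constant depth with an adjusted core", {
  st <- shells_fixed_depth(compartment_geometry(1.0, 1), 0.1)
  expect_length(st$depths, 5L)
  expect_equal(st$depths, rep(0.1, 5), tolerance = 1e-12)
  st <- shells_fixed_depth(compartment_geometry(0.9, 1), 0.1)
  expect_length(st$depths, 5L)
  expect_equal(st$depths[5], 0.05, tolerance = 1e-12)
  # a compartment thinner than two nominal depths is one core shell
  st <- shells_fixed_depth(compartment_geometry(0.15, 1), 0.1)
  expect_length(st$depths, 1L)
  expect_equal(st$depths, 0.075)
  # float round-off near exact multiples must not create a zero-depth core
  st <- shells_fixed_depth(compartment_geometry(seq(0.1, 6, by = 0.1)[12], 1), 0.1)
  expect_length(st$depths, 6L)
  expect_true(all(st$depths > 0))
})

test_that("hybrid stacks fix the outer depth and split the rest equally", {
  st <- shells_hybrid_fd(compartment_geometry(1.0, 1), 0.1, 4)
  expect_equal(st$depths, c(0.1, rep(0.4 / 3, 3)), tolerance = 1e-12)
  st <- shells_hybrid_fd(compartment_geometry(0.4, 1), 0.1, 2)
  expect_equal(st$depths, c(0.1, 0.1), tolerance = 1e-12)
  st <- shells_hybrid_fd(compartment_geometry(6, 1), 0.1, 4)
  expect_equal(st$depths, c(0.1, rep(2.9 / 3, 3)), tolerance = 1e-12)
  expect_error(shells_hybrid_fd(compartment_geometry(0.2, 1), 0.1, 3),
               class = "dendroca_invalid_geometry")
})

test_that("all schemes close depth and volume budgets exactly", {
  L <- 1.7
  for (diam in seq(0.21, 6, by = 0.23)) {
    g <- compartment_geometry(diam, L)
    stacks <- list(shells_fixed_depth(g, 0.1))
    if (variable_depth_count(diam, 0.1) >= 2) {
      stacks <- c(stacks, list(shells_variable_depth(g, 0.1)))
    }
    if (diam / 2 > 0.1) {
      stacks <- c(stacks, list(shells_hybrid_fd(g, 0.1, 5)))
    }
    for (st in stacks) {
      expect_equal(sum(st$depths), diam / 2, tolerance = 1e-12)
      expect_equal(sum(st$volumes), g$Vol_f, tolerance = 1e-12)
      expect_true(all(st$depths > 0))
      # interface areas are lateral areas at the shared radii
      n <- length(st$depths)
      if (n > 1) {
        expect_equal(st$interface_areas, 2 * pi * st$r_in[-n] * L,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("variable-depth outer shell stays in the quarter band of the nominal depth", {
  d <- 0.1
  diams <- seq(0.2, 20, by = 0.001)
  n <- variable_depth_count(diams, d)
  d1 <- variable_depth_d1(diams, d)
  keep <- n >= 3
  expect_true(all(d1[keep] >= 0.75 * d))
  expect_true(all(d1[keep] < 1.25 * d))
})

test_that("shell counts are non-decreasing in diameter for both schemes", {
  diams <- seq(0.25, 8, by = 0.01)
  n_var <- variable_depth_count(diams, 0.1)
  n_fd <- sapply(diams, function(dm)
    length(shells_fixed_depth(compartment_geometry(dm, 1), 0.1)$depths))
  expect_true(all(diff(n_var) >= 0))
  expect_true(all(diff(n_fd) >= 0))
})

test_that("geometry audit tabulates both schemes per diameter", {
  aud <- geometry_audit(c(0.6, 1, 2), d = 0.1)
  expect_equal(aud$shells_dm, c(3L, 4L, 6L))
  expect_equal(aud$d1_dm, c(0.075, 1 / 12, 0.1), tolerance = 1e-12)
  expect_equal(aud$shells_dmfd, c(3L, 5L, 10L))
  expect_equal(aud$vol_um3, pi * c(0.6, 1, 2)^2 / 4, tolerance = 1e-12)
})
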