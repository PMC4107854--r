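test_that("zero influx holds the pool at rest", {
  wf <- current_waveform(c(0, 100), c(0, 0))
  for (diam in c(0.2, 1, 6)) {
    tr <- simulate_pool(compartment_geometry(diam, 1), pool_params(), wf,
                        dt = 0.02, t_end = 100)
    expect_true(all(tr$ca == REST))
  }
})

test_that("legacy pool is diameter-blind: identical influx gives bit-identical traces", {
  wf <- ghk_waveform(ramp_drive())
  tr1 <- simulate_pool(compartment_geometry(0.2, 1),
                       pool_params(variant = "SP_old"), wf)
  tr2 <- simulate_pool(compartment_geometry(6.0, 1),
                       pool_params(variant = "SP_old"), wf)
  expect_identical(tr1$ca, tr2$ca)
})

test_that("above-rest responses scale exactly as d over d_eq between conventions", {
  wf <- ghk_waveform(ramp_drive())
  for (diam in c(0.5, 1, 3)) {
    for (d in c(0.05, 0.169)) {
      po <- simulate_pool(compartment_geometry(diam, 1),
                          pool_params(d, 6.86, variant = "SP_old"), wf)
      pn <- simulate_pool(compartment_geometry(diam, 1),
                          pool_params(d, 6.86, variant = "SP_new"), wf)
      ratio <- (pn$ca[-1] - REST) / (po$ca[-1] - REST)
      expect_equal(max(abs(ratio - d / equivalent_depth(d, diam))), 0,
                   tolerance = 1e-9)
    }
  }
})

test_that("post-influx decay rate equals beta", {
  wf <- make_spike_burst_waveform(1, 10, 0.05, 1, t_end = 20)
  beta <- 0.1; dt <- 0.02
  tr <- simulate_pool(compartment_geometry(1, 1), pool_params(0.1, beta), wf,
                      dt = dt, t_end = 120)
  late <- tr$time > 25 & tr$time < 90   # influx long over, deviation resolvable
  dev <- log(tr$ca[late] - REST)
  slopes <- diff(dev) / dt
  expect_equal(max(abs(slopes + beta)) / beta, 0, tolerance = 1e-6)
})

test_that("self-consistent GHK coupling and prescribed influx agree closely at low calcium", {
  # the pool's own calcium stays far below external calcium, so clamping the
  # GHK concentration at rest changes the influx only marginally
  g <- compartment_geometry(1, 1)
  tr_c <- simulate_pool(g, pool_params(), ramp_drive())
  tr_p <- simulate_pool(g, pool_params(), ghk_waveform(ramp_drive()))
  expect_equal(max(tr_c$ca), max(tr_p$ca), tolerance = 2e-3)
})

test_that("peak-error grid shows the legacy underestimate and its depth dependence", {
  drv <- ramp_drive()
  # zero influx: both conventions peak at rest, error 0
  g0 <- peak_error_grid(1, 0.1, 6.86,
                        influx = current_waveform(c(0, 180), c(0, 0)))
  expect_equal(g0$error_pct, 0)
  # legacy always underestimates
  grid <- peak_error_grid(c(0.3, 0.5, 1, 2, 6), c(0.05, 0.1, 0.169), 6.86,
                          influx = drv)
  expect_true(all(grid$error_pct[grid$valid] <= 0))
  # |error| grows with depth at fixed diameter
  at1 <- grid[grid$diam == 1, ]
  expect_true(all(diff(abs(at1$error_pct[order(at1$d)])) > 0))
  # invalid geometry (depth >= diameter) is skipped and flagged
  gbad <- peak_error_grid(0.1, 0.15, 6.86, influx = drv)
  expect_false(gbad$valid)
  expect_true(is.na(gbad$error_pct))
})

test_that("large influx drives the peak error to the closed-form depth ratio", {
  # with peaks dwarfing rest, error -> d_eq/d - 1 = -25% at d = 0.05, diam = 0.2
  wf <- current_waveform(c(0, 50, 50.04, 100), c(-5, -5, 0, 0))
  grid <- peak_error_grid(0.2, 0.05, 6.86, influx = wf)
  expect_equal(grid$error_pct,
               100 * (equivalent_depth(0.05, 0.2) / 0.05 - 1),
               tolerance = 1e-3)
})
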