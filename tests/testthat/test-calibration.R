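# Coarse observable grids keep the optimization cheap in tests.
.coarse <- list(atp_grid = 10^seq(log10(1e-6), log10(3e-3), length.out = 7),
                activation_horizon_s = 4, activation_grid_s = 0.02,
                withdrawal_horizon_s = 50, withdrawal_grid_s = 0.1)

test_that("calibration is self-consistent when started at the truth", {
  g <- build_topology("WT")
  truth <- do.call(observable_vector, c(list(g), .coarse))
  targets <- list(
    calibration_target("po", truth$po, tolerance = 0.02),
    calibration_target("pdim", truth$pdim, tolerance = 0.02),
    calibration_target("dwell_ratio", truth$dwell_ratio, tolerance = 0.05))
  fit <- suppressWarnings(calibrate_rates(
    targets, g, free = c("k2", "k3"), restarts = 1L, maxit = 5L,
    atp_grid = .coarse$atp_grid,
    activation_horizon_s = .coarse$activation_horizon_s,
    activation_grid_s = .coarse$activation_grid_s,
    withdrawal_horizon_s = .coarse$withdrawal_horizon_s,
    withdrawal_grid_s = .coarse$withdrawal_grid_s))
  expect_lt(fit$objective, 1e-4)
  expect_equal(fit$rates[["k2"]], g$rates[["k2"]], tolerance = 0.01)
  expect_false(any(fit$report$missed))
})

test_that("perturbed starts recover the generating observables", {
  g <- build_topology("WT")
  truth <- do.call(observable_vector, c(list(g), .coarse))
  targets <- list(
    calibration_target("po", truth$po, tolerance = 0.02),
    calibration_target("pdim", truth$pdim, tolerance = 0.02),
    calibration_target("dwell_ratio", truth$dwell_ratio, tolerance = 0.05),
    calibration_target("tau_opening_s", truth$tau_opening_s, tolerance = 0.05))
  init <- g$rates
  init[c("k2", "k4")] <- init[c("k2", "k4")] * 3
  fit <- suppressWarnings(calibrate_rates(
    targets, g, init = init, free = c("k2", "k4"),
    restarts = 2L, seed = 7L, maxit = 60L,
    atp_grid = .coarse$atp_grid,
    activation_horizon_s = .coarse$activation_horizon_s,
    activation_grid_s = .coarse$activation_grid_s,
    withdrawal_horizon_s = .coarse$withdrawal_horizon_s,
    withdrawal_grid_s = .coarse$withdrawal_grid_s))
  got <- do.call(observable_vector,
                 c(list(g, rates = fit$rates), .coarse))
  for (nm in c("po", "pdim", "dwell_ratio", "tau_opening_s"))
    expect_equal(got[[nm]], truth[[nm]], tolerance = 0.05)
})

test_that("the objective is invariant to target order and seeded-deterministic", {
  g <- build_topology("WT")
  targets <- list(
    calibration_target("po", 0.25, tolerance = 0.05),
    calibration_target("pdim", 0.8, tolerance = 0.05),
    calibration_target("turnover_per_s", window = c(0.2, 1), tolerance = 0.25))
  args <- list(g, free = c("k3"), restarts = 2L, seed = 5L, maxit = 4L,
               atp_grid = .coarse$atp_grid,
               activation_horizon_s = .coarse$activation_horizon_s,
               activation_grid_s = .coarse$activation_grid_s,
               withdrawal_horizon_s = .coarse$withdrawal_horizon_s,
               withdrawal_grid_s = .coarse$withdrawal_grid_s)
  f1 <- suppressWarnings(do.call(calibrate_rates, c(list(targets), args)))
  f2 <- suppressWarnings(do.call(calibrate_rates, c(list(rev(targets)), args)))
  expect_equal(f1$objective, f2$objective, tolerance = 1e-12)
  expect_equal(f1$rates, f2$rates, tolerance = 1e-12)
})

test_that("target and bound validation raise errors", {
  expect_error(calibration_target("po"), "point targets")
  expect_error(calibration_target("po", window = c(2, 1)), "window")
  g <- build_topology("WT")
  expect_error(
    calibrate_rates(list(calibration_target("po", 0.2)), g,
                    free = "k2", bounds = list(k2 = c(5, 1))),
    "infeasible bounds")
})
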