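per_grid <- 10^seq(-1, 2, length.out = 9)

test_that("direct regulation is period- and shape-invariant in a sweep", {
  cfg <- direct_motif(std_y(), 0.75)
  sw <- period_sweep(cfg, "symmetric", per_grid)
  expect_equal(nrow(sw), length(per_grid))
  expect_lt(diff(range(sw$y_mean)) / mean(sw$y_mean), 1e-9)
  sh <- shape_sweep(cfg, period = 1)
  expect_equal(nrow(sh), 3L)
  expect_lt(diff(range(sh$y_mean)) / mean(sh$y_mean), 1e-9)
  expect_error(period_sweep(cfg, "symmetric", 1), "at least two")
})

test_that("two-step switching direction follows the threshold/mean ordering", {
  y <- std_y(); z <- std_z()
  # threshold above the intermediate mean (1.125): off at short periods
  swH <- period_sweep(two_step_motif(y, z, 0.1, 1.3), "symmetric", per_grid)
  expect_true(all(diff(swH$z_mean) >= -1e-12))
  expect_equal(swH$z_mean[1L], 0)            # basal equilibrium reached
  # threshold below the mean: fully expressed at short periods
  swL <- period_sweep(two_step_motif(y, z, 0.1, 0.5), "symmetric", per_grid)
  expect_true(all(diff(swL$z_mean) <= 1e-12))
  expect_equal(swL$z_mean[1L], 1.5)          # full on-equilibrium
})

test_that("regime classification assigns the four cases from the two orderings", {
  y <- std_y(); z <- std_z()
  expect_identical(classify_regime(ffl_motif(1, "AND", y, z, 0.1, 0.75, 0.5))$case, "A")
  expect_identical(classify_regime(ffl_motif(1, "AND", y, z, 0.1, 0.75, 1.3))$case, "B")
  expect_identical(classify_regime(ffl_motif(1, "AND", y, z, 0.75, 0.1, 0.2))$case, "C")
  expect_identical(classify_regime(ffl_motif(1, "AND", y, z, 0.75, 0.1, 0.6))$case, "D")
  expect_identical(classify_regime(ffl_motif(5, "AND", y, z, 0.75, 0.1, 0.6))$case, "D")
  # degenerate ordering: explicit boundary, not a silent pick
  expect_identical(classify_regime(ffl_motif(1, "AND", y, z, 0.5, 0.5, 1.3))$case,
                   "boundary")
  expect_error(classify_regime(direct_motif(y, 0.5)), "FFL")
})

test_that("assigned regimes are consistent with the computed sweeps", {
  y <- std_y(); z <- std_z()
  # case A: flat in period
  cfgA <- ffl_motif(1, "AND", y, z, 0.1, 0.75, 0.5)
  swA <- period_sweep(cfgA, "symmetric", per_grid)
  expect_lt(diff(range(swA$z_mean)), 1e-9)
  # case B: off at short periods, saturates to the direct-branch value
  cfgB <- ffl_motif(1, "AND", y, z, 0.1, 0.75, 1.3)
  swB <- period_sweep(cfgB, "symmetric", per_grid)
  expect_equal(swB$z_mean[1L], 0)
  expect_equal(swB$z_mean[length(per_grid)],
               stationary_mean(0.25, z), tolerance = 1e-6)
  # case C: response grows as the period shrinks
  cfgC <- ffl_motif(1, "AND", y, z, 0.75, 0.1, 0.2)
  swC <- period_sweep(cfgC, "symmetric", per_grid)
  expect_gt(swC$z_mean[1L], swC$z_mean[length(per_grid)])
  # case D (IFFL-1): repression ceases at short periods
  cfgD <- ffl_motif(5, "AND", y, z, 0.75, 0.1, 0.6)
  swD <- period_sweep(cfgD, "symmetric", per_grid)
  expect_gt(swD$z_mean[1L], swD$z_mean[length(per_grid)])
})

test_that("shape has no effect in case A but matters in case B", {
  y <- std_y(); z <- std_z()
  shA <- shape_sweep(ffl_motif(1, "AND", y, z, 0.1, 0.75, 0.5), period = 1)
  expect_lt(diff(range(shA$z_mean)), 1e-9)
  cfgB <- ffl_motif(1, "AND", y, z, 0.1, 0.75, 1.3)
  # near the switching period the transition sharpness depends on the shape
  diffs <- vapply(c(0.7, 1, 1.5, 2), function(T)
    diff(range(shape_sweep(cfgB, period = T)$z_mean)), 0)
  expect_gt(max(diffs), 1e-3)
})

test_that("step responses: sign-sensitive delay, pulse counts and the two-path delay cross-check", {
  y <- std_y(); z <- std_z()
  cffl <- ffl_motif(1, "AND", y, z, 0.5, 0.5, 0.75)
  r <- step_response(cffl, step_signal(1, 6))
  expect_identical(r$off_delay, 0)
  expect_gt(r$on_delay, 0)
  expect_equal(r$on_delay, onset_delay(0, 1.5, 0.75, 1), tolerance = 1e-10)
  iffl <- ffl_motif(5, "AND", y, z, 0.5, 0.5, 0.75)
  r2 <- step_response(iffl, step_signal(1, 20))
  expect_identical(r2$n_pulses, 1L)
  # a step too short for Y to reach the gate threshold: no pulse, no error
  r3 <- step_response(cffl, step_signal(1, 1.2))
  expect_identical(r3$n_pulses, 0L)
  expect_true(is.na(r3$on_delay))
  expect_error(step_response(direct_motif(y, 0.5), step_signal(1, 2)), "FFL")
})
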