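test_that("analytic trajectories agree with the ODE oracle on a spot-check grid", {
  y <- std_y(); z <- std_z()
  cfgs <- list(direct = direct_motif(y, 0.75),
               two_step = two_step_motif(y, z, 0.1, 0.8),
               cffl1 = ffl_motif(1, "AND", y, z, 0.1, 0.75, 0.8),
               iffl1_or = ffl_motif(5, "OR", y, z, 0.75, 0.1, 0.6))
  for (nm in names(cfgs)) {
    d <- compare_with_oracle(cfgs[[nm]], periodic_signal("symmetric", 1), 6)
    expect_lt(max(d), 1e-7, label = paste(nm, "discrepancy"))
  }
})

test_that("CFFL-1 AND under a step shows the sign-sensitive delay", {
  y <- std_y(); z <- std_z()
  cfg <- ffl_motif(1, "AND", y, z, 0.5, 0.5, 0.75)
  step <- step_signal(1, 6)
  sim <- simulate_motif(cfg, step, 12)
  gate <- trace_intervals(sim$traces$gate)
  on <- gate[gate$state == 1L, ]
  expect_equal(nrow(on), 1L)
  # Z synthesis starts after the delay needed for Y to accumulate to k_yz
  d <- onset_delay(0, 1.5, 0.75, 1)
  expect_equal(on$start, 1 + d, tolerance = 1e-10)
  # and stops at the very instant the stimulus ends
  expect_identical(on$end, 6)
})

test_that("IFFL-1 AND is a pulse generator under a sustained step and an oscillation detector under periodic drive", {
  y <- std_y(); z <- std_z()
  cfg <- ffl_motif(5, "AND", y, z, 0.5, 0.5, 0.75)
  sim <- simulate_motif(cfg, step_signal(1, 20), 25)
  gate <- trace_intervals(sim$traces$gate)
  expect_equal(sum(gate$state == 1L), 1L)
  # periodic input: one expression pulse every cycle at stationarity
  cfg2 <- ffl_motif(5, "AND", y, z, 0.75, 0.1, 0.4)
  ms <- motif_stationary(cfg2, periodic_signal("symmetric", 1))
  on <- trace_intervals(ms$traces$gate)
  expect_equal(sum(on$state == 1L), 1L)
  expect_gt(ms$stats$Z$mean, 0)
})

test_that("stationary means are independent of period and shape for direct regulation", {
  y <- std_y()
  cfg <- direct_motif(y, 0.75)
  means <- c()
  for (lbl in canonical_labels)
    for (T in c(0.5, 1, 3))
      means <- c(means, motif_stationary(cfg,
                   periodic_signal(lbl, T))$stats$Y$mean)
  expect_lt(diff(range(means)) / mean(means), 1e-9)
  expect_equal(means[1], stationary_mean(0.25, y), tolerance = 1e-12)
})

test_that("stationary analysis requires a periodic input", {
  cfg <- direct_motif(std_y(), 0.5)
  expect_error(motif_stationary(cfg, step_signal(0, 5)), "periodic")
})

test_that("the CFFL-1 mean never exceeds the direct-branch duty cap", {
  y <- std_y(); z <- std_z()
  cfg <- ffl_motif(1, "AND", y, z, 0.1, 0.75, 0.5)
  cap <- stationary_mean(0.25, z)   # duty of X above k_xz = 0.75
  for (T in 10^seq(-1, 2, length.out = 7)) {
    m <- motif_stationary(cfg, periodic_signal("symmetric", T))$stats$Z$mean
    expect_lte(m, cap + 1e-12)
  }
})

test_that("intermediate onset/offset delays populate when Y crosses its gate threshold once", {
  y <- std_y(); z <- std_z()
  cfg <- two_step_motif(y, z, 0.1, 1.1)
  ms <- motif_stationary(cfg, periodic_signal("symmetric", 1))
  s <- ms$stats$Y
  expect_gt(s$onset_delay, 0)
  expect_gt(s$offset_delay, 0)
  expect_equal(s$duty_out,
               downstream_duty(s, 1.1, y, 1), tolerance = 1e-9)
})
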