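test_that("propagation from equilibrium stays at equilibrium and relaxes toward asymptotes", {
  y <- std_y()
  w <- c(0, 20)
  on <- synthesis_rate_trace(y, digital_trace(numeric(), 1L, w))
  traj <- propagate(1.5, on, y$degradation)
  t <- seq(0, 20, length.out = 50)
  expect_equal(pwexp_value(traj, t), rep(1.5, 50))
  # long window under constant drive ends within e^-10 of the asymptote
  traj0 <- propagate(0, on, y$degradation)
  expect_lt(abs(pwexp_value(traj0, 20) - 1.5), 1.5 * exp(-10))
  expect_error(propagate(-0.1, on, y$degradation), "non-negative")
})

test_that("a single on-pulse matches numerical integration to high accuracy", {
  y <- std_y()
  cfg <- direct_motif(y, 0.5)
  inp <- step_signal(1, 3)
  sim <- simulate_motif(cfg, inp, 8)
  ode <- integrate_step_model(cfg, inp, c(0, 8), n_out = 400)
  rel <- max(abs(pwexp_value(sim$trajectories$Y, ode$time) - ode$y)) /
    max(abs(ode$y))
  expect_lt(rel, 1e-8)
})

test_that("the stationary cycle is an exact fixed point of the period map", {
  y <- std_y()
  for (T in c(0.5, 1, 3)) {
    dr <- digitize(periodic_signal("symmetric", T), 0.75, c(0, T))
    cyc <- stationary_cycle(dr, y, T)
    expect_equal(pwexp_value(cyc, 0), pwexp_value(cyc, T), tolerance = 1e-13)
  }
  # duty-1 drive gives the on-equilibrium, constant
  full <- digital_trace(numeric(), 1L, c(0, 1))
  cyc <- stationary_cycle(full, y, 1)
  expect_equal(attr(cyc, "stats")$mean, 1.5)
  expect_equal(attr(cyc, "stats")$y_min, 1.5)
})

test_that("closed-form square-wave extrema agree with the event-driven cycle", {
  y <- gene_stage("Y", 0.2, 1.2, 0.7)
  for (f in c(0.25, 0.5, 0.75)) {
    for (T in c(0.3, 1, 5)) {
      dr <- digitize(square_wave(f, T), 0.5, c(0, T))
      st <- attr(stationary_cycle(dr, y, T), "stats")
      ex <- stationary_extrema(y, f, T)
      expect_equal(st$y_max, ex$y_max, tolerance = 1e-12)
      expect_equal(st$y_min, ex$y_min, tolerance = 1e-12)
      expect_equal(st$mean, ex$mean, tolerance = 1e-12)
    }
  }
})

test_that("cycle maximum rises and minimum falls with the period", {
  y <- std_y()
  periods <- 10^seq(-1, 1.5, length.out = 10)
  ex <- lapply(periods, function(T) stationary_extrema(y, 0.25, T))
  ymax <- vapply(ex, `[[`, 0, "y_max")
  ymin <- vapply(ex, `[[`, 0, "y_min")
  expect_true(all(diff(ymax) > 0))
  expect_true(all(diff(ymin) < 0))
})

test_that("extrema collapse to the duty-weighted mean at short periods and to the equilibria at long ones", {
  y <- std_y()
  m <- stationary_mean(0.25, y)
  ex0 <- stationary_extrema(y, 0.25, 1e-3)
  expect_equal(ex0$y_max, m, tolerance = 1e-3)
  expect_equal(ex0$y_min, m, tolerance = 1e-3)
  exI <- stationary_extrema(y, 0.25, 1e3)
  expect_equal(exI$y_max, 1.5, tolerance = 1e-9)
  expect_equal(exI$y_min, 0, tolerance = 1e-9)
})

test_that("the stationary mean is the duty-weighted equilibrium average and the exact cycle integral", {
  y <- gene_stage("Y", 0.3, 1.2, 0.8)
  expect_equal(stationary_mean(0, y), 0.3 / 0.8)
  expect_equal(stationary_mean(1, y), 1.2 / 0.8)
  for (lbl in canonical_labels) {
    dr <- digitize(periodic_signal(lbl, 1), 0.75, c(0, 1))
    cyc <- stationary_cycle(dr, y, 1)
    expect_equal(attr(cyc, "stats")$mean, stationary_mean(0.25, y),
                 tolerance = 1e-9)
  }
})

test_that("onset delay is exact against a root-finding oracle and flags unreachable thresholds", {
  y <- std_y()
  expect_equal(onset_delay(0.4, 1.5, 0.4, 1), 0)
  expect_error(onset_delay(0.4, 1.5, 1.5, 1), "never crosses")
  expect_error(onset_delay(0.4, 1.5, 1.7, 1), "never crosses")
  rt <- synthesis_rate_trace(y, digital_trace(numeric(), 1L, c(0, 10)))
  for (thr in c(0.5, 1.0, 1.4)) {
    d <- onset_delay(0.2, 1.5, thr, 1)
    traj <- propagate(0.2, rt, 1)
    root <- stats::uniroot(function(t) pwexp_value(traj, t) - thr,
                           c(0, 10), tol = 1e-14)$root
    expect_lt(abs(d - root), 1e-10)
    expect_equal(pwexp_value(traj, d), thr, tolerance = 1e-12)
  }
})

test_that("downstream duty matches event-driven measurement and saturates correctly", {
  y <- std_y()
  dr <- digitize(periodic_signal("symmetric", 1), 0.1, c(0, 1))
  cyc <- stationary_cycle(dr, y, 1)
  st <- attr(cyc, "stats")
  expect_equal(downstream_duty(st, st$y_min * 0.9, y, 1), 1)
  expect_equal(downstream_duty(st, st$y_max * 1.1, y, 1), 0)
  for (thr in c(1.0, 1.1, 1.2)) {
    dd <- downstream_duty(st, thr, y, 1)
    meas <- trace_duty(digitize(cyc, thr, c(0, 1)))
    expect_lt(abs(dd - meas), 1e-9)
  }
})

test_that("the closed-form duty refuses drives with multiple crossings per cycle", {
  y <- std_y()
  dr <- digital_trace(c(0.1, 0.3, 0.5, 0.7), 0L, c(0, 1))
  cyc <- stationary_cycle(dr, y, 1)
  expect_error(downstream_duty(attr(cyc, "stats"), 0.4, y, 1),
               "event-driven")
})

test_that("piecewise-exponential crossings honour junction equalities exactly", {
  y <- std_y()
  dr <- digital_trace(c(0.25, 0.75), 0L, c(0, 2))
  traj <- propagate(0.5, synthesis_rate_trace(y, dr), 1)
  # threshold exactly at the initial value: the first event is at t = 0
  cr <- pwexp_crossings(traj, pwexp_value(traj, 1.0), c(0, 2))
  expect_true(all(diff(cr$time) > 0))
  expect_true(all(cr$direction %in% c("up", "down")))
})
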