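test_that("the step-model integrator reproduces the exponential closed form under constant drive", {
  y <- std_y()
  cfg <- direct_motif(y, 0.5)
  # input permanently above threshold: Y relaxes toward 1.5
  inp <- step_signal(-1, 100)
  ode <- integrate_step_model(cfg, inp, c(0, 5), n_out = 200)
  exact <- 1.5 * (1 - exp(-ode$time))
  expect_lt(max(abs(ode$y - exact)), 1e-8)
  # zero synthesis everywhere: pure decay from the initial value
  inp0 <- step_signal(90, 100)
  ode0 <- integrate_step_model(cfg, inp0, c(0, 5), initial = c(Y = 2),
                               n_out = 200)
  expect_lt(max(abs(ode0$y - 2 * exp(-ode0$time))), 1e-8)
})

test_that("the oracle's accumulated integral matches the analytic segment integrals", {
  y <- std_y()
  cfg <- direct_motif(y, 0.75)
  s <- periodic_signal("left_skewed", 1)
  ode <- integrate_step_model(cfg, s, c(0, 4))
  sim <- simulate_motif(cfg, s, 4)
  expect_equal(ode$integrals$Y, pwexp_integral(sim$trajectories$Y),
               tolerance = 1e-9)
})

test_that("a Hill exponent of 1 at the half-activation point gives half-maximal synthesis", {
  y <- std_y()
  cfg <- direct_motif(y, 0.5)
  inp <- step_signal(-1, 1e3, level = 0.5)   # input pinned at K
  h <- integrate_hill_model(cfg, inp, c(0, 40), exponent = 1)
  # steady state: (b0 + (b1-b0)/2) / alpha = 0.75
  expect_equal(h$y[length(h$y)], 0.75, tolerance = 1e-6)
})

test_that("the Hill model converges monotonically to the step model as the exponent grows", {
  y <- std_y()
  cfg <- direct_motif(y, 0.75)
  s <- periodic_signal("symmetric", 1)
  step <- integrate_step_model(cfg, s, c(0, 6), n_out = 400)
  devs <- vapply(c(2, 5, 10, 50), function(n) {
    h <- integrate_hill_model(cfg, s, c(0, 6), exponent = n, n_out = 400)
    yh <- stats::approx(h$time, h$y, xout = step$time, rule = 2)$y
    max(abs(yh - step$y)) / max(abs(step$y))
  }, 0)
  expect_true(all(diff(devs) < 0))
  # very large exponent: close to the step model
  h <- integrate_hill_model(cfg, s, c(0, 6), exponent = 1e3, n_out = 400)
  yh <- stats::approx(h$time, h$y, xout = step$time, rule = 2)$y
  expect_lt(max(abs(yh - step$y)) / max(abs(step$y)), 1e-2)
})

test_that("the Hill stationary mean approaches the duty-weighted mean for large exponents", {
  y <- std_y()
  cfg <- direct_motif(y, 0.75)
  s <- periodic_signal("symmetric", 1)
  h <- integrate_hill_model(cfg, s, c(0, 60), exponent = 200, n_out = 2000)
  sel <- h$time >= 20
  avg <- mean(h$y[sel])   # crude cycle average over the stationary tail
  expect_equal(avg, stationary_mean(0.25, y), tolerance = 0.02)
})

test_that("the Hill variant rejects unsupported configurations", {
  y <- std_y(); z <- std_z()
  cfg2 <- two_step_motif(y, z, 0.1, 0.8)
  expect_error(integrate_hill_model(cfg2, periodic_signal("symmetric", 1),
                                    c(0, 2)), "direct regulation")
  cfg <- direct_motif(y, 0.5)
  expect_error(integrate_hill_model(cfg, periodic_signal("symmetric", 1),
                                    c(0, 2), exponent = 0.5), ">= 1")
})
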