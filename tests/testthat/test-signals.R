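test_that("canonical profiles pass through their anchors and keep the printed duty structure", {
  for (lbl in canonical_labels) {
    p <- canonical_profile(lbl)
    a <- p$anchors
    expect_equal(profile_value(p, a[, "time"]), unname(a[, "value"]),
                 tolerance = 1e-12, info = lbl)
    s <- periodic_signal(p, 1)
    expect_equal(duty_fraction(s, 0.1), 0.75, tolerance = 1e-9)
    expect_equal(duty_fraction(s, 0.75), 0.25, tolerance = 1e-9)
  }
  # left-skewed peak is an anchor; value between peak and the 0.75 anchor
  # stays bracketed by monotonicity
  p <- canonical_profile("left_skewed")
  expect_identical(profile_value(p, 0.1333), 1)
  v <- profile_value(p, 0.2)
  expect_gt(v, 0.75); expect_lt(v, 1)
  expect_identical(profile_value(p, 0), 0)
})

test_that("profile construction rejects malformed anchor lists with a pointed diagnostic", {
  expect_error(anchor_profile(cbind(c(0, 0.5, 0.4, 1), c(0, 1, 0.5, 0))),
               "strictly increasing.*#3")
  expect_error(anchor_profile(cbind(c(0, 0.5, 1), c(0, 1.4, 0))),
               "\\[0,1\\].*#2")
  expect_error(anchor_profile(cbind(c(0, 1), c(0, 0))), "at least 3")
  expect_error(anchor_profile(cbind(c(0, 0.5, 1), c(0.2, 1, 0))),
               "first and last")
  expect_error(anchor_profile(cbind(c(0.1, 0.5, 1), c(0, 1, 0))),
               "start at 0")
})

test_that("profile interpolation never leaves [0,1] on a dense grid", {
  g <- seq(0, 1, length.out = 1e6)
  for (lbl in canonical_labels) {
    v <- profile_value(canonical_profile(lbl), g)
    expect_gte(min(v), 0)
    expect_lte(max(v), 1)
  }
})

test_that("crossing times are exact at anchor-coincident thresholds", {
  s <- periodic_signal("left_skewed", 1)
  cr <- crossing_times(s, 0.1, c(0, 1))
  expect_equal(cr$time, c(0.05, 0.80), tolerance = 1e-12)
  expect_equal(cr$direction, c("up", "down"))
  # directions alternate and sign is constant between events over 3 cycles
  cr3 <- crossing_times(s, 0.1, c(0, 3))
  expect_true(all(diff(cr3$time) > 0))
  expect_true(all(cr3$direction == rep(c("up", "down"), 3)))
})

test_that("root-refined crossings match a dense-grid sign-change oracle", {
  s <- periodic_signal("symmetric", 1)
  cr <- crossing_times(s, 0.5, c(0, 1))
  expect_equal(nrow(cr), 2L)
  g <- seq(0, 1, by = 1e-5)
  v <- signal_value(s, g) - 0.5
  idx <- which(v[-length(v)] * v[-1L] < 0)
  brackets <- g[idx]
  for (i in seq_len(nrow(cr)))
    expect_lt(abs(cr$time[i] - brackets[i]), 1e-5)
  # between consecutive events the sign of signal - threshold is constant
  mids <- c(mean(c(0, cr$time[1L])), mean(cr$time),
            mean(c(cr$time[2L], 1)))
  expect_equal(sign(signal_value(s, mids) - 0.5), c(-1, 1, -1))
})

test_that("thresholds outside the signal range give empty crossings and saturated duty", {
  s <- periodic_signal("right_skewed", 2)
  expect_equal(nrow(crossing_times(s, 1.5, c(0, 4))), 0L)
  expect_equal(duty_fraction(s, 1.5), 0)
})

test_that("stretching the period rescales crossings linearly and leaves duty invariant", {
  for (T in c(0.5, 3)) {
    s <- periodic_signal("left_skewed", T)
    cr <- crossing_times(s, 0.1, c(0, T))
    expect_equal(cr$time, c(0.05, 0.80) * T, tolerance = 1e-12)
    expect_equal(duty_fraction(s, 0.1), 0.75, tolerance = 1e-9)
    expect_equal(duty_fraction(s, 0.75), 0.25, tolerance = 1e-9)
  }
})

test_that("square waves have the declared duty and evenly spaced up-crossings", {
  sq <- square_wave(0.25, 1)
  expect_equal(duty_fraction(sq, 0.5), 0.25)
  sq2 <- square_wave(0.5, 2)
  cr <- crossing_times(sq2, 0.5, c(0, 8))
  ups <- cr$time[cr$direction == "up"]
  expect_equal(diff(ups), rep(2, length(ups) - 1L))
  expect_error(square_wave(1.2, 1), "strictly inside")
})

test_that("step signals are level on [on, off) and zero elsewhere", {
  st <- step_signal(1, 5, level = 0.8)
  expect_equal(signal_value(st, c(0.5, 1, 3, 5, 6)), c(0, 0.8, 0.8, 0, 0))
  cr <- crossing_times(st, 0.4, c(0, 10))
  expect_equal(cr$time, c(1, 5))
  expect_equal(cr$direction, c("up", "down"))
})
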