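#' Exact piecewise-exponential solution of a driven gene
#'
#' Between synthesis-rate switches, a linearly degraded gene obeys
#' `dy/dt = beta - alpha * y` with constant `beta`, whose solution relaxes
#' exponentially toward the equilibrium `beta/alpha`.  `propagate()` chains
#' these closed-form segments across a piecewise-constant rate trace,
#' producing the exact trajectory with no numerical integration: each
#' segment evaluates as
#' `asymptote + (start_value - asymptote) * exp(-rate * (t - start))`.
#'
#' @param initial_value concentration at the start of the window, >= 0.
#' @param rate_trace a [synthesis_rate_trace()].
#' @param degradation first-order decay rate, 1/hour, > 0.
#' @return object of class `pwexp_trajectory`: a data.frame of segments with
#'   columns `start`, `end`, `asymptote`, `start_value`, `rate`, plus a
#'   `window` attribute.
#' @export
propagate <- function(initial_value, rate_trace, degradation) {
  stopifnot(inherits(rate_trace, "rate_trace"))
  if (!(is.numeric(degradation) && degradation > 0))
    stop("degradation must be strictly positive")
  if (!(is.numeric(initial_value) && initial_value >= 0))
    stop("initial value must be non-negative")
  b <- rate_trace$breaks
  n <- length(b) - 1L
  m <- rate_trace$rates / degradation
  y <- numeric(n + 1L)
  y[1L] <- initial_value
  d <- diff(b)
  for (i in seq_len(n))
    y[i + 1L] <- m[i] + (y[i] - m[i]) * exp(-degradation * d[i])
  seg <- data.frame(start = b[-(n + 1L)], end = b[-1L], asymptote = m,
                    start_value = y[-(n + 1L)], rate = degradation)
  structure(seg, window = rate_trace$window,
            class = c("pwexp_trajectory", "data.frame"))
}

#' Evaluate a piecewise-exponential trajectory
#'
#' @param traj a `pwexp_trajectory`.
#' @param t times within the trajectory window (clamped to it).
#' @return numeric concentrations.
#' @export
pwexp_value <- function(traj, t) {
  stopifnot(inherits(traj, "pwexp_trajectory"))
  w <- attr(traj, "window")
  t <- pmin(pmax(t, w[1L]), w[2L])
  i <- pmin(pmax(findInterval(t, traj$start), 1L), nrow(traj))
  traj$asymptote[i] + (traj$start_value[i] - traj$asymptote[i]) *
    exp(-traj$rate[i] * (t - traj$start[i]))
}

#' Exact time integral of a piecewise-exponential trajectory
#'
#' Closed-form segment integrals (no quadrature).
#'
#' @param traj a `pwexp_trajectory`.
#' @return the integral of the trajectory over its whole window.
#' @export
pwexp_integral <- function(traj) {
  stopifnot(inherits(traj, "pwexp_trajectory"))
  d <- traj$end - traj$start
  sum(traj$asymptote * d +
        (traj$start_value - traj$asymptote) *
        (1 - exp(-traj$rate * d)) / traj$rate)
}

# final value of the trajectory (continuity: end of last segment)
.pwexp_end <- function(traj) {
  n <- nrow(traj)
  traj$asymptote[n] + (traj$start_value[n] - traj$asymptote[n]) *
    exp(-traj$rate[n] * (traj$end[n] - traj$start[n]))
}

#' Threshold crossings of a piecewise-exponential trajectory
#'
#' Each segment is a monotone exponential, so crossing times have the closed
#' form `t = start + log((start_value - asymptote)/(threshold - asymptote)) /
#' rate`; junction values exactly at the threshold are honoured exactly.
#'
#' @param traj a `pwexp_trajectory`.
#' @param threshold concentration threshold.
#' @param window optional sub-window (defaults to the trajectory window);
#'   crossings strictly inside it are reported.
#' @return data.frame with columns `time`, `direction` (`"up"`/`"down"`).
#' @export
pwexp_crossings <- function(traj, threshold, window = attr(traj, "window")) {
  stopifnot(inherits(traj, "pwexp_trajectory"))
  .window_check(window)
  yend <- numeric(nrow(traj))
  cand <- numeric()
  for (i in seq_len(nrow(traj))) {
    m <- traj$asymptote[i]; y0 <- traj$start_value[i]
    al <- traj$rate[i]
    d <- traj$end[i] - traj$start[i]
    y1 <- m + (y0 - m) * exp(-al * d)
    yend[i] <- y1
    if (y0 == threshold) cand <- c(cand, traj$start[i])
    if ((y0 - threshold) * (y1 - threshold) < 0) {
      dt <- log((y0 - m) / (threshold - m)) / al
      cand <- c(cand, traj$start[i] + dt)
    }
  }
  if (yend[length(yend)] == threshold) cand <- c(cand, traj$end[nrow(traj)])
  w <- attr(traj, "window")
  nodes <- sort(unique(c(w[1L], cand, w[2L])))
  mids <- (nodes[-length(nodes)] + nodes[-1L]) / 2
  above <- pwexp_value(traj, mids) > threshold
  flips <- which(diff(above) != 0L) + 1L
  times <- nodes[flips]
  dirs <- ifelse(above[flips], "up", "down")
  keep <- times > window[1L] & times < window[2L]
  data.frame(time = times[keep], direction = dirs[keep],
             stringsAsFactors = FALSE)
}

#' @export
print.pwexp_trajectory <- function(x, ...) {
  w <- attr(x, "window")
  cat("<pwexp_trajectory>", nrow(x), "segments on [", w[1L], ",", w[2L],
      "]\n")
  invisible(x)
}

#' @export
plot.pwexp_trajectory <- function(x, n = 1000, ...) {
  w <- attr(x, "window")
  t <- sort(unique(c(seq(w[1L], w[2L], length.out = n), x$start, x$end)))
  graphics::plot(t, pwexp_value(x, t), type = "l", xlab = "time (h)",
                 ylab = "concentration", ...)
  invisible(x)
}

#' Stationary one-period cycle of a periodically driven gene
#'
#' Under a periodic digital drive the gene settles, after a transient, onto
#' a periodic orbit.  Because each constant-rate segment acts affinely on
#' the concentration, the one-period return map is affine,
#' `y(T) = A + B y(0)` with `B = exp(-degradation * T)`, and the stationary
#' cycle is obtained exactly as its fixed point `y* = A / (1 - B)` -- no
#' burn-in simulation.
#'
#' @param drive a [digital_trace()] spanning exactly one period.
#' @param stage the responding [gene_stage()].
#' @param period drive period, hours.
#' @return a `pwexp_trajectory` over one period satisfying
#'   `value(0) == value(period)` exactly, with attribute `stats` holding
#'   `mean`, `y_min`, `y_max`, `duty_in` and `dimensionless_period`.
#' @export
stationary_cycle <- function(drive, stage, period) {
  stopifnot(inherits(drive, "digital_trace"), inherits(stage, "gene_stage"))
  if (diff(drive$window) <= 0)
    stop("drive window is empty")
  if (abs(diff(drive$window) - period) > 1e-9 * period)
    stop("drive window must span exactly one period")
  al <- stage$degradation
  rt <- synthesis_rate_trace(stage, drive)
  A <- .pwexp_end(propagate(0, rt, al))
  B <- exp(-al * period)
  ystar <- A / (1 - B)
  traj <- propagate(ystar, rt, al)
  vals <- c(traj$start_value, .pwexp_end(traj))
  duty_in <- trace_duty(drive)
  stats <- list(mean = pwexp_integral(traj) / period,
                y_min = min(vals), y_max = max(vals),
                duty_in = duty_in,
                n_switches = length(drive$times),
                dimensionless_period = period * al)
  structure(traj, stats = stats,
            class = c("stationary_cycle", class(traj)))
}

#' Stationary mean expression under a given drive duty
#'
#' The time-averaged stationary expression of a directly driven gene is the
#' duty-weighted average of its two equilibria:
#' `(1 - duty) * synth_off/degradation + duty * synth_on/degradation`.
#' It equals the exact integral of the stationary cycle divided by the
#' period and is therefore independent of the drive period and shape at
#' fixed duty.
#'
#' @param duty_in fraction of the cycle the drive is on, in \[0,1\].
#' @param stage a [gene_stage()].
#' @return stationary mean concentration.
#' @export
stationary_mean <- function(duty_in, stage) {
  stopifnot(is.numeric(duty_in), duty_in >= 0, duty_in <= 1,
            inherits(stage, "gene_stage"))
  eq <- .equilibria(stage)
  (1 - duty_in) * eq[["off"]] + duty_in * eq[["on"]]
}

#' Closed-form stationary cycle extrema under a single-crossing drive
#'
#' For a periodic drive that is on for `duty_in * period` and off for the
#' remainder of each cycle (one up and one down switch per cycle), the
#' stationary maximum and minimum follow from the two-exponential
#' self-consistency conditions: with `a = exp(-alpha * duty * T)`,
#' `b = exp(-alpha * (1-duty) * T)` and equilibria `y1 = synth_on/alpha`,
#' `y0 = synth_off/alpha`,
#' `y_max = (y1 (1-a) + y0 a (1-b)) / (1 - a b)` and
#' `y_min = (y0 (1-b) + y1 b (1-a)) / (1 - a b)`.
#' The maximum increases and the minimum decreases with the period; both
#' tend to the duty-weighted mean as the dimensionless period goes to 0 and
#' to the on/off equilibria as it grows.
#'
#' @param stage a [gene_stage()].
#' @param duty_in on-fraction of the drive, in (0,1).
#' @param period drive period, hours.
#' @return list with `y_max`, `y_min`, `mean` and `dimensionless_period`.
#' @export
stationary_extrema <- function(stage, duty_in, period) {
  stopifnot(inherits(stage, "gene_stage"), period > 0)
  if (!(duty_in > 0 && duty_in < 1))
    stop("duty_in must lie strictly inside (0,1)")
  al <- stage$degradation
  eq <- .equilibria(stage)
  a <- exp(-al * duty_in * period)
  b <- exp(-al * (1 - duty_in) * period)
  den <- 1 - a * b
  hi <- max(eq); lo <- min(eq)
  ymax <- (hi * (1 - a) + lo * a * (1 - b)) / den
  ymin <- (lo * (1 - b) + hi * b * (1 - a)) / den
  if (stage$synth_on < stage$synth_off) {  # inhibitor drive: roles swap
    a2 <- exp(-al * (1 - duty_in) * period)
    b2 <- exp(-al * duty_in * period)
    den <- 1 - a2 * b2
    ymax <- (hi * (1 - a2) + lo * a2 * (1 - b2)) / den
    ymin <- (lo * (1 - b2) + hi * b2 * (1 - a2)) / den
  }
  list(y_max = ymax, y_min = ymin,
       mean = stationary_mean(duty_in, stage),
       dimensionless_period = al * period)
}

#' Closed-form delay to reach a threshold along one relaxation branch
#'
#' Time for an exponential relaxation from `y_start` toward `asymptote` to
#' reach `threshold`:
#' `log((asymptote - y_start) / (asymptote - threshold)) / degradation`,
#' valid for both rising and falling branches.  Diverges logarithmically as
#' the threshold approaches the asymptote.
#'
#' @param y_start concentration at the start of the branch.
#' @param asymptote equilibrium the branch relaxes toward.
#' @param threshold level to be reached.
#' @param degradation relaxation rate, 1/hour.
#' @return delay in hours (0 if `threshold == y_start`).
#' @export
onset_delay <- function(y_start, asymptote, threshold, degradation) {
  stopifnot(degradation > 0)
  if (threshold == y_start) return(0)
  if ((asymptote - threshold) * (threshold - y_start) <= 0)
    stop("trajectory never crosses the threshold: ", format(threshold),
         " does not lie strictly between start ", format(y_start),
         " and asymptote ", format(asymptote))
  log((asymptote - y_start) / (asymptote - threshold)) / degradation
}

#' Duty fraction of the intermediate gene above a downstream threshold
#'
#' In a cascade the intermediate Y, driven with duty `duty_in`, itself
#' drives a downstream gene through threshold `threshold`.  Under the
#' single-crossing assumption (Y's drive switches once up and once down per
#' cycle), the downstream duty has the closed form
#' `duty_in + (log((y_max - y0)/(threshold - y0)) -
#'             log((y1 - y_min)/(y1 - threshold))) / (alpha * period)`,
#' where `y0`, `y1` are Y's off/on equilibria: the input duty corrected by
#' an onset-delay and an offset-delay term whose signs depend on the
#' threshold.  Saturation: the downstream gene is driven all the time
#' (duty 1) if `threshold <= y_min`, never (duty 0) if `threshold >= y_max`.
#'
#' @param stats list with fields `y_min`, `y_max`, `duty_in` (e.g. the
#'   `stats` attribute of a [stationary_cycle()]), describing the
#'   intermediate's stationary cycle.
#' @param threshold downstream activation threshold on the intermediate.
#' @param stage the intermediate [gene_stage()] (supplies equilibria and
#'   degradation rate).
#' @param period oscillation period, hours.
#' @return fraction of the cycle in \[0,1\].
#' @export
downstream_duty <- function(stats, threshold, stage, period) {
  stopifnot(inherits(stage, "gene_stage"), period > 0)
  if (!is.null(stats$n_switches) && stats$n_switches > 2L)
    stop("closed form inapplicable: the drive crosses its threshold more ",
         "than once per cycle; use the event-driven path")
  ymin <- stats$y_min; ymax <- stats$y_max; f <- stats$duty_in
  if (threshold <= ymin) return(1)
  if (threshold >= ymax) return(0)
  eq <- .equilibria(stage)
  y0 <- min(eq); y1 <- max(eq)
  al <- stage$degradation
  # rising phase lasts f*T for an activator drive, (1-f)*T for an inhibitor
  f_rise <- if (stage$synth_on >= stage$synth_off) f else 1 - f
  d_on <- log((y1 - ymin) / (y1 - threshold)) / al
  d_off <- log((ymax - y0) / (threshold - y0)) / al
  f_rise + (d_off - d_on) / period
}
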