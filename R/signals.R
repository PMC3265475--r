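#' Anchor-point signal profile on the unit interval
#'
#' An `anchor_profile` describes the shape of an oscillatory transcription
#' factor over one cycle, normalized in both time and concentration: it is a
#' continuous curve on \[0,1\] passing exactly through a small set of anchor
#' points, starting and ending at zero.  Interpolation is monotone
#' shape-preserving piecewise cubic (Fritsch-Carlson), so the curve never
#' leaves the value range spanned by neighbouring anchors: no overshoot above
#' 1, no undershoot below 0, and no spurious threshold crossings beyond those
#' implied by the anchors themselves.
#'
#' @param anchors two-column matrix or data.frame of (time, value) pairs;
#'   times strictly increasing from 0 to 1, values in \[0,1\] with first and
#'   last values equal to 0.  At least 3 anchors are required.
#' @param label optional shape label (`"left_skewed"`, `"symmetric"`,
#'   `"right_skewed"` or `"custom"`).
#' @return an object of class `anchor_profile`: callable via
#'   [profile_value()], with fields `anchors` and `label`.
#' @seealso [canonical_profile()] for the three canonical shapes,
#'   [periodic_signal()] to stretch a profile to a real time axis.
#' @examples
#' p <- canonical_profile("left_skewed")
#' profile_value(p, c(0, 0.1333, 0.5))
#' @export
anchor_profile <- function(anchors, label = "custom") {
  anchors <- as.matrix(anchors)
  if (ncol(anchors) != 2L)
    stop("`anchors` must have two columns (time, value)")
  storage.mode(anchors) <- "double"
  colnames(anchors) <- c("time", "value")
  n <- nrow(anchors)
  if (n < 3L)
    stop("at least 3 anchors are required, got ", n)
  tt <- anchors[, 1L]; vv <- anchors[, 2L]
  if (any(!is.finite(tt)) || any(!is.finite(vv)))
    stop("anchors must be finite")
  bad <- which(diff(tt) <= 0)
  if (length(bad))
    stop("anchor times must be strictly increasing; offending anchor #",
         bad[1L] + 1L, " at time ", format(tt[bad[1L] + 1L]))
  if (tt[1L] != 0 || tt[n] != 1)
    stop("anchor times must start at 0 and end at 1")
  bad <- which(vv < 0 | vv > 1)
  if (length(bad))
    stop("anchor values must lie in [0,1]; offending anchor #", bad[1L],
         " with value ", format(vv[bad[1L]]))
  if (vv[1L] != 0 || vv[n] != 0)
    stop("first and last anchor values must be 0")
  # shape-preserving piecewise-cubic Hermite (Fritsch-Carlson): passes
  # through every anchor, monotone between consecutive anchors, so the
  # curve never leaves [0,1] and adds no spurious threshold crossings
  fun <- function(u) {
    v <- pracma::pchip(tt, vv, u)
    pmin(pmax(v, 0), 1)
  }
  structure(list(anchors = anchors, label = label, fun = fun),
            class = "anchor_profile")
}

#' The three canonical oscillation shapes
#'
#' Left-skewed (fast rise, slow decay), symmetric, and right-skewed (slow
#' rise, fast decay) unit-cycle profiles.  All three spend 75% of the cycle
#' above the level 0.1 and 25% above 0.75, so they share the same duty
#' structure and differ only in temporal shape.
#'
#' @param label one of `"left_skewed"`, `"symmetric"`, `"right_skewed"`.
#' @return an [anchor_profile()].
#' @export
canonical_profile <- function(label = c("left_skewed", "symmetric",
                                        "right_skewed")) {
  label <- match.arg(label)
  anchors <- switch(label,
    left_skewed = cbind(
      time  = c(0, 0.05, 0.1, 0.1333, 0.35, 0.8, 1),
      value = c(0, 0.1, 0.75, 1, 0.75, 0.1, 0)),
    symmetric = cbind(
      time  = c(0, 0.125, 0.375, 0.5, 0.625, 0.875, 1),
      value = c(0, 0.1, 0.75, 1, 0.75, 0.1, 0)),
    right_skewed = cbind(
      time  = c(0, 0.2, 0.65, 0.8667, 0.9, 0.95, 1),
      value = c(0, 0.1, 0.75, 1, 0.75, 0.1, 0)))
  anchor_profile(anchors, label = label)
}

#' Evaluate an anchor profile
#'
#' @param profile an [anchor_profile()].
#' @param t times in \[0,1\] (values outside are clamped into \[0,1\]).
#' @return numeric vector of profile values in \[0,1\].
#' @export
profile_value <- function(profile, t) {
  stopifnot(inherits(profile, "anchor_profile"))
  profile$fun(pmin(pmax(t, 0), 1))
}

#' @export
print.anchor_profile <- function(x, ...) {
  cat("<anchor_profile> label:", x$label, "-", nrow(x$anchors), "anchors\n")
  invisible(x)
}

#' Periodic transcription-factor signal
#'
#' Stretches a unit-cycle profile to a period `period` (hours) and repeats
#' it, giving the input concentration X(t).  Evaluation at time t equals the
#' profile evaluated at `((t - phase) mod period) / period`.
#'
#' @param profile an [anchor_profile()] or a canonical shape label.
#' @param period oscillation period in hours, > 0.
#' @param phase time offset in hours (default 0; cycle starts at `phase`).
#' @return object of class `c("periodic_signal", "osc_signal")`.
#' @export
periodic_signal <- function(profile, period, phase = 0) {
  if (is.character(profile)) profile <- canonical_profile(profile)
  stopifnot(inherits(profile, "anchor_profile"),
            is.numeric(period), length(period) == 1L, period > 0,
            is.numeric(phase), length(phase) == 1L, is.finite(phase))
  structure(list(profile = profile, period = period, phase = phase),
            class = c("periodic_signal", "osc_signal"))
}

#' Step (transient on/off) stimulus
#'
#' Value `level` on \[`on_time`, `off_time`), 0 elsewhere.
#'
#' @param on_time,off_time stimulus start and end, hours, `off_time > on_time`.
#' @param level plateau concentration (default 1).
#' @return object of class `c("step_signal", "osc_signal")`.
#' @export
step_signal <- function(on_time, off_time, level = 1) {
  stopifnot(is.numeric(on_time), is.numeric(off_time),
            off_time > on_time, level > 0)
  structure(list(on_time = on_time, off_time = off_time, level = level),
            class = c("step_signal", "osc_signal"))
}

#' Idealized square-wave input
#'
#' Value 1 for the first `duty` fraction of each cycle and 0 for the rest.
#' Useful as the simplest single-crossing periodic drive: the stationary
#' cycle extrema then follow two-exponential closed forms exactly.
#'
#' @param duty fraction of the cycle spent at 1, in (0,1).
#' @param period cycle length in hours.
#' @param phase time offset in hours.
#' @return object of class `c("square_wave", "osc_signal")`.
#' @export
square_wave <- function(duty, period, phase = 0) {
  stopifnot(is.numeric(duty), length(duty) == 1L)
  if (!(duty > 0 && duty < 1))
    stop("`duty` must lie strictly inside (0,1), got ", format(duty))
  stopifnot(period > 0, is.finite(phase))
  structure(list(duty = duty, period = period, phase = phase),
            class = c("square_wave", "osc_signal"))
}

#' Evaluate a signal at given times
#'
#' @param signal a `periodic_signal`, `square_wave` or `step_signal`.
#' @param t numeric vector of times (hours).
#' @return numeric vector of concentrations.
#' @export
signal_value <- function(signal, t) UseMethod("signal_value")

#' @export
signal_value.periodic_signal <- function(signal, t) {
  u <- ((t - signal$phase) / signal$period) %% 1
  profile_value(signal$profile, u)
}

#' @export
signal_value.square_wave <- function(signal, t) {
  u <- ((t - signal$phase) / signal$period) %% 1
  as.numeric(u < signal$duty)
}

#' @export
signal_value.step_signal <- function(signal, t) {
  ifelse(t >= signal$on_time & t < signal$off_time, signal$level, 0)
}

#' @export
print.osc_signal <- function(x, ...) {
  if (inherits(x, "periodic_signal"))
    cat("<periodic_signal>", x$profile$label, "profile, period",
        x$period, "h\n")
  else if (inherits(x, "square_wave"))
    cat("<square_wave> duty", x$duty, ", period", x$period, "h\n")
  else
    cat("<step_signal> on [", x$on_time, ",", x$off_time, ") level",
        x$level, "\n")
  invisible(x)
}

#' @export
plot.osc_signal <- function(x, window = NULL, n = 1000, ...) {
  if (is.null(window)) {
    window <- if (inherits(x, "step_signal"))
      c(x$on_time - 0.5, x$off_time + 0.5) else c(0, 3 * x$period)
  }
  t <- seq(window[1L], window[2L], length.out = n)
  graphics::plot(t, signal_value(x, t), type = "l", xlab = "time (h)",
                 ylab = "concentration", ...)
  invisible(x)
}

# Crossing structure of the unit-interval profile.
# Returns times in [0,1) where (value > threshold) flips, with directions.
# Anchor points sitting exactly at the threshold are honoured exactly; roots
# interior to a monotone anchor interval are refined by uniroot to ~1e-14.
.profile_crossings <- function(profile, threshold) {
  a <- profile$anchors
  tt <- a[, 1L]; vv <- a[, 2L]
  f <- profile$fun
  cand <- tt[vv == threshold]
  for (i in seq_len(nrow(a) - 1L)) {
    if ((vv[i] - threshold) * (vv[i + 1L] - threshold) < 0) {
      r <- stats::uniroot(function(u) f(u) - threshold,
                          lower = tt[i], upper = tt[i + 1L],
                          tol = 1e-14)$root
      cand <- c(cand, r)
    }
  }
  nodes <- sort(unique(c(0, cand, 1)))
  mids <- (nodes[-length(nodes)] + nodes[-1L]) / 2
  above <- f(mids) > threshold
  flips <- which(diff(above) != 0L) + 1L   # index into nodes (interior)
  list(times = nodes[flips],
       direction = ifelse(above[flips], "up", "down"),
       above = above, nodes = nodes)
}

#' Threshold-crossing times of a signal
#'
#' Locates every time in `window` at which the signal crosses `threshold`,
#' with the direction of crossing.  A value exactly equal to the threshold
#' counts as *not* above (strict inequality), the convention used throughout
#' the package.  Crossings are found by bracketing sign changes on the
#' monotone anchor intervals and refining with a bracketing root-finder, so
#' event times are accurate to ~1e-12 relative; crossings that coincide with
#' anchor points are exact.
#'
#' @param signal a `periodic_signal`, `square_wave` or `step_signal`.
#' @param threshold concentration threshold, strictly inside the signal's
#'   value range for a non-empty answer.
#' @param window numeric length-2 interval; crossings strictly inside
#'   `(window[1], window[2])` are reported.
#' @return data.frame with columns `time` (strictly increasing) and
#'   `direction` (`"up"`/`"down"`, alternating).  Empty if the threshold is
#'   never crossed.
#' @export
crossing_times <- function(signal, threshold, window) UseMethod("crossing_times")

.empty_crossings <- function()
  data.frame(time = numeric(), direction = character(),
             stringsAsFactors = FALSE)

.window_check <- function(window) {
  stopifnot(is.numeric(window), length(window) == 2L,
            is.finite(window), window[2L] > window[1L])
}

#' @export
crossing_times.periodic_signal <- function(signal, threshold, window) {
  .window_check(window)
  cr <- .profile_crossings(signal$profile, threshold)
  if (!length(cr$times)) return(.empty_crossings())
  T <- signal$period
  k0 <- floor((window[1L] - signal$phase) / T) - 1
  k1 <- ceiling((window[2L] - signal$phase) / T) + 1
  ks <- seq(k0, k1)
  times <- as.vector(outer(cr$times * T, ks * T + signal$phase, `+`))
  dirs <- rep(cr$direction, times = length(ks))
  ord <- order(times)
  times <- times[ord]; dirs <- dirs[ord]
  keep <- times > window[1L] & times < window[2L]
  data.frame(time = times[keep], direction = dirs[keep],
             stringsAsFactors = FALSE)
}

#' @export
crossing_times.square_wave <- function(signal, threshold, window) {
  .window_check(window)
  if (threshold >= 1 || threshold <= 0) return(.empty_crossings())
  T <- signal$period
  k0 <- floor((window[1L] - signal$phase) / T) - 1
  k1 <- ceiling((window[2L] - signal$phase) / T) + 1
  ks <- seq(k0, k1)
  times <- c(ks * T + signal$phase, ks * T + signal$phase + signal$duty * T)
  dirs <- c(rep("up", length(ks)), rep("down", length(ks)))
  ord <- order(times)
  times <- times[ord]; dirs <- dirs[ord]
  keep <- times > window[1L] & times < window[2L]
  data.frame(time = times[keep], direction = dirs[keep],
             stringsAsFactors = FALSE)
}

#' @export
crossing_times.step_signal <- function(signal, threshold, window) {
  .window_check(window)
  if (threshold >= signal$level || threshold <= 0) return(.empty_crossings())
  times <- c(signal$on_time, signal$off_time)
  dirs <- c("up", "down")
  keep <- times > window[1L] & times < window[2L]
  data.frame(time = times[keep], direction = dirs[keep],
             stringsAsFactors = FALSE)
}

#' Duty fraction of a periodic signal above a threshold
#'
#' Fraction of each cycle during which the signal is strictly above
#' `threshold`.  Computed exactly from the crossing structure of one cycle
#' (no sampling), so anchors sitting on the threshold contribute their exact
#' crossing times.  Independent of the period: stretching the cycle rescales
#' all crossings linearly.
#'
#' @param signal a `periodic_signal` or `square_wave`.
#' @param threshold concentration threshold.
#' @return fraction in \[0,1\].
#' @export
duty_fraction <- function(signal, threshold) UseMethod("duty_fraction")

#' @export
duty_fraction.periodic_signal <- function(signal, threshold) {
  cr <- .profile_crossings(signal$profile, threshold)
  nodes <- cr$nodes
  gaps <- diff(nodes)
  sum(gaps[cr$above])
}

#' @export
duty_fraction.square_wave <- function(signal, threshold) {
  if (threshold >= 1) 0 else if (threshold < 0) 1 else signal$duty
}
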