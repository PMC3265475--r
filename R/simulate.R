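#' Event-driven simulation of a regulatory motif
#'
#' Evaluates the cascade exactly, in topological order: the input is
#' digitized against its edge thresholds, the intermediate Y is propagated
#' as a piecewise exponential, Y is digitized against the downstream
#' threshold, the FFL gate (if any) combines the two branch conditions, and
#' the target Z is propagated.  Every switch time is located in closed form,
#' so the trajectories are exact solutions of the threshold model, not
#' numerical approximations.
#'
#' @param config a [motif_config()].
#' @param input a `periodic_signal`, `square_wave` or `step_signal`.
#' @param horizon simulation end time, hours (window is \[0, horizon\]).
#' @param initial named numeric vector of initial concentrations (`Y`, and
#'   `Z` where present); missing genes start at 0.
#' @return object of class `motif_sim`: list with elements `config`,
#'   `input`, `window`, `trajectories` (named `pwexp_trajectory` list) and
#'   `traces` (named [digital_trace()] list: `S_xy`, and `S_xz`, `S_yz`,
#'   `gate` as applicable).
#' @export
simulate_motif <- function(config, input, horizon, initial = c(Y = 0, Z = 0)) {
  stopifnot(inherits(config, "motif_config"), inherits(input, "osc_signal"),
            is.numeric(horizon), horizon > 0)
  window <- c(0, horizon)
  init <- function(g) if (g %in% names(initial)) initial[[g]] else 0
  ed <- config$edges
  st <- config$stages
  s_xy <- digitize(input, ed[["X->Y"]]$threshold, window,
                   sense = ed[["X->Y"]]$sense)
  y <- propagate(init("Y"), synthesis_rate_trace(st$Y, s_xy),
                 st$Y$degradation)
  traces <- list(S_xy = s_xy)
  trajectories <- list(Y = y)
  if (config$topology != "direct") {
    s_yz <- digitize(y, ed[["Y->Z"]]$threshold, window,
                     sense = ed[["Y->Z"]]$sense)
    traces$S_yz <- s_yz
    drive_z <- s_yz
    if (config$topology == "ffl") {
      s_xz <- digitize(input, ed[["X->Z"]]$threshold, window,
                       sense = ed[["X->Z"]]$sense)
      traces$S_xz <- s_xz
      drive_z <- gate_combine(config$gate, s_xz, s_yz)
      traces$gate <- drive_z
    }
    trajectories$Z <- propagate(init("Z"),
                                synthesis_rate_trace(st$Z, drive_z),
                                st$Z$degradation)
  }
  structure(list(config = config, input = input, window = window,
                 trajectories = trajectories, traces = traces),
            class = "motif_sim")
}

#' @export
print.motif_sim <- function(x, ...) {
  cat("<motif_sim> over [", x$window[1L], ",", x$window[2L], "] h\n")
  print(x$config)
  invisible(x)
}

#' @export
plot.motif_sim <- function(x, n = 1000, ...) {
  t <- seq(x$window[1L], x$window[2L], length.out = n)
  xv <- signal_value(x$input, t)
  genes <- names(x$trajectories)
  old <- graphics::par(mfrow = c(length(genes) + 1L, 1L),
                       mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(old))
  graphics::plot(t, xv, type = "l", ylab = "X", xlab = "")
  for (g in genes)
    graphics::plot(t, pwexp_value(x$trajectories[[g]], t), type = "l",
                   ylab = g, xlab = "")
  invisible(x)
}

#' Stationary-regime statistics of a periodically driven motif
#'
#' Computes, gene by gene down the cascade, the exact periodic attractor as
#' the fixed point of each stage's one-period return map (the feed-forward
#' structure guarantees every stage's drive is periodic once the upstream
#' stage is stationary), and summarizes it: time-averaged expression, cycle
#' minimum and maximum, input and output duty fractions, onset/offset delays
#' of the intermediate relative to its own drive, and the dimensionless
#' period (period times the gene's degradation rate).
#'
#' @param config a [motif_config()].
#' @param input a periodic signal ([periodic_signal()] or [square_wave()]).
#' @return object of class `motif_stationary`: list with `cycles` (named
#'   list of [stationary_cycle()] trajectories over one period), `traces`
#'   (digital drives over one period), and `stats` (named per-gene list:
#'   `mean`, `y_min`, `y_max`, `duty_in`, `duty_out`, `onset_delay`,
#'   `offset_delay`, `dimensionless_period`).
#' @export
motif_stationary <- function(config, input) {
  stopifnot(inherits(config, "motif_config"))
  if (!(inherits(input, "periodic_signal") || inherits(input, "square_wave")))
    stop("stationary analysis requires a periodic input signal")
  T <- input$period
  w <- c(0, T)
  ed <- config$edges
  st <- config$stages
  s_xy <- digitize(input, ed[["X->Y"]]$threshold, w, sense = ed[["X->Y"]]$sense)
  ycyc <- stationary_cycle(s_xy, st$Y, T)
  ystats <- attr(ycyc, "stats")
  ystats$duty_out <- NA_real_
  ystats$onset_delay <- NA_real_
  ystats$offset_delay <- NA_real_
  cycles <- list(Y = ycyc)
  traces <- list(S_xy = s_xy)
  stats <- list()
  if (config$topology != "direct") {
    k_yz <- ed[["Y->Z"]]$threshold
    s_yz <- digitize(ycyc, k_yz, w, sense = ed[["Y->Z"]]$sense)
    traces$S_yz <- s_yz
    ystats$duty_out <- trace_duty(s_yz)
    # delays of Y's own threshold condition relative to its drive, defined
    # when Y crosses k_yz once per cycle strictly inside (y_min, y_max)
    if (length(s_yz$times) == 2L && k_yz > ystats$y_min &&
        k_yz < ystats$y_max) {
      eq <- .equilibria(st$Y)
      ystats$onset_delay <- onset_delay(ystats$y_min, max(eq), k_yz,
                                        st$Y$degradation)
      ystats$offset_delay <- onset_delay(ystats$y_max, min(eq), k_yz,
                                         st$Y$degradation)
    }
    drive_z <- s_yz
    if (config$topology == "ffl") {
      s_xz <- digitize(input, ed[["X->Z"]]$threshold, w,
                       sense = ed[["X->Z"]]$sense)
      traces$S_xz <- s_xz
      drive_z <- gate_combine(config$gate, s_xz, s_yz)
      traces$gate <- drive_z
    }
    zcyc <- stationary_cycle(drive_z, st$Z, T)
    zstats <- attr(zcyc, "stats")
    zstats$duty_out <- NA_real_
    zstats$onset_delay <- NA_real_
    zstats$offset_delay <- NA_real_
    cycles$Z <- zcyc
    stats <- list(Y = ystats, Z = zstats)
  } else {
    stats <- list(Y = ystats)
  }
  structure(list(config = config, input = input, period = T,
                 cycles = cycles, traces = traces, stats = stats),
            class = "motif_stationary")
}

#' @export
print.motif_stationary <- function(x, ...) {
  cat("<motif_stationary> period", x$period, "h\n")
  for (g in names(x$stats)) {
    s <- x$stats[[g]]
    cat(sprintf(
      "  %s: mean %.6g  min %.6g  max %.6g  duty_in %.4g  tau %.4g\n",
      g, s$mean, s$y_min, s$y_max, s$duty_in, s$dimensionless_period))
  }
  invisible(x)
}

#' @export
summary.motif_stationary <- function(object, ...) {
  rows <- lapply(names(object$stats), function(g) {
    s <- object$stats[[g]]
    data.frame(gene = g, mean = s$mean, y_min = s$y_min, y_max = s$y_max,
               duty_in = s$duty_in, duty_out = s$duty_out,
               onset_delay = s$onset_delay, offset_delay = s$offset_delay,
               dimensionless_period = s$dimensionless_period)
  })
  do.call(rbind, rows)
}
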