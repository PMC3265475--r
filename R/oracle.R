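#' Numerical integration of the step-function motif model
#'
#' Independent cross-check for the event-driven engine: integrates the same
#' threshold model with `deSolve::lsoda` at tight tolerances.  The input's
#' threshold-crossing times (known in closed form from the signal layer) are
#' used as integration breakpoints so the integrator never steps across a
#' synthesis-rate discontinuity; threshold crossings of the *intermediate*
#' gene, by contrast, are detected numerically (grid sign changes refined by
#' root-finding on an interpolant of the numerical solution), keeping the
#' oracle independent of the closed-form crossing algebra it validates.
#'
#' @param config a [motif_config()].
#' @param input a signal (see [signal_value()]).
#' @param window length-2 integration window, hours.
#' @param initial named initial concentrations (missing genes start at 0).
#' @param n_out number of output sample times (evenly spaced; breakpoints
#'   are added internally).
#' @param rtol,atol relative and absolute integration tolerances.  The
#'   defaults are tight enough that disagreement with the analytic engine
#'   beyond ~1e-8 indicates a logic error rather than integrator error.
#' @return object of class `oracle_sim`: list with `time`, `x`, `y`
#'   (and `z`), `y_events` (numerically detected crossing times of Y),
#'   `integrals` (exact-to-tolerance time integrals of each gene over the
#'   window, accumulated as auxiliary ODE states) and `method`.
#' @export
integrate_step_model <- function(config, input, window,
                                 initial = c(Y = 0, Z = 0),
                                 n_out = 400, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(config, "motif_config"), inherits(input, "osc_signal"))
  .window_check(window)
  ed <- config$edges
  st <- config$stages
  init <- function(g) if (g %in% names(initial)) initial[[g]] else 0

  # digital drives derived from the input (crossings supplied analytically)
  s_xy <- digitize(input, ed[["X->Y"]]$threshold, window,
                   sense = ed[["X->Y"]]$sense)
  out_times <- seq(window[1L], window[2L], length.out = n_out)

  # --- stage Y: piecewise integration with breakpoints at input switches
  yres <- .ode_linear_stages(
    intervals = trace_intervals(s_xy),
    beta = function(state) if (state == 1L) st$Y$synth_on else st$Y$synth_off,
    alpha = st$Y$degradation, y0 = init("Y"),
    out_times = out_times, rtol = rtol, atol = atol)

  res <- list(time = yres$time, x = signal_value(input, yres$time),
              y = yres$y, y_events = numeric(),
              integrals = list(Y = yres$integral),
              window = window, method = "ode_step")

  if (config$topology != "direct") {
    k_yz <- ed[["Y->Z"]]$threshold
    ycross <- .ode_detect_crossings(yres, k_yz)
    res$y_events <- ycross
    init_above <- yres$y[1L] > k_yz
    s_yz <- digital_trace(ycross, as.integer(init_above), window)
    if (ed[["Y->Z"]]$sense == "active_below")
      s_yz <- complement_trace(s_yz)
    drive_z <- s_yz
    if (config$topology == "ffl") {
      s_xz <- digitize(input, ed[["X->Z"]]$threshold, window,
                       sense = ed[["X->Z"]]$sense)
      drive_z <- gate_combine(config$gate, s_xz, s_yz)
    }
    zres <- .ode_linear_stages(
      intervals = trace_intervals(drive_z),
      beta = function(state) if (state == 1L) st$Z$synth_on else st$Z$synth_off,
      alpha = st$Z$degradation, y0 = init("Z"),
      out_times = res$time, rtol = rtol, atol = atol)
    res$z <- zres$y[match(res$time, zres$time)]
    res$integrals$Z <- zres$integral
  }
  class(res) <- "oracle_sim"
  res
}

# integrate dy/dt = beta - alpha*y interval by interval with lsoda,
# accumulating the time integral of y as an auxiliary state.
.ode_linear_stages <- function(intervals, beta, alpha, y0,
                               out_times, rtol, atol) {
  all_t <- y0s <- NULL
  tcur <- intervals$start[1L]
  ycur <- y0; icur <- 0
  times_acc <- list(); y_acc <- list(); seg_id <- list()
  for (i in seq_len(nrow(intervals))) {
    t0 <- intervals$start[i]; t1 <- intervals$end[i]
    b <- beta(intervals$state[i])
    tt <- sort(unique(c(t0, out_times[out_times > t0 & out_times < t1], t1)))
    # a handful of interior points so crossing detection has something to see
    if (length(tt) < 12L)
      tt <- sort(unique(c(tt, seq(t0, t1, length.out = 12L))))
    sol <- deSolve::lsoda(
      y = c(y = ycur, cum = icur), times = tt,
      func = function(t, s, p) list(c(b - alpha * s[[1L]], s[[1L]])),
      rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1L] < 0)
      stop("ODE integration failed on interval [", t0, ", ", t1, "]")
    times_acc[[i]] <- sol[, "time"]
    y_acc[[i]] <- sol[, "y"]
    seg_id[[i]] <- rep(i, nrow(sol))
    ycur <- unname(sol[nrow(sol), "y"])
    icur <- unname(sol[nrow(sol), "cum"])
  }
  time <- unlist(times_acc); yv <- unlist(y_acc); seg <- unlist(seg_id)
  keep <- !duplicated(time)
  list(time = time[keep], y = yv[keep], seg = seg[keep],
       integral = icur,
       raw = list(time = time, y = yv, seg = seg))
}

# numerical crossing detection on the sampled solution: sign changes on the
# per-interval grids refined by uniroot on a local spline interpolant.
.ode_detect_crossings <- function(yres, threshold) {
  raw <- yres$raw
  found <- numeric()
  for (i in unique(raw$seg)) {
    sel <- raw$seg == i
    tt <- raw$time[sel]; yy <- raw$y[sel]
    if (length(tt) < 4L) next
    sf <- stats::splinefun(tt, yy, method = "fmm")
    dv <- yy - threshold
    sc <- which(dv[-length(dv)] * dv[-1L] < 0)
    for (j in sc)
      found <- c(found, stats::uniroot(function(u) sf(u) - threshold,
                                       lower = tt[j], upper = tt[j + 1L],
                                       tol = 1e-13)$root)
    zero <- which(dv == 0)
    zero <- zero[zero > 1L & zero < length(dv)]
    found <- c(found, tt[zero])
  }
  sort(unique(found))
}

#' Numerical integration of the Hill-function model variant
#'
#' Replaces the step-function synthesis switch of direct regulation with a
#' smooth Hill rate, `beta0 + (beta1 - beta0) * x^n / (x^n + K^n)`, and
#' integrates numerically.  As the exponent `n` grows the Hill model
#' converges to the step-function model; the half-activation constant is
#' identified with the edge threshold `K`.
#'
#' @param config a direct-regulation [motif_config()].
#' @param input a signal.
#' @param window integration window.
#' @param initial initial Y concentration.
#' @param exponent Hill coefficient, >= 1.
#' @param half_activation half-activation constant; defaults to the X->Y
#'   edge threshold.
#' @param n_out,rtol,atol as in [integrate_step_model()].
#' @return object of class `oracle_sim` with `method = "ode_hill"`.
#' @export
integrate_hill_model <- function(config, input, window,
                                 initial = c(Y = 0), exponent = 2,
                                 half_activation = NULL,
                                 n_out = 400, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(config, "motif_config"))
  if (config$topology != "direct")
    stop("the Hill-rate variant is implemented for direct regulation")
  if (!(is.numeric(exponent) && exponent >= 1))
    stop("Hill exponent must be >= 1")
  .window_check(window)
  st <- config$stages$Y
  K <- if (is.null(half_activation))
    config$edges[["X->Y"]]$threshold else half_activation
  stopifnot(K > 0)
  y0 <- if ("Y" %in% names(initial)) initial[["Y"]] else 0
  b0 <- st$synth_off; b1 <- st$synth_on; al <- st$degradation
  n <- exponent
  rhs <- function(t, s, p) {
    x <- signal_value(input, t)
    h <- if (x <= 0) 0 else 1 / (1 + (K / x)^n)
    list(c(b0 + (b1 - b0) * h - al * s[[1L]], s[[1L]]))
  }
  # anchor kinks of the input as mandatory output/breakpoint times
  kinks <- numeric()
  if (inherits(input, "periodic_signal")) {
    T <- input$period
    k0 <- floor((window[1L] - input$phase) / T)
    k1 <- ceiling((window[2L] - input$phase) / T)
    a <- input$profile$anchors[, 1L]
    kinks <- as.vector(outer(a * T, seq(k0, k1) * T + input$phase, `+`))
  } else if (inherits(input, "step_signal")) {
    kinks <- c(input$on_time, input$off_time)
  } else if (inherits(input, "square_wave")) {
    stop("the Hill variant requires a continuous input signal")
  }
  kinks <- kinks[kinks > window[1L] & kinks < window[2L]]
  tt <- sort(unique(c(seq(window[1L], window[2L], length.out = n_out), kinks)))
  sol <- deSolve::lsoda(y = c(y = y0, cum = 0), times = tt, func = rhs,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0)
    stop("ODE integration failed for the Hill model")
  structure(list(time = sol[, "time"], x = signal_value(input, sol[, "time"]),
                 y = sol[, "y"],
                 integrals = list(Y = sol[nrow(sol), "cum"]),
                 window = window, method = "ode_hill",
                 hill = list(exponent = n, half_activation = K)),
            class = "oracle_sim")
}

#' @export
print.oracle_sim <- function(x, ...) {
  cat("<oracle_sim> method", x$method, "on [", x$window[1L], ",",
      x$window[2L], "],", length(x$time), "samples\n")
  invisible(x)
}
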