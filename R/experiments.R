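#' Stationary response across oscillation periods
#'
#' Runs the closed-form stationary machinery for one motif over a grid of
#' input periods and tabulates per-gene statistics.  Deterministic: no
#' randomness anywhere in the pipeline.
#'
#' @param config a [motif_config()].
#' @param shape an [anchor_profile()] (or canonical label) defining the
#'   input shape; alternatively a [square_wave()]-style duty via
#'   `square_duty` for idealized drives.
#' @param periods numeric vector of at least two oscillation periods, hours.
#' @param square_duty if not `NULL`, use a square wave with this duty
#'   instead of a spline profile.
#' @return a `sweep_result` data.frame: one row per period with columns
#'   `motif`, `gate`, `shape`, `period`, `duty_in`, per-gene `tau`
#'   (dimensionless period), `mean`, `min`, `max`, plus the intermediate's
#'   `duty_out` and onset/offset delays where defined.
#' @export
period_sweep <- function(config, shape, periods, square_duty = NULL) {
  stopifnot(inherits(config, "motif_config"), is.numeric(periods))
  if (length(periods) < 2L)
    stop("a sweep needs at least two periods")
  if (is.character(shape)) shape <- canonical_profile(shape)
  rows <- lapply(periods, function(T) {
    input <- if (is.null(square_duty)) periodic_signal(shape, T)
             else square_wave(square_duty, T)
    .stationary_row(config, input)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Stationary response across input shapes
#'
#' Compares the three canonical profiles (or any list of profiles sharing a
#' duty structure) at a fixed period.
#'
#' @param config a [motif_config()].
#' @param shapes list of [anchor_profile()] objects or labels.
#' @param period oscillation period, hours.
#' @return a `sweep_result` data.frame, one row per shape.
#' @export
shape_sweep <- function(config,
                        shapes = list("left_skewed", "symmetric",
                                      "right_skewed"),
                        period = 1) {
  stopifnot(inherits(config, "motif_config"))
  rows <- lapply(shapes, function(sh) {
    if (is.character(sh)) sh <- canonical_profile(sh)
    .stationary_row(config, periodic_signal(sh, period))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

.stationary_row <- function(config, input) {
  ms <- motif_stationary(config, input)
  s <- ms$stats
  lbl <- if (config$topology == "ffl")
    ffl_sign_table$label[config$ffl_type] else config$topology
  shape <- if (inherits(input, "square_wave"))
    sprintf("square(%.3g)", input$duty) else input$profile$label
  z <- s$Z
  data.frame(
    motif = lbl,
    gate = if (is.null(config$gate)) NA_character_ else config$gate,
    shape = shape,
    period = input$period,
    duty_in = s$Y$duty_in,
    tau_y = s$Y$dimensionless_period,
    y_mean = s$Y$mean, y_min = s$Y$y_min, y_max = s$Y$y_max,
    y_duty_out = s$Y$duty_out,
    onset_delay = s$Y$onset_delay, offset_delay = s$Y$offset_delay,
    tau_z = if (is.null(z)) NA_real_ else z$dimensionless_period,
    z_mean = if (is.null(z)) NA_real_ else z$mean,
    z_min = if (is.null(z)) NA_real_ else z$y_min,
    z_max = if (is.null(z)) NA_real_ else z$y_max,
    stringsAsFactors = FALSE)
}

#' Classify the frequency-response regime of an FFL
#'
#' Feed-forward loops driven by an oscillatory input fall into four response
#' classes, determined by two orderings only: the direct-branch input
#' threshold versus the indirect-branch input threshold (`k_xz` vs `k_xy`),
#' and the intermediate's gate threshold versus the intermediate's
#' stationary mean (`k_yz` vs mean(Y)).  The label is invariant to the
#' oscillation period (the stationary mean of Y depends only on the input
#' duty, not the period).
#'
#' * **A** (`k_xy < k_xz`, `k_yz < mean(Y)`): indirect branch always ready;
#'   response flat in period, as for direct regulation.
#' * **B** (`k_xy < k_xz`, `k_yz > mean(Y)`): controlled by Y's cycle
#'   maximum; switched off at high-frequency oscillation.
#' * **C** (`k_xy > k_xz`, `k_yz < mean(Y)`): controlled by Y's cycle
#'   minimum; branch overlap grows as the period shrinks.
#' * **D** (`k_xy > k_xz`, `k_yz > mean(Y)`): dominated by the indirect
#'   branch; behaves like two-step regulation.
#'
#' Degenerate orderings (equalities within `tol`) give the explicit outcome
#' `"boundary"` rather than a silent pick.
#'
#' @param config an FFL [motif_config()].
#' @param input periodic input used to evaluate the intermediate's
#'   stationary mean (defaults to the symmetric canonical shape, period 1 h;
#'   only its duty structure matters).
#' @param tol tolerance for calling an ordering degenerate.
#' @return object of class `regime_label`: list with `case` (`"A"`..`"D"`
#'   or `"boundary"`), `motif`, `gate` and the two signed orderings.
#' @export
classify_regime <- function(config, input = NULL, tol = 1e-9) {
  stopifnot(inherits(config, "motif_config"))
  if (config$topology != "ffl")
    stop("regime classification applies to FFL topologies")
  if (is.null(input)) input <- periodic_signal("symmetric", 1)
  ed <- config$edges
  k_xy <- ed[["X->Y"]]$threshold
  k_xz <- ed[["X->Z"]]$threshold
  k_yz <- ed[["Y->Z"]]$threshold
  s_xy <- digitize(input, k_xy, c(0, input$period), sense = ed[["X->Y"]]$sense)
  ybar <- stationary_mean(trace_duty(s_xy), config$stages$Y)
  o_input <- k_xy - k_xz      # negative: indirect branch triggered first
  o_gate <- k_yz - ybar       # negative: gate threshold below Y's mean
  case <- if (abs(o_input) <= tol || abs(o_gate) <= tol) "boundary"
          else if (o_input < 0 && o_gate < 0) "A"
          else if (o_input < 0 && o_gate > 0) "B"
          else if (o_input > 0 && o_gate < 0) "C"
          else "D"
  structure(list(case = case,
                 motif = ffl_sign_table$label[config$ffl_type],
                 gate = config$gate,
                 k_xy_minus_k_xz = o_input,
                 k_yz_minus_ymean = o_gate,
                 y_mean = ybar),
            class = "regime_label")
}

#' @export
print.regime_label <- function(x, ...) {
  cat("<regime_label>", x$motif, x$gate, "gate: case", x$case, "\n")
  cat("  k_xy - k_xz =", format(x$k_xy_minus_k_xz),
      "; k_yz - mean(Y) =", format(x$k_yz_minus_ymean), "\n")
  invisible(x)
}

#' Step-response characterization of an FFL
#'
#' Simulates the motif under a step stimulus and characterizes the target's
#' expression window from exact event times: delay between stimulus onset
#' and the first activation of Z's synthesis, delay between stimulus
#' removal and the last deactivation, the number of expression pulses, and
#' their durations.  A CFFL-1 with an AND gate shows the sign-sensitive
#' delay (positive on-delay, exactly zero off-delay); an IFFL-1 with an AND
#' gate produces exactly one pulse under a sustained step.
#'
#' @param config an FFL [motif_config()].
#' @param step a [step_signal()].
#' @param horizon simulation end; defaults to the step end plus ten
#'   lifetimes of the slowest gene.
#' @return object of class `step_response`: list with `on_delay`,
#'   `off_delay`, `n_pulses`, `pulse_durations` and the raw gate trace.
#'   A step too short to trigger any activation gives `n_pulses = 0` and
#'   `NA` delays.
#' @export
step_response <- function(config, step, horizon = NULL) {
  stopifnot(inherits(config, "motif_config"), inherits(step, "step_signal"))
  if (config$topology != "ffl")
    stop("step-response characterization applies to FFL topologies")
  if (is.null(horizon)) {
    tau <- max(1 / config$stages$Y$degradation,
               1 / config$stages$Z$degradation)
    horizon <- step$off_time + 10 * tau
  }
  sim <- simulate_motif(config, step, horizon)
  gate <- sim$traces$gate
  iv <- trace_intervals(gate)
  on <- iv[iv$state == 1L, , drop = FALSE]
  if (nrow(on) == 0L)
    return(structure(list(on_delay = NA_real_, off_delay = NA_real_,
                          n_pulses = 0L, pulse_durations = numeric(),
                          gate = gate, sim = sim),
                     class = "step_response"))
  structure(list(on_delay = on$start[1L] - step$on_time,
                 off_delay = on$end[nrow(on)] - step$off_time,
                 n_pulses = nrow(on),
                 pulse_durations = on$end - on$start,
                 gate = gate, sim = sim),
            class = "step_response")
}

#' @export
print.step_response <- function(x, ...) {
  cat("<step_response>", x$n_pulses, "pulse(s); on-delay",
      format(x$on_delay), "h; off-delay", format(x$off_delay), "h\n")
  invisible(x)
}
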