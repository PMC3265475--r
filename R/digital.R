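#' Digital (0/1) piecewise-constant trace
#'
#' Represents the paper-style "digital signal" obtained by thresholding an
#' analog concentration: a right-continuous 0/1 function on a bounded
#' window, given by its ordered switch times.  All gate logic operates
#' exactly on this switch-time algebra; no sampling is involved.
#'
#' @param switch_times strictly increasing times strictly inside the window;
#'   the state flips at each.
#' @param initial_state 0 or 1, the state at the start of the window.
#' @param window numeric length-2 time interval.
#' @return object of class `digital_trace`.
#' @export
digital_trace <- function(switch_times, initial_state, window) {
  .window_check(window)
  switch_times <- as.numeric(switch_times)
  if (length(switch_times)) {
    if (any(diff(switch_times) <= 0))
      stop("switch times must be strictly increasing")
    if (switch_times[1L] <= window[1L] ||
        switch_times[length(switch_times)] >= window[2L])
      stop("switch times must lie strictly inside the window")
  }
  if (!initial_state %in% c(0, 1)) stop("initial_state must be 0 or 1")
  structure(list(times = switch_times, init = as.integer(initial_state),
                 window = as.numeric(window)),
            class = "digital_trace")
}

#' @export
print.digital_trace <- function(x, ...) {
  cat("<digital_trace> window [", x$window[1L], ",", x$window[2L],
      "], initial state", x$init, ",", length(x$times), "switches\n")
  invisible(x)
}

#' Evaluate a digital trace (right-continuous)
#'
#' @param trace a [digital_trace()].
#' @param t numeric times.
#' @return integer vector of 0/1 states.
#' @export
digital_value <- function(trace, t) {
  stopifnot(inherits(trace, "digital_trace"))
  nflips <- findInterval(t, trace$times)   # switches at time s affect t >= s
  as.integer((trace$init + nflips) %% 2)
}

#' Constant-state intervals of a digital trace
#'
#' @param trace a [digital_trace()].
#' @return data.frame with columns `start`, `end`, `state`.
#' @export
trace_intervals <- function(trace) {
  stopifnot(inherits(trace, "digital_trace"))
  b <- c(trace$window[1L], trace$times, trace$window[2L])
  n <- length(b) - 1L
  data.frame(start = b[-length(b)], end = b[-1L],
             state = as.integer((trace$init + seq_len(n) - 1L) %% 2))
}

#' Fraction of the window spent in state 1
#'
#' @param trace a [digital_trace()].
#' @return fraction in \[0,1\].
#' @export
trace_duty <- function(trace) {
  iv <- trace_intervals(trace)
  sum((iv$end - iv$start)[iv$state == 1L]) / diff(trace$window)
}

#' Logical complement of a digital trace
#'
#' @param trace a [digital_trace()].
#' @return a [digital_trace()] with all states flipped.
#' @export
complement_trace <- function(trace) {
  stopifnot(inherits(trace, "digital_trace"))
  digital_trace(trace$times, 1L - trace$init, trace$window)
}

#' Combine two digital traces through a logic gate
#'
#' Pointwise boolean AND/OR computed exactly on the merged switch-time set;
#' simultaneous switches on both inputs are merged into a single event and
#' redundant events (no state change in the output) are dropped.
#'
#' @param gate `"AND"` or `"OR"`.
#' @param a,b [digital_trace()] objects on the same window.
#' @return a [digital_trace()].
#' @export
gate_combine <- function(gate = c("AND", "OR"), a, b) {
  gate <- match.arg(gate)
  stopifnot(inherits(a, "digital_trace"), inherits(b, "digital_trace"))
  if (!isTRUE(all.equal(a$window, b$window, tolerance = 0)))
    stop("digital traces must share the same window")
  op <- if (gate == "AND") function(u, v) u & v else function(u, v) u | v
  nodes <- sort(unique(c(a$times, b$times)))
  # state of the combination just after each node, plus the initial state
  init <- as.integer(op(a$init == 1L, b$init == 1L))
  if (!length(nodes)) return(digital_trace(numeric(), init, a$window))
  sa <- digital_value(a, nodes)
  sb <- digital_value(b, nodes)
  states <- as.integer(op(sa == 1L, sb == 1L))
  prev <- c(init, states[-length(states)])
  keep <- states != prev
  digital_trace(nodes[keep], init, a$window)
}

#' Threshold an analog signal into a digital trace
#'
#' Converts a concentration trace into the step-function drive of a
#' regulatory edge: state 1 exactly where `signal > threshold` (sense
#' `"active_above"`) or `signal < threshold` (sense `"active_below"`, the
#' repressor-arm condition).  Values exactly at the threshold count as not
#' above and not below, a measure-zero convention applied everywhere.
#'
#' @param signal a signal (see [signal_value()]) or a piecewise-exponential
#'   trajectory ([propagate()]).
#' @param threshold activation threshold, > 0.
#' @param window time interval over which to digitize.
#' @param sense `"active_above"` or `"active_below"`.
#' @return a [digital_trace()].
#' @export
digitize <- function(signal, threshold, window,
                     sense = c("active_above", "active_below")) {
  sense <- match.arg(sense)
  .window_check(window)
  if (inherits(signal, "pwexp_trajectory")) {
    cr <- pwexp_crossings(signal, threshold, window)
    v0 <- pwexp_value(signal, window[1L])
  } else {
    cr <- crossing_times(signal, threshold, window)
    v0 <- signal_value(signal, window[1L])
  }
  init <- as.integer(v0 > threshold)
  tr <- digital_trace(cr$time, init, window)
  if (sense == "active_below") complement_trace(tr) else tr
}
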