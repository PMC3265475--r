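#' Compare the analytic engine with the numerical oracle
#'
#' Runs the same scenario through the event-driven piecewise-exponential
#' engine and through the `deSolve` integrator, and reports the relative
#' sup-norm discrepancy per gene, measured on the oracle's sample grid and
#' normalized by the gene's maximum analytic level.
#'
#' @param config a [motif_config()].
#' @param input a signal.
#' @param horizon comparison window end (window is \[0, horizon\]).
#' @param initial named initial concentrations.
#' @param n_out number of comparison sample points.
#' @param rtol,atol oracle integration tolerances.
#' @return named numeric vector of relative sup-norm discrepancies (one
#'   entry per gene).
#' @export
compare_with_oracle <- function(config, input, horizon,
                                initial = c(Y = 0, Z = 0), n_out = 600,
                                rtol = 1e-10, atol = 1e-12) {
  sim <- simulate_motif(config, input, horizon, initial)
  ode <- integrate_step_model(config, input, c(0, horizon), initial,
                              n_out = n_out, rtol = rtol, atol = atol)
  out <- c(Y = .supnorm_rel(pwexp_value(sim$trajectories$Y, ode$time),
                            ode$y))
  if (!is.null(sim$trajectories$Z))
    out["Z"] <- .supnorm_rel(pwexp_value(sim$trajectories$Z, ode$time),
                             ode$z)
  out
}

.supnorm_rel <- function(a, b) {
  scale <- max(abs(a), 1e-12)
  max(abs(a - b)) / scale
}

#' Oracle cross-check suite over the standard scenario grid
#'
#' Evaluates [compare_with_oracle()] on the full validation grid: six motif
#' scenarios (direct, two-step, CFFL-1 and IFFL-1 with AND and OR gates)
#' crossed with the three canonical input shapes and a set of periods.
#' Scenario parameters use unit degradation and off/on rates 0 and 1.5,
#' with thresholds placed so every stage actually switches.
#'
#' @param periods oscillation periods (hours) to test.
#' @param shapes canonical profile labels.
#' @param horizon comparison window length, hours.
#' @param n_out comparison sample points per run.
#' @return data.frame with one row per (scenario, shape, period, gene) and
#'   a `discrepancy` column (relative sup-norm).
#' @export
validate_engine <- function(periods = c(0.5, 1, 3),
                            shapes = c("left_skewed", "symmetric",
                                       "right_skewed"),
                            horizon = 8, n_out = 500) {
  scen <- .validation_scenarios()
  rows <- list()
  for (nm in names(scen)) {
    for (sh in shapes) {
      for (T in periods) {
        d <- compare_with_oracle(scen[[nm]], periodic_signal(sh, T),
                                 horizon, n_out = n_out)
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = nm, shape = sh, period = T,
          gene = names(d), discrepancy = unname(d),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

.validation_scenarios <- function() {
  y <- gene_stage("Y", 0, 1.5, 1)
  z <- gene_stage("Z", 0, 1.5, 1)
  list(
    direct = direct_motif(y, 0.75),
    two_step = two_step_motif(y, z, 0.1, 0.8),
    cffl1_and = ffl_motif(1, "AND", y, z, 0.1, 0.75, 0.8),
    cffl1_or = ffl_motif(1, "OR", y, z, 0.1, 0.75, 0.8),
    iffl1_and = ffl_motif(5, "AND", y, z, 0.75, 0.1, 0.6),
    iffl1_or = ffl_motif(5, "OR", y, z, 0.75, 0.1, 0.6))
}
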