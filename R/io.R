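#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration describing an input signal, a motif
#' and optionally an experiment, validates it fully -- every violation is
#' reported, not just the first -- and returns ready-to-use objects.
#'
#' The schema has top-level keys `signal`, `motif` and optional
#' `experiment`, `tolerances`:
#' \preformatted{
#' signal:
#'   type: periodic            # periodic | square | step
#'   profile: symmetric        # canonical label, or `anchors:` list
#'   period: 1                 # hours (periodic/square)
#'   phase: 0                  # optional
#'   duty: 0.25                # square only
#'   on_time: 1                # step only
#'   off_time: 5               # step only
#'   level: 1                  # step, optional
#' motif:
#'   topology: ffl             # direct | two_step | ffl
#'   ffl_type: 1               # ffl only (1-8)
#'   gate: AND                 # ffl only
#'   stages:
#'     Y: {synth_off: 0, synth_on: 1.5, degradation: 1}
#'     Z: {synth_off: 0, synth_on: 1.5, degradation: 1}
#'   thresholds: {k_xy: 0.1, k_xz: 0.75, k_yz: 0.5}
#'   senses: {xy: active_above, xz: active_above, yz: active_below}  # optional
#' experiment:
#'   periods: [0.5, 1, 3]
#'   step: {on_time: 1, off_time: 5}
#' tolerances: {rtol: 1.0e-10, atol: 1.0e-12}
#' }
#' For an FFL, omitted `senses` default to the senses implied by `ffl_type`
#' (all stages activator-ordered, repression carried by `active_below`
#' arms).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return object of class `run_config`: list with `signal` (a signal
#'   object), `motif` (a [motif_config()]), `experiment` (list or NULL) and
#'   `tolerances`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  errs <- character()
  note <- function(...) errs <<- c(errs, paste0(...))

  known_top <- c("signal", "motif", "experiment", "tolerances", "name",
                 "description")
  extra <- setdiff(names(raw), known_top)
  if (length(extra)) note("unknown top-level key(s): ",
                          paste(extra, collapse = ", "))
  if (is.null(raw$signal)) note("missing required section `signal`")
  if (is.null(raw$motif)) note("missing required section `motif`")

  signal <- NULL
  if (!is.null(raw$signal)) {
    s <- raw$signal
    extra <- setdiff(names(s), c("type", "profile", "anchors", "period",
                                 "phase", "duty", "on_time", "off_time",
                                 "level"))
    if (length(extra)) note("signal: unknown key(s): ",
                            paste(extra, collapse = ", "))
    type <- s$type %||% "periodic"
    signal <- tryCatch(switch(type,
      periodic = {
        prof <- if (!is.null(s$anchors))
          anchor_profile(do.call(rbind, lapply(s$anchors, unlist)))
        else canonical_profile(s$profile %||% "symmetric")
        periodic_signal(prof, s$period %||% 1, s$phase %||% 0)
      },
      square = square_wave(s$duty, s$period %||% 1, s$phase %||% 0),
      step = step_signal(s$on_time, s$off_time, s$level %||% 1),
      stop("unknown signal type '", type, "'")),
      error = function(e) { note("signal: ", conditionMessage(e)); NULL })
  }

  motif <- NULL
  if (!is.null(raw$motif)) {
    m <- raw$motif
    extra <- setdiff(names(m), c("topology", "ffl_type", "gate", "stages",
                                 "thresholds", "senses"))
    if (length(extra)) note("motif: unknown key(s): ",
                            paste(extra, collapse = ", "))
    motif <- tryCatch(.build_motif(m),
      error = function(e) { note("motif: ", conditionMessage(e)); NULL })
  }

  tolerances <- list(rtol = 1e-10, atol = 1e-12)
  if (!is.null(raw$tolerances)) {
    for (k in names(raw$tolerances)) {
      v <- raw$tolerances[[k]]
      if (!is.numeric(v) || v <= 0) note("tolerances: `", k,
                                         "` must be a positive number")
      else tolerances[[k]] <- v
    }
  }
  if (length(errs))
    stop("invalid configuration '", path, "':\n  - ",
         paste(errs, collapse = "\n  - "))
  structure(list(signal = signal, motif = motif,
                 experiment = raw$experiment, tolerances = tolerances,
                 name = raw$name %||% basename(path)),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.build_motif <- function(m) {
  topology <- m$topology %||% stop("`topology` is required")
  if (!is.null(m$stages)) {
    # YAML 1.1 reads a bare `Y:` key as boolean; map it back to the gene name
    ns <- names(m$stages)
    ns[ns %in% c("TRUE", "yes", "y")] <- "Y"
    ns[ns == "z"] <- "Z"
    names(m$stages) <- ns
  }
  mkstage <- function(g) {
    sp <- m$stages[[g]]
    if (is.null(sp)) stop("stage `", g, "` is required for topology '",
                          topology, "'")
    gene_stage(g, sp$synth_off %||% 0, sp$synth_on %||%
                 stop("stage ", g, ": synth_on required"),
               sp$degradation %||% stop("stage ", g, ": degradation required"))
  }
  th <- m$thresholds
  need_th <- switch(topology, direct = "k_xy", two_step = c("k_xy", "k_yz"),
                    ffl = c("k_xy", "k_xz", "k_yz"),
                    stop("unknown topology '", topology, "'"))
  miss <- setdiff(need_th, names(th))
  if (length(miss)) stop("missing threshold(s): ", paste(miss, collapse = ", "))
  if (topology == "direct") {
    cfg <- direct_motif(mkstage("Y"), th$k_xy)
  } else if (topology == "two_step") {
    cfg <- two_step_motif(mkstage("Y"), mkstage("Z"), th$k_xy, th$k_yz)
  } else {
    if (is.null(m$ffl_type)) stop("`ffl_type` is required for an FFL")
    gate <- m$gate %||% "AND"
    if (is.null(m$senses)) {
      cfg <- ffl_motif(m$ffl_type, gate, mkstage("Y"), mkstage("Z"),
                       th$k_xy, th$k_xz, th$k_yz)
    } else {
      sn <- function(arm) m$senses[[arm]] %||% "active_above"
      cfg <- motif_config("ffl",
        stages = list(Y = mkstage("Y"), Z = mkstage("Z")),
        edges = list(reg_edge("X", "Y", th$k_xy, sn("xy")),
                     reg_edge("X", "Z", th$k_xz, sn("xz")),
                     reg_edge("Y", "Z", th$k_yz, sn("yz"))),
        ffl_type = m$ffl_type, gate = gate)
    }
  }
  cfg
}

#' Export a simulated time course as CSV
#'
#' Fixed column order: `time`, analog traces (`x`, `y`, `z`), digital
#' traces (`s_xy`, `s_xz`, `s_yz`, `gate`) as 0/1 columns, then `method`.
#' Sample times are the user grid augmented with every exact event time, so
#' the discontinuity structure survives the export.  Comma separator, `.`
#' decimal, no quoting: repeated runs are byte-identical.
#'
#' @param sim a `motif_sim` (from [simulate_motif()]) or `oracle_sim`.
#' @param path output file path.
#' @param n number of regular grid points (event times are added).
#' @return the exported data.frame, invisibly.
#' @export
write_timecourse <- function(sim, path, n = 400) {
  df <- as_timecourse(sim, n = n)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' @rdname write_timecourse
#' @export
as_timecourse <- function(sim, n = 400) {
  if (inherits(sim, "oracle_sim")) {
    df <- data.frame(time = sim$time, x = sim$x, y = sim$y)
    if (!is.null(sim$z)) df$z <- sim$z
    df$method <- sim$method
    return(df)
  }
  stopifnot(inherits(sim, "motif_sim"))
  w <- sim$window
  ev <- unlist(lapply(sim$traces, `[[`, "times"), use.names = FALSE)
  t <- sort(unique(c(seq(w[1L], w[2L], length.out = n), ev)))
  df <- data.frame(time = t, x = signal_value(sim$input, t))
  for (g in c("Y", "Z"))
    if (!is.null(sim$trajectories[[g]]))
      df[[tolower(g)]] <- pwexp_value(sim$trajectories[[g]], t)
  for (tr in c("S_xy", "S_xz", "S_yz", "gate"))
    if (!is.null(sim$traces[[tr]]))
      df[[sub("^S_", "s_", tr)]] <- digital_value(sim$traces[[tr]], t)
  df$method <- "analytic"
  df
}

#' Read back a time-course CSV
#'
#' @param path CSV written by [write_timecourse()].
#' @return data.frame.
#' @export
read_timecourse <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Export a threshold-crossing table as CSV
#'
#' @param crossings data.frame from [crossing_times()].
#' @param path output file path.
#' @export
write_crossings <- function(crossings, path) {
  utils::write.csv(crossings[, c("time", "direction")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(crossings)
}

#' Export stationary statistics as JSON
#'
#' One record per gene, keyed by gene name.
#'
#' @param stat a `motif_stationary` object.
#' @param path output file path.
#' @export
write_stationary_json <- function(stat, path) {
  stopifnot(inherits(stat, "motif_stationary"))
  jsonlite::write_json(stat$stats, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(stat$stats)
}

# Representative figure-level scenarios.  All stages use off/on synthesis
# rates 0 and 1.5 conc/h and degradation 1/h, so the dimensionless period
# equals the period in hours; thresholds are chosen to satisfy each
# scenario's ordering constraints (e.g. gate threshold above or below the
# intermediate's stationary mean).
.fixture_set <- function() {
  st <- list(synth_off = 0, synth_on = 1.5, degradation = 1)
  stages1 <- list(Y = st)
  stages2 <- list(Y = st, Z = st)
  per_grid <- signif(10^seq(-1, 2, length.out = 13), 6)
  cffl <- function(k_xy, k_xz, k_yz, gate = "AND")
    list(topology = "ffl", ffl_type = 1, gate = gate, stages = stages2,
         thresholds = list(k_xy = k_xy, k_xz = k_xz, k_yz = k_yz))
  iffl <- function(k_xy, k_xz, k_yz, gate = "AND")
    list(topology = "ffl", ffl_type = 5, gate = gate, stages = stages2,
         thresholds = list(k_xy = k_xy, k_xz = k_xz, k_yz = k_yz))
  osc <- function(profile = "symmetric", period = 1)
    list(type = "periodic", profile = profile, period = period)
  sweep <- list(periods = per_grid)
  list(
    direct_osc = list(
      name = "direct_osc",
      description = "direct regulation under a symmetric oscillation; gene active 25% of each cycle",
      signal = osc(), experiment = sweep,
      motif = list(topology = "direct", stages = stages1,
                   thresholds = list(k_xy = 0.75))),
    direct_square = list(
      name = "direct_square",
      description = "direct regulation under an idealized square-wave drive",
      signal = list(type = "square", duty = 0.25, period = 1),
      experiment = sweep,
      motif = list(topology = "direct", stages = stages1,
                   thresholds = list(k_xy = 0.5))),
    two_step_high = list(
      name = "two_step_high",
      description = "two-step cascade, downstream threshold above the intermediate mean: shut off at short periods",
      signal = osc(), experiment = sweep,
      motif = list(topology = "two_step", stages = stages2,
                   thresholds = list(k_xy = 0.1, k_yz = 1.3))),
    two_step_low = list(
      name = "two_step_low",
      description = "two-step cascade, downstream threshold below the intermediate mean: fully expressed at short periods",
      signal = osc(), experiment = sweep,
      motif = list(topology = "two_step", stages = stages2,
                   thresholds = list(k_xy = 0.1, k_yz = 0.5))),
    cffl1_and_step = list(
      name = "cffl1_and_step",
      description = "CFFL-1 AND gate, step stimulus: sign-sensitive delay",
      signal = list(type = "step", on_time = 1, off_time = 6),
      motif = cffl(0.5, 0.5, 0.75)),
    cffl1_and_case_a = list(
      name = "cffl1_and_case_a",
      description = "CFFL-1 AND, case A: k_xy < k_xz, k_yz below mean(Y); period-flat",
      signal = osc(), experiment = sweep,
      motif = cffl(0.1, 0.75, 0.5)),
    cffl1_and_case_b = list(
      name = "cffl1_and_case_b",
      description = "CFFL-1 AND, case B: k_yz above mean(Y); high-frequency shutoff",
      signal = osc(), experiment = sweep,
      motif = cffl(0.1, 0.75, 1.3)),
    cffl1_and_case_c = list(
      name = "cffl1_and_case_c",
      description = "CFFL-1 AND, case C: k_xy > k_xz, k_yz below mean(Y)",
      signal = osc(), experiment = sweep,
      motif = cffl(0.75, 0.1, 0.2)),
    cffl1_and_case_d = list(
      name = "cffl1_and_case_d",
      description = "CFFL-1 AND, case D: k_xy > k_xz, k_yz above mean(Y); two-step-like",
      signal = osc(), experiment = sweep,
      motif = cffl(0.75, 0.1, 0.6)),
    cffl1_or_osc = list(
      name = "cffl1_or_osc",
      description = "CFFL-1 with OR gate under the symmetric oscillation",
      signal = osc(), experiment = sweep,
      motif = cffl(0.1, 0.75, 1.3, gate = "OR")),
    iffl1_and_step = list(
      name = "iffl1_and_step",
      description = "IFFL-1 AND gate, sustained step: single expression pulse",
      signal = list(type = "step", on_time = 1, off_time = 6),
      motif = iffl(0.5, 0.5, 0.75)),
    iffl1_and_case_a = list(
      name = "iffl1_and_case_a",
      description = "IFFL-1 AND, case A: repression always overlaps activation",
      signal = osc(), experiment = sweep,
      motif = iffl(0.1, 0.75, 0.5)),
    iffl1_and_case_b = list(
      name = "iffl1_and_case_b",
      description = "IFFL-1 AND, case B: repressor threshold above mean(Y)",
      signal = osc(), experiment = sweep,
      motif = iffl(0.1, 0.75, 1.3)),
    iffl1_and_case_c = list(
      name = "iffl1_and_case_c",
      description = "IFFL-1 AND, case C: low repressor threshold, direct branch triggered first",
      signal = osc(), experiment = sweep,
      motif = iffl(0.75, 0.1, 0.2)),
    iffl1_and_case_d = list(
      name = "iffl1_and_case_d",
      description = "IFFL-1 AND, case D: repression ceases at short periods",
      signal = osc(), experiment = sweep,
      motif = iffl(0.75, 0.1, 0.6)),
    iffl1_or_osc = list(
      name = "iffl1_or_osc",
      description = "IFFL-1 with OR gate under the symmetric oscillation",
      signal = osc(), experiment = sweep,
      motif = iffl(0.75, 0.1, 0.6, gate = "OR")))
}

#' Generate the canonical fixture set
#'
#' Writes the deterministic, seed-free fixture collection: one YAML config
#' per figure-level scenario (direct, two-step, CFFL-1/IFFL-1 cases A-D,
#' step responses, OR-gate variants), plus the anchor tables of the three
#' canonical profiles as CSV.  There is no randomness anywhere in the core
#' model, so repeated calls produce byte-identical files.
#'
#' @param dir output directory (created if needed).
#' @return character vector of written file paths, invisibly.
#' @export
generate_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (fx in .fixture_set()) {
    p <- file.path(dir, paste0(fx$name, ".yaml"))
    yaml::write_yaml(fx, p, precision = 12)
    paths <- c(paths, p)
  }
  prof <- do.call(rbind, lapply(
    c("left_skewed", "symmetric", "right_skewed"), function(lbl) {
      a <- canonical_profile(lbl)$anchors
      data.frame(profile = lbl, time = a[, 1L], value = a[, 2L])
    }))
  p <- file.path(dir, "canonical_profiles.csv")
  utils::write.csv(prof, p, row.names = FALSE, quote = FALSE)
  invisible(c(paths, p))
}
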