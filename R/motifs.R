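#' Kinetic description of one gene
#'
#' A gene is synthesized at a basal rate `synth_off` when its regulatory
#' drive is off and at `synth_on` when the drive is on, and degrades by mass
#' action with rate `degradation`.  The two equilibria are
#' `synth_off/degradation` and `synth_on/degradation`.  `synth_on >
#' synth_off` makes the drive an activator of this gene, the reverse an
#' inhibitor.
#'
#' @param name gene identifier (e.g. `"Y"`, `"Z"`).
#' @param synth_off basal synthesis rate, concentration/hour, >= 0.
#' @param synth_on driven synthesis rate, concentration/hour, >= 0.
#' @param degradation first-order decay rate, 1/hour, > 0.
#' @return object of class `gene_stage`.
#' @export
gene_stage <- function(name, synth_off, synth_on, degradation) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(synth_off), synth_off >= 0,
            is.numeric(synth_on), synth_on >= 0)
  if (!(is.numeric(degradation) && degradation > 0))
    stop("degradation rate must be strictly positive (gene ", name, ")")
  if (synth_on == synth_off)
    stop("synth_on and synth_off must differ (gene ", name,
         "): the drive would have no effect")
  structure(list(name = name, synth_off = synth_off, synth_on = synth_on,
                 degradation = degradation),
            class = "gene_stage")
}

#' @export
print.gene_stage <- function(x, ...) {
  cat("<gene_stage>", x$name, ": rates", x$synth_off, "->", x$synth_on,
      "/h, degradation", x$degradation, "/h (equilibria",
      x$synth_off / x$degradation, "/", x$synth_on / x$degradation, ")\n")
  invisible(x)
}

# equilibria helper
.equilibria <- function(stage)
  c(off = stage$synth_off / stage$degradation,
    on = stage$synth_on / stage$degradation)

#' Regulatory edge with activation threshold
#'
#' One thresholded interaction: the source concentration switches the target
#' condition on when it is above (`"active_above"`) or below
#' (`"active_below"`) the threshold.  `active_below` encodes the repressor
#' arm of a gate (e.g. the IFFL-1 condition that the repressor be absent).
#'
#' @param source source identifier (`"X"` for the input, or a gene name).
#' @param target target gene name.
#' @param threshold activation threshold, > 0.
#' @param sense `"active_above"` or `"active_below"`.
#' @return object of class `reg_edge`.
#' @export
reg_edge <- function(source, target, threshold,
                     sense = c("active_above", "active_below")) {
  sense <- match.arg(sense)
  if (!(is.numeric(threshold) && threshold > 0))
    stop("edge ", source, "->", target, ": threshold must be positive")
  structure(list(source = source, target = target,
                 threshold = threshold, sense = sense),
            class = "reg_edge")
}

# Sign convention table for the eight feed-forward loop types.
# Type 1 is the all-activator loop; types 1-4 are coherent (both paths carry
# the same net sign), 5-8 incoherent.  Columns give the sign of the
# X->Y, Y->Z and X->Z interactions.
ffl_sign_table <- data.frame(
  ffl_type = 1:8,
  class = rep(c("CFFL", "IFFL"), each = 4L),
  label = c("CFFL-1", "CFFL-2", "CFFL-3", "CFFL-4",
            "IFFL-1", "IFFL-2", "IFFL-3", "IFFL-4"),
  sign_xy = c(+1, -1, +1, -1, +1, -1, +1, -1),
  sign_yz = c(+1, -1, -1, +1, -1, +1, +1, -1),
  sign_xz = c(+1, +1, -1, -1, +1, +1, -1, -1))

.edge_sign <- function(edge) if (edge$sense == "active_above") +1 else -1
.rate_sign <- function(stage) sign(stage$synth_on - stage$synth_off)

#' Motif configuration
#'
#' Assembles a regulatory motif from gene stages and thresholded edges.
#' Three topologies are supported: `direct` (X->Y), `two_step` (X->Y->Z) and
#' `ffl` (X->Y, X->Z, Y->Z combined by an AND/OR gate at Z).  Feedback
#' (cyclic) edge sets are rejected.  For an FFL the declared `ffl_type`
#' (1-8, type 1 = all activators) must agree with the net interaction signs
#' derived from the edge senses and the stages' rate orderings; repression
#' may be expressed either way (a `sense = "active_below"` edge or a stage
#' with `synth_on < synth_off`), and the config states which.
#'
#' @param topology `"direct"`, `"two_step"` or `"ffl"`.
#' @param stages named list of [gene_stage()] objects (`Y`, and `Z` for
#'   two-step/FFL topologies).
#' @param edges list of [reg_edge()] objects matching the topology.
#' @param ffl_type integer 1-8 (FFL topologies only).
#' @param gate `"AND"` or `"OR"` (FFL topologies only).
#' @return object of class `motif_config`.
#' @export
motif_config <- function(topology = c("direct", "two_step", "ffl"),
                         stages, edges, ffl_type = NULL, gate = NULL) {
  topology <- match.arg(topology)
  stopifnot(is.list(stages), all(vapply(stages, inherits, TRUE, "gene_stage")),
            is.list(edges), all(vapply(edges, inherits, TRUE, "reg_edge")))
  names(stages) <- vapply(stages, `[[`, "", "name")
  keys <- vapply(edges, function(e) paste0(e$source, "->", e$target), "")
  names(edges) <- keys
  need <- switch(topology,
    direct = "X->Y",
    two_step = c("X->Y", "Y->Z"),
    ffl = c("X->Y", "X->Z", "Y->Z"))
  if (!setequal(keys, need))
    stop("edge set {", paste(keys, collapse = ", "),
         "} inconsistent with topology '", topology, "' (expected {",
         paste(need, collapse = ", "), "})")
  for (e in edges)
    if (e$target == "X" || identical(e$source, e$target) ||
        (e$source == "Z"))
      stop("cyclic or invalid edge ", e$source, "->", e$target,
           ": feedback topologies are not supported")
  need_genes <- if (topology == "direct") "Y" else c("Y", "Z")
  if (!setequal(names(stages), need_genes))
    stop("stages must define exactly {", paste(need_genes, collapse = ", "),
         "} for topology '", topology, "'")
  if (topology == "ffl") {
    if (is.null(ffl_type) || !ffl_type %in% 1:8)
      stop("ffl_type must be an integer in 1..8")
    gate <- match.arg(gate, c("AND", "OR"))
    s_xy <- .edge_sign(edges[["X->Y"]]) * .rate_sign(stages$Y)
    s_yz <- .edge_sign(edges[["Y->Z"]]) * .rate_sign(stages$Z)
    s_xz <- .edge_sign(edges[["X->Z"]]) * .rate_sign(stages$Z)
    row <- ffl_sign_table[ffl_type, ]
    if (s_xy != row$sign_xy || s_yz != row$sign_yz || s_xz != row$sign_xz)
      stop("declared ffl_type ", ffl_type, " (", row$label,
           ", signs xy=", row$sign_xy, " yz=", row$sign_yz,
           " xz=", row$sign_xz, ") does not match the edge senses and rate",
           " orderings (derived xy=", s_xy, " yz=", s_yz, " xz=", s_xz, ")")
  } else {
    ffl_type <- NULL; gate <- NULL
  }
  structure(list(topology = topology, stages = stages, edges = edges,
                 ffl_type = ffl_type, gate = gate),
            class = "motif_config")
}

#' @export
print.motif_config <- function(x, ...) {
  lbl <- if (x$topology == "ffl")
    paste0(ffl_sign_table$label[x$ffl_type], " (", x$gate, " gate)")
  else x$topology
  cat("<motif_config>", lbl, "\n")
  for (e in x$edges)
    cat("  ", e$source, "->", e$target, " threshold ", e$threshold,
        " (", e$sense, ")\n", sep = "")
  for (s in x$stages) print(s)
  invisible(x)
}

#' Coherence class of an FFL configuration
#'
#' @param config an FFL [motif_config()].
#' @return `"CFFL"` if both regulatory paths from X to Z carry the same net
#'   sign, `"IFFL"` otherwise.
#' @export
ffl_class <- function(config) {
  stopifnot(inherits(config, "motif_config"), config$topology == "ffl")
  ffl_sign_table$class[config$ffl_type]
}

#' Convenience constructors for the standard motifs
#'
#' `direct_motif()`, `two_step_motif()` and `ffl_motif()` assemble
#' [motif_config()] objects from rates and thresholds.  `ffl_motif()`
#' realizes any of the eight loop types by flipping the senses of the gate
#' arms and (for a repressive X->Y arm) of the intermediate's drive, keeping
#' all stages activator-ordered (`synth_on > synth_off`).
#'
#' @param y,z [gene_stage()] objects for the intermediate and target genes.
#' @param k_xy,k_xz,k_yz activation thresholds for the X->Y, X->Z and Y->Z
#'   interactions.
#' @param ffl_type integer 1-8.
#' @param gate `"AND"` or `"OR"`.
#' @return a [motif_config()].
#' @export
direct_motif <- function(y, k_xy) {
  motif_config("direct", stages = list(Y = y),
               edges = list(reg_edge("X", "Y", k_xy)))
}

#' @rdname direct_motif
#' @export
two_step_motif <- function(y, z, k_xy, k_yz) {
  motif_config("two_step", stages = list(Y = y, Z = z),
               edges = list(reg_edge("X", "Y", k_xy),
                            reg_edge("Y", "Z", k_yz)))
}

#' @rdname direct_motif
#' @export
ffl_motif <- function(ffl_type, gate, y, z, k_xy, k_xz, k_yz) {
  row <- ffl_sign_table[ffl_type, ]
  sense_of <- function(s) if (s > 0) "active_above" else "active_below"
  motif_config("ffl",
               stages = list(Y = y, Z = z),
               edges = list(
                 reg_edge("X", "Y", k_xy, sense_of(row$sign_xy)),
                 reg_edge("X", "Z", k_xz, sense_of(row$sign_xz)),
                 reg_edge("Y", "Z", k_yz, sense_of(row$sign_yz))),
               ffl_type = ffl_type, gate = gate)
}

#' Piecewise-constant synthesis-rate trace of a driven gene
#'
#' Maps a digital drive onto the gene's synthesis rate: `synth_on` where the
#' drive is 1 and `synth_off` where it is 0, with identical switch times.
#'
#' @param stage a [gene_stage()].
#' @param drive a [digital_trace()].
#' @return object of class `rate_trace`: fields `breaks` (interval
#'   endpoints) and `rates` (one synthesis rate per interval).
#' @export
synthesis_rate_trace <- function(stage, drive) {
  stopifnot(inherits(stage, "gene_stage"), inherits(drive, "digital_trace"))
  iv <- trace_intervals(drive)
  structure(list(breaks = c(iv$start, iv$end[nrow(iv)]),
                 rates = ifelse(iv$state == 1L, stage$synth_on,
                                stage$synth_off),
                 window = drive$window),
            class = "rate_trace")
}
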