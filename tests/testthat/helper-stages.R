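# standard stages used across tests: off/on rates 0 and 1.5 conc/h,
# unit degradation, so dimensionless period == period in hours
std_y <- function() gene_stage("Y", 0, 1.5, 1)
std_z <- function() gene_stage("Z", 0, 1.5, 1)

# a digital trace with pseudo-random switch times (test plumbing only;
# the model itself is deterministic)
random_trace <- function(window = c(0, 1), n_switch = 5L) {
  times <- sort(stats::runif(n_switch, window[1L] + 1e-3, window[2L] - 1e-3))
  digital_trace(times, sample(0:1, 1L), window)
}

canonical_labels <- c("left_skewed", "symmetric", "right_skewed")
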