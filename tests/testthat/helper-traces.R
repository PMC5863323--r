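# Shared fixtures: all synthetic, built in code at test time.

# trace from raw values at 5-min spacing
make_trace <- function(values, trace_id = "t") {
  glucose_trace(seq(0, by = 300, length.out = length(values)), values,
                trace_id = trace_id)
}

# the canonical 5-point zigzag used throughout: values 5,8,4,9,5
zigzag_trace <- function() make_trace(c(5, 8, 4, 9, 5))

zigzag_problem <- function(threshold = 2.168, comparator = "ge") {
  selection_problem(c(5, 8, 4, 9, 5),
                    c("min", "max", "min", "max", "min"),
                    threshold = threshold, comparator = comparator)
}

# random wiggly trace with guaranteed strict alternation (no plateaus)
random_plateau_free_trace <- function(n = 60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- 6 + cumsum(rnorm(n, 0, 0.8))
  v <- v - min(v) + 2
  # nudge any accidental equal neighbours apart
  eq <- which(diff(v) == 0)
  if (length(eq)) v[eq + 1L] <- v[eq + 1L] + 1e-6
  make_trace(v)
}

# write a trace as a CSV file in the default cgm_io dialect
write_trace_csv <- function(trace, path, unit = c("mmol_L", "mg_dL")) {
  unit <- match.arg(unit)
  vals <- if (unit == "mg_dL") mmol_to_mgdl(trace$values) else trace$values
  df <- data.frame(time = trace$times, glucose = vals)
  write.csv(df, path, row.names = FALSE)
  path
}

expect_same_optimum <- function(a, b, tol = 1e-9) {
  if (is.null(a) || is.null(b)) {
    expect_true(is.null(a) && is.null(b))
  } else {
    expect_identical(a$k, b$k)
    expect_lt(abs(a$z - b$z), tol)
  }
}

# seeded planted trace for the recovery suites. The suites condition on
# every planted amplitude clearing 1.5x the realized SDBG of the
# interpolated trace; amplitudes within a factor 2 of each other usually
# satisfy that, and draws that do not (long alternating drifts inflate the
# SD) are rejected and redrawn deterministically.
random_planted_trace <- function(seed) {
  for (attempt in 0:40) {
    set.seed(seed + 1e6 * attempt)
    n_exc <- sample(2:10, 1)
    pt <- generate_alternating_trace(
      runif(n_exc, 2.5, 5), baseline = runif(1, 8, 12),
      samples_per_leg = sample(2:8, 1),
      first_direction = sample(c("up", "down"), 1))
    if (pt$truth$sd_multiple >= 1.5) return(pt)
  }
  stop("could not draw a planted trace with sd_multiple >= 1.5")
}
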