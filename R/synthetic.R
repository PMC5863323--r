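# Synthetic CGM-like traces with known excursion structure, and random
# selection-problem instances for the oracle suites. These generators give
# every solver a testable ground truth without any clinical data.

#' Generate a piecewise-linear trace with planted excursions
#'
#' Builds a trace that rises and falls alternately by the given amplitudes
#' from a baseline, linearly interpolated at 5-minute CGM spacing. The
#' returned ground truth records the vertex positions and the MAGE
#' statistics implied when every planted amplitude qualifies, plus the
#' realized ratio of the smallest amplitude to the trace's own SDBG
#' (`sd_multiple`) so callers can verify the planted excursions clear the
#' threshold.
#'
#' @param amplitudes positive amplitudes (mmol/L) of consecutive legs,
#'   applied alternately up/down.
#' @param baseline starting glucose (mmol/L), default 5.
#' @param samples_per_leg number of 5-minute sampling intervals per leg
#'   (1 = vertices only). Default 6 (a 30-minute swing).
#' @param first_direction `"up"` (default) or `"down"` for the first leg.
#' @param dt sample spacing in seconds (default 300).
#' @return list with elements `trace` (a [glucose_trace()]) and `truth`
#'   (class `planted_truth`: vertex indices/kinds/values, `mage_plus`,
#'   `mage_minus`, `mage`, `mage_a`, `sdbg`, `sd_multiple`).
#' @examples
#' pt <- generate_alternating_trace(c(3, 4, 5, 4), baseline = 5,
#'                                  samples_per_leg = 1)
#' pt$truth$mage
#' @export
generate_alternating_trace <- function(amplitudes, baseline = 5,
                                       samples_per_leg = 6L,
                                       first_direction = c("up", "down"),
                                       dt = 300) {
  first_direction <- match.arg(first_direction)
  amplitudes <- as.numeric(amplitudes)
  stopifnot(length(amplitudes) >= 1L, all(amplitudes > 0),
            samples_per_leg >= 1L)
  n_leg <- length(amplitudes)
  s0 <- if (first_direction == "up") 1 else -1
  signs <- s0 * (-1)^(seq_len(n_leg) - 1L)
  vertex_vals <- baseline + cumsum(c(0, signs * amplitudes))
  if (any(vertex_vals <= 0)) {
    stop("amplitudes drive the trace non-positive; raise `baseline`",
         call. = FALSE)
  }
  spl <- as.integer(samples_per_leg)
  # interpolate each leg at spl intervals
  vertex_idx <- 1L + (0:n_leg) * spl
  values <- approx(x = vertex_idx, y = vertex_vals,
                   xout = seq_len(n_leg * spl + 1L))$y
  times <- (seq_along(values) - 1L) * dt
  trace <- glucose_trace(times, values, trace_id = "planted")

  kinds <- rep(c(if (s0 > 0) "min" else "max",
                 if (s0 > 0) "max" else "min"),
               length.out = n_leg + 1L)
  rising <- signs > 0
  mage_plus <- if (any(rising)) mean(amplitudes[rising]) else NA_real_
  mage_minus <- if (any(!rising)) mean(amplitudes[!rising]) else NA_real_
  mage <- if (kinds[1L] == "min") mage_plus else mage_minus
  mage_a <- if (!is.na(mage_plus) && !is.na(mage_minus)) {
    (mage_plus + mage_minus) / 2
  } else if (!is.na(mage_plus)) mage_plus else mage_minus
  sdbg <- sd(values)
  truth <- structure(
    list(vertex_indices = vertex_idx, vertex_kinds = kinds,
         vertex_values = vertex_vals, amplitudes = amplitudes,
         mage_plus = mage_plus, mage_minus = mage_minus,
         mage = mage, mage_a = mage_a,
         sdbg = sdbg, sd_multiple = min(amplitudes) / sdbg),
    class = "planted_truth")
  list(trace = trace, truth = truth)
}

#' Add noise and plateaus to a trace
#'
#' Adds i.i.d. Gaussian noise to every value and, with probability
#' `plateau_prob` per adjacent pair, copies a value into its successor to
#' create the equal-valued turning runs that the plateau-merging rule must
#' handle. With `noise_sd = 0` and `plateau_prob = 0` the trace is returned
#' unchanged. Noisy values are floored at 0.1 mmol/L to keep the trace
#' valid.
#'
#' @param base a [glucose_trace()].
#' @param noise_sd Gaussian noise SD in mmol/L (>= 0).
#' @param plateau_prob per-pair probability of duplicating a value forward.
#' @param seed RNG seed for reproducibility (`NULL`: current RNG state).
#' @return a [glucose_trace()].
#' @export
generate_noisy_trace <- function(base, noise_sd = 0, plateau_prob = 0,
                                 seed = NULL) {
  stopifnot(inherits(base, "glucose_trace"), noise_sd >= 0,
            plateau_prob >= 0, plateau_prob <= 1)
  if (!is.null(seed)) set.seed(seed)
  v <- base$values
  n <- length(v)
  if (noise_sd > 0) v <- pmax(v + rnorm(n, 0, noise_sd), 0.1)
  if (plateau_prob > 0) {
    dup <- runif(n - 1L) < plateau_prob
    for (i in which(dup)) v[i + 1L] <- v[i]
  }
  glucose_trace(base$times, v, trace_id = base$trace_id,
                start_time = base$start_time)
}

#' Generate a random selection-problem instance
#'
#' Draws an alternating extreme-value sequence (adjacent amplitudes uniform
#' on 0.3-4 mmol/L, random first kind) and sets the threshold at the given
#' quantile of the adjacent amplitudes, so that qualifying and
#' non-qualifying amplitudes both occur. Used by the oracle-equivalence
#' suites.
#'
#' @param n_extremes number of extreme points N (>= 0).
#' @param threshold_quantile quantile of adjacent amplitudes used as the
#'   threshold (0 = every amplitude qualifies, 1 = only the largest).
#' @param seed RNG seed (`NULL`: current RNG state).
#' @return a [selection_problem()].
#' @export
generate_random_problem <- function(n_extremes, threshold_quantile = 0.5,
                                    seed = NULL) {
  stopifnot(n_extremes >= 0, threshold_quantile >= 0,
            threshold_quantile <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_extremes)
  if (n == 0L) {
    return(selection_problem(numeric(0), character(0), threshold = 0))
  }
  first <- sample(c("min", "max"), 1L)
  kinds <- rep(c(first, setdiff(c("min", "max"), first)), length.out = n)
  if (n == 1L) {
    return(selection_problem(6, kinds, threshold = 0))
  }
  amps <- runif(n - 1L, 0.3, 4)
  signs <- (if (first == "min") 1 else -1) * (-1)^(seq_len(n - 1L) - 1L)
  vals <- 6 + cumsum(c(0, signs * amps))
  vals <- vals - min(vals) + 1  # keep values positive for realism
  # threshold from the REALIZED adjacent amplitudes (diff of the stored
  # values), so that quantile 0 makes every adjacent step qualify exactly
  thr <- as.numeric(quantile(abs(diff(vals)), threshold_quantile))
  selection_problem(vals, kinds, threshold = thr)
}
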