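# Excursion core: SDBG, extreme-point extraction with plateau merging,
# and MAGE statistics from an optimal selection.

#' Standard deviation of blood glucose (SDBG)
#'
#' SDBG over all values of a trace is the classical MAGE threshold: an
#' excursion is countable when its amplitude reaches the SDBG of the
#' 24-hour trace it belongs to.
#'
#' @param trace a [glucose_trace()] (or plain numeric vector of values).
#' @param ddof degrees-of-freedom correction: `1` (default) for the sample
#'   standard deviation (denominator n-1), `0` for the population form
#'   (denominator n).
#' @return SDBG in mmol/L.
#' @export
compute_sdbg <- function(trace, ddof = 1) {
  v <- if (inherits(trace, "glucose_trace")) trace$values else as.numeric(trace)
  n <- length(v)
  if (n < 2L) stop("SDBG needs at least 2 values", call. = FALSE)
  if (!ddof %in% c(0, 1)) stop("`ddof` must be 0 or 1", call. = FALSE)
  s <- sd(v)
  if (ddof == 0) s <- s * sqrt((n - 1) / n)
  s
}

#' Extract the alternating extreme-point sequence of a trace
#'
#' Finds all local maxima (peaks) and local minima (nadirs) of the glucose
#' series. Runs of equal consecutive values (plateaus) are merged into the
#' last point of the run, which is then typed by the run's neighbours: a
#' plateau preceded by a fall and followed by a rise becomes a single nadir
#' at the run's last index, and symmetrically for peaks. By default the
#' first and last trace points are included as extreme points, typed by
#' their single neighbour, so an opening or closing excursion can be
#' counted. The returned kinds strictly alternate by construction.
#'
#' @param trace a [glucose_trace()].
#' @param include_endpoints include the trace endpoints as extreme points
#'   (default `TRUE`).
#' @return an object of class `extreme_points` with fields `indices`
#'   (1-based positions into the trace), `kinds` (`"min"`/`"max"`),
#'   `values`, `times` and `n`. A constant trace yields `n = 0`.
#' @export
find_extreme_points <- function(trace, include_endpoints = TRUE) {
  stopifnot(inherits(trace, "glucose_trace"))
  v <- trace$values
  L <- length(v)
  # plateau merging: keep the LAST index of each run of equal values
  keep <- c(v[-L] != v[-1L], TRUE)
  idx <- which(keep)
  w <- v[idx]
  m <- length(w)
  empty <- structure(
    list(indices = integer(0), kinds = character(0),
         values = numeric(0), times = numeric(0), n = 0L),
    class = "extreme_points")
  if (m < 2L) return(empty)  # constant trace
  d <- sign(diff(w))  # nonzero after merging
  turn <- which(d[-1L] != d[-(m - 1L)]) + 1L  # positions in w
  kinds <- ifelse(d[turn - 1L] > 0, "max", "min")
  pos <- turn
  if (include_endpoints) {
    pos <- c(1L, pos, m)
    kinds <- c(if (d[1L] > 0) "min" else "max",
               kinds,
               if (d[m - 1L] > 0) "max" else "min")
  }
  if (length(pos) < 2L) return(empty)
  structure(
    list(indices = idx[pos], kinds = unname(kinds),
         values = w[pos], times = trace$times[idx[pos]],
         n = length(pos)),
    class = "extreme_points")
}

#' @export
print.extreme_points <- function(x, ...) {
  cat(sprintf("<extreme_points> n = %d (%d peaks, %d nadirs)\n",
              x$n, sum(x$kinds == "max"), sum(x$kinds == "min")))
  invisible(x)
}

new_mage_result <- function(trace_id, sdbg, mage_plus, mage_minus, mage,
                            mage_a, direction, n_excursions,
                            selected_times, selected_values,
                            selected_indices = integer(0)) {
  structure(
    list(trace_id = as.character(trace_id), sdbg = as.numeric(sdbg),
         mage_plus = as.numeric(mage_plus),
         mage_minus = as.numeric(mage_minus),
         mage = as.numeric(mage), mage_a = as.numeric(mage_a),
         direction = as.character(direction),
         n_excursions = as.integer(n_excursions),
         selected_times = as.numeric(selected_times),
         selected_values = as.numeric(selected_values),
         selected_indices = as.integer(selected_indices)),
    class = "mage_result")
}

#' @export
print.mage_result <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.3f", v)
  cat(sprintf("<mage_result '%s'>\n", x$trace_id))
  cat(sprintf("  SDBG  = %s mmol/L\n", fmt(x$sdbg)))
  cat(sprintf("  MAGE+ = %s  MAGE- = %s  MAGEa = %s mmol/L\n",
              fmt(x$mage_plus), fmt(x$mage_minus), fmt(x$mage_a)))
  cat(sprintf("  MAGE  = %s mmol/L (%s; %d countable excursion%s)\n",
              fmt(x$mage), x$direction, x$n_excursions,
              if (x$n_excursions == 1L) "" else "s"))
  invisible(x)
}

#' MAGE statistics from an optimal extreme-point selection
#'
#' Given a feasible selection of alternating extreme points whose adjacent
#' amplitudes all pass the threshold, computes the directional excursion
#' means. MAGE+ is the mean of rising (nadir-to-peak) amplitudes and MAGE-
#' the mean of falling (peak-to-nadir) amplitudes among the selected points.
#' MAGE equals MAGE+ when the first selected extreme is a nadir (the first
#' countable excursion rises) and MAGE- when it is a peak. MAGEa is the mean
#' of MAGE+ and MAGE- when both exist, otherwise the one that is defined;
#' an absent direction is reported as `NA`, never 0.
#'
#' @param selection integer vector of selected positions into the problem's
#'   extreme sequence (a `mage_selection` from a solver is also accepted).
#' @param problem a [selection_problem()].
#' @param sdbg SDBG of the parent trace, carried into the result.
#' @param trace_id,times optional labelling / selected-point times.
#' @return a `mage_result`.
#' @export
compute_mage_from_selection <- function(selection, problem, sdbg,
                                        trace_id = "trace", times = NULL) {
  if (inherits(selection, "mage_selection")) selection <- selection$indices
  sel <- as.integer(selection)
  if (length(sel) < 2L) {
    stop("a selection needs at least 2 extreme points (no countable ",
         "excursion otherwise)", call. = FALSE)
  }
  feas <- is_feasible(sel, problem)
  if (!feas) {
    stop("selection is infeasible: ",
         paste(attr(feas, "violations")$type, collapse = ", "),
         call. = FALSE)
  }
  v <- problem$extreme_values[sel]
  kinds <- problem$extreme_kinds[sel]
  amps <- abs(diff(v))
  rising <- kinds[-length(kinds)] == "min"
  mage_plus <- if (any(rising)) mean(amps[rising]) else NA_real_
  mage_minus <- if (any(!rising)) mean(amps[!rising]) else NA_real_
  upward_first <- kinds[1L] == "min"
  mage <- if (upward_first) mage_plus else mage_minus
  mage_a <- if (!is.na(mage_plus) && !is.na(mage_minus)) {
    (mage_plus + mage_minus) / 2
  } else if (!is.na(mage_plus)) mage_plus else mage_minus
  new_mage_result(
    trace_id = trace_id, sdbg = sdbg,
    mage_plus = mage_plus, mage_minus = mage_minus,
    mage = mage, mage_a = mage_a,
    direction = if (upward_first) "upward" else "downward",
    n_excursions = length(amps),
    selected_times = if (is.null(times)) rep(NA_real_, length(sel)) else
      times[sel],
    selected_values = v, selected_indices = sel)
}

#' Compute MAGE for a glucose trace
#'
#' Runs the full pipeline: SDBG threshold, extreme-point extraction with
#' plateau merging, optimal selection of countable excursions, and MAGE
#' statistics. The default solver is the exact dynamic program; the
#' differential-evolution solver (`solver = "de"`) is the stochastic
#' alternative, useful for studying the evolutionary search itself.
#'
#' @param trace a [glucose_trace()].
#' @param sd_ddof SDBG denominator: 1 for n-1 (default), 0 for n.
#' @param threshold_multiplier threshold is `threshold_multiplier * SDBG`
#'   (default 1).
#' @param threshold explicit threshold in mmol/L, overriding the SDBG
#'   multiple (useful for comparing traces under one common threshold).
#' @param comparator `"ge"` (amplitude qualifies when >= threshold, default)
#'   or `"gt"` (strictly greater).
#' @param include_endpoints count the trace endpoints as extreme points
#'   (default `TRUE`).
#' @param solver `"dp"` (exact, default), `"de"` (differential evolution) or
#'   `"bruteforce"` (exhaustive; small traces only).
#' @param config a [de_config()] for `solver = "de"`.
#' @param empty_policy when no countable excursion exists: report MAGE as
#'   `NA` (`"nan"`, default) or `0` (`"zero"`).
#' @return a `mage_result`.
#' @examples
#' tr <- glucose_trace(seq(0, by = 300, length.out = 5), c(5, 8, 4, 9, 5))
#' calculate_mage(tr)
#' @export
calculate_mage <- function(trace, sd_ddof = 1, threshold_multiplier = 1,
                           threshold = NULL, comparator = c("ge", "gt"),
                           include_endpoints = TRUE,
                           solver = c("dp", "de", "bruteforce"),
                           config = de_config(),
                           empty_policy = c("nan", "zero")) {
  comparator <- match.arg(comparator)
  solver <- match.arg(solver)
  empty_policy <- match.arg(empty_policy)
  stopifnot(inherits(trace, "glucose_trace"))
  sdbg <- compute_sdbg(trace, ddof = sd_ddof)
  thr <- if (is.null(threshold)) threshold_multiplier * sdbg else threshold
  ep <- find_extreme_points(trace, include_endpoints = include_endpoints)
  prob <- selection_problem(ep$values, ep$kinds, threshold = thr,
                            comparator = comparator)
  sel <- if (ep$n < 2L) NULL else switch(
    solver,
    dp = solve_exact_dp(prob),
    bruteforce = solve_exact_bruteforce(prob),
    de = solve_de(prob, config))
  if (is.null(sel)) {
    none <- if (empty_policy == "nan") NA_real_ else 0
    return(new_mage_result(
      trace_id = trace$trace_id, sdbg = sdbg,
      mage_plus = none, mage_minus = none, mage = none, mage_a = none,
      direction = "none", n_excursions = 0L,
      selected_times = numeric(0), selected_values = numeric(0)))
  }
  res <- compute_mage_from_selection(sel, prob, sdbg,
                                     trace_id = trace$trace_id,
                                     times = ep$times)
  res$selected_indices <- ep$indices[sel$indices]
  res
}
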