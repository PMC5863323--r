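# Integer-nonlinear-programming view of excursion selection: choose an
# alternating subsequence of the N extreme points whose adjacent amplitudes
# all pass the threshold, maximizing (K, Z) lexicographically where K is the
# number of selected points and Z the total amplitude. Exact solvers
# (enumeration and dynamic programming) serve as oracles for the stochastic
# solver.

.Z_TOL <- 1e-9  # tolerance for comparing total amplitudes between solvers

#' Construct an excursion-selection problem
#'
#' The instance consists of the ordered extreme values of a trace (with
#' strictly alternating peak/nadir kinds), the amplitude threshold (a
#' multiple of SDBG), and the comparator deciding when an amplitude
#' qualifies.
#'
#' @param extreme_values numeric vector of extreme-point glucose values.
#' @param extreme_kinds character vector, `"min"`/`"max"`, strictly
#'   alternating, same length as `extreme_values`.
#' @param threshold amplitude threshold in mmol/L (>= 0).
#' @param comparator `"ge"` (default): amplitude qualifies when
#'   `>= threshold`; `"gt"`: strictly greater.
#' @return an object of class `selection_problem`.
#' @export
selection_problem <- function(extreme_values, extreme_kinds, threshold,
                              comparator = c("ge", "gt")) {
  comparator <- match.arg(comparator)
  extreme_values <- as.numeric(extreme_values)
  extreme_kinds <- as.character(extreme_kinds)
  n <- length(extreme_values)
  if (length(extreme_kinds) != n) {
    stop("`extreme_values` and `extreme_kinds` must have equal length",
         call. = FALSE)
  }
  if (n && !all(extreme_kinds %in% c("min", "max"))) {
    stop("kinds must be 'min' or 'max'", call. = FALSE)
  }
  if (n > 1L && any(extreme_kinds[-1L] == extreme_kinds[-n])) {
    stop("extreme kinds must strictly alternate", call. = FALSE)
  }
  if (!is.finite(threshold) || threshold < 0) {
    stop("`threshold` must be finite and >= 0", call. = FALSE)
  }
  structure(
    list(extreme_values = extreme_values, extreme_kinds = extreme_kinds,
         threshold = as.numeric(threshold), comparator = comparator),
    class = "selection_problem")
}

#' @export
print.selection_problem <- function(x, ...) {
  cat(sprintf(
    "<selection_problem> N = %d extreme points, threshold = %.4g (%s)\n",
    length(x$extreme_values), x$threshold,
    if (x$comparator == "ge") ">=" else ">"))
  invisible(x)
}

.check_indices <- function(sel, problem) {
  n <- length(problem$extreme_values)
  if (length(sel) && (anyNA(sel) || any(sel < 1L) || any(sel > n))) {
    stop("selection indices out of range 1..", n, call. = FALSE)
  }
}

.amp_pass <- function(amp, problem) {
  if (problem$comparator == "ge") amp >= problem$threshold
  else amp > problem$threshold
}

# signed directional amplitude of each selected step: a step leaving a nadir
# must rise, a step leaving a peak must fall, so the amplitude carries the
# sign of the expected direction. For a feasible selection it equals |dv|;
# a wrong-direction step comes out negative and can never pass a positive
# threshold (counting a "downward excursion" from a peak to a HIGHER nadir
# would be meaningless).
.step_amplitudes <- function(sel, problem) {
  v <- problem$extreme_values[sel]
  s <- ifelse(problem$extreme_kinds[sel] == "min", 1, -1)
  s[-length(s)] * diff(v)
}

new_mage_selection <- function(indices, z, per_k = NULL) {
  structure(list(indices = as.integer(indices), k = length(indices),
                 z = as.numeric(z), per_k = per_k),
            class = "mage_selection")
}

#' @export
print.mage_selection <- function(x, ...) {
  cat(sprintf("<mage_selection> K = %d, Z = %.4f; indices: %s\n",
              x$k, x$z, paste(x$indices, collapse = " ")))
  invisible(x)
}

#' Total amplitude of a candidate selection
#'
#' `Z = sum over consecutive selected points of |v(n_{k+1}) - v(n_k)|`.
#' No feasibility check is applied.
#'
#' @param selection integer vector of positions into the extreme sequence
#'   (strictly increasing for a valid candidate; repeats are tolerated as
#'   they arise as intermediates in the stochastic solver).
#' @param problem a [selection_problem()].
#' @return total amplitude in mmol/L (0 for fewer than 2 indices).
#' @export
objective_z <- function(selection, problem) {
  if (inherits(selection, "mage_selection")) selection <- selection$indices
  sel <- as.integer(selection)
  .check_indices(sel, problem)
  if (length(sel) < 2L) return(0)
  sum(abs(diff(problem$extreme_values[sel])))
}

#' Feasibility of a candidate selection
#'
#' A selection is feasible when (i) every adjacent *directional* amplitude
#' passes the comparator against the threshold — the step leaving a nadir
#' must rise by that much, the step leaving a peak must fall by it — and
#' (ii) every adjacent index difference is odd, which on an alternating
#' extreme list is exactly the requirement that selected kinds alternate
#' peak/nadir. The direction requirement rules out degenerate monotone
#' "staircase" selections in which a peak below a later nadir would be
#' counted as a falling excursion. Selections with fewer than 2 points are
#' infeasible (no countable excursion).
#'
#' @inheritParams objective_z
#' @return logical; attribute `"violations"` is a data frame with columns
#'   `k` (position of the violating step) and `type`
#'   (`"amplitude"`/`"parity"`/`"too_short"`).
#' @export
is_feasible <- function(selection, problem) {
  if (inherits(selection, "mage_selection")) selection <- selection$indices
  sel <- as.integer(selection)
  .check_indices(sel, problem)
  if (length(sel) < 2L) {
    return(structure(FALSE, violations = data.frame(
      k = 0L, type = "too_short", stringsAsFactors = FALSE)))
  }
  d <- .step_amplitudes(sel, problem)
  dn <- diff(sel)
  amp_bad <- which(!.amp_pass(d, problem))
  par_bad <- which(dn %% 2L == 0L)
  viol <- rbind(
    if (length(amp_bad)) data.frame(k = amp_bad, type = "amplitude",
                                    stringsAsFactors = FALSE),
    if (length(par_bad)) data.frame(k = par_bad, type = "parity",
                                    stringsAsFactors = FALSE))
  if (is.null(viol)) viol <- data.frame(k = integer(0), type = character(0),
                                        stringsAsFactors = FALSE)
  structure(nrow(viol) == 0L, violations = viol)
}

#' Penalty-relaxed objective
#'
#' Unconstrained form of the selection problem used by the stochastic
#' solver: `Y = -sum_k d_k + sum_k mu * max(0, g_k)^2 + sum_k lam * h_k^2`,
#' where `d_k` is the signed directional amplitude of step k (rise leaving a
#' nadir, fall leaving a peak; equal to `|v(n_{k+1}) - v(n_k)|` on feasible
#' selections), `g_k = threshold - d_k` is the amplitude shortfall and
#' `h_k = (-1)^(n_{k+1} - n_k) + 1` the parity violation. For a feasible
#' selection all penalty terms vanish and `Y = -Z` exactly; any violation
#' makes `Y > -Z`.
#'
#' @inheritParams objective_z
#' @param mu,lam positive penalty weights for the amplitude and parity
#'   constraints.
#' @return scalar penalized objective (to be minimized).
#' @export
penalty_objective_y <- function(selection, problem, mu, lam) {
  if (inherits(selection, "mage_selection")) selection <- selection$indices
  sel <- as.integer(selection)
  .check_indices(sel, problem)
  stopifnot(mu > 0, lam > 0)
  if (length(sel) < 2L) return(0)
  d <- .step_amplitudes(sel, problem)
  g <- problem$threshold - d
  h <- (-1)^(diff(sel)) + 1
  -sum(d) + mu * sum(pmax(0, g)^2) + lam * sum(h^2)
}

# lexicographic comparison of index vectors: TRUE if a < b
.lex_less <- function(a, b) {
  la <- length(a); lb <- length(b)
  m <- min(la, lb)
  for (i in seq_len(m)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  la < lb
}

# candidate (K, Z, idx) better than incumbent under (max K, max Z, lex-min)?
.better <- function(k, z, idx, bk, bz, bidx) {
  if (is.null(bidx)) return(TRUE)
  if (k != bk) return(k > bk)
  if (abs(z - bz) > .Z_TOL) return(z > bz)
  .lex_less(idx, bidx)
}

# all index subsets of 1..n with size >= 2, cached per n (n <= 20)
.subset_cache <- new.env(parent = emptyenv())
.all_subsets <- function(n) {
  key <- as.character(n)
  if (!is.null(.subset_cache[[key]])) return(.subset_cache[[key]])
  subs <- list()
  for (mask in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) != 0L)
    if (length(idx) >= 2L) subs[[length(subs) + 1L]] <- idx
  }
  .subset_cache[[key]] <- subs
  subs
}

#' Exact solver by exhaustive enumeration
#'
#' Enumerates every subsequence of the extreme points with `2 <= K <= N`
#' (exponentially many, hence the guard) and returns a feasible one that is
#' optimal under the ordering: maximal K first, then maximal Z, then
#' lexicographically smallest index vector. Intended as the ground-truth
#' oracle on small instances.
#'
#' @param problem a [selection_problem()].
#' @param k_max optional cap on K.
#' @param n_guard refuse instances with more extreme points than this
#'   (default 20).
#' @return a `mage_selection`, or `NULL` when no feasible selection exists.
#' @export
solve_exact_bruteforce <- function(problem, k_max = Inf, n_guard = 20L) {
  n <- length(problem$extreme_values)
  if (n > n_guard) {
    stop("enumeration refused for N = ", n, " > ", n_guard,
         " extreme points; use solve_exact_dp()", call. = FALSE)
  }
  if (n < 2L) return(NULL)
  thr <- problem$threshold
  ge <- problem$comparator == "ge"
  best_idx <- NULL; best_k <- 0L; best_z <- -Inf
  for (idx in .all_subsets(n)) {
    if (length(idx) > k_max) next
    dn <- diff(idx)
    if (any(dn %% 2L == 0L)) next
    amps <- .step_amplitudes(idx, problem)
    ok <- if (ge) all(amps >= thr) else all(amps > thr)
    if (!ok) next
    z <- sum(amps)
    if (.better(length(idx), z, idx, best_k, best_z, best_idx)) {
      best_idx <- idx; best_k <- length(idx); best_z <- z
    }
  }
  if (is.null(best_idx)) NULL else new_mage_selection(best_idx, best_z)
}

#' Maximum total amplitude over all feasible selections
#'
#' Dynamic program maximizing Z alone (no priority on K). This is the
#' natural upper bound on the total amplitude any solver can return: because
#' a single point cannot be inserted into an odd index gap without breaking
#' alternation, the best selection at K - 1 points can exceed the best at K,
#' so the optimum under the (K, Z)-lexicographic ordering does not bound Z
#' across different K.
#'
#' @param problem a [selection_problem()].
#' @return largest Z over feasible selections (K >= 2), or 0 when none
#'   exists.
#' @export
max_total_amplitude <- function(problem) {
  n <- length(problem$extreme_values)
  if (n < 2L) return(0)
  vals <- problem$extreme_values
  sgn <- ifelse(problem$extreme_kinds == "min", 1, -1)
  thr <- problem$threshold
  ge <- problem$comparator == "ge"
  m <- rep(0, n)  # best suffix total starting at i (0 = stop here)
  for (i in seq.int(n - 1L, 1L)) {
    js <- seq.int(i + 1L, n)
    odd <- (js - i) %% 2L == 1L
    amp <- sgn[i] * (vals[js] - vals[i])
    ok <- odd & (if (ge) amp >= thr else amp > thr)
    if (any(ok)) m[i] <- max(amp[ok] + m[js[ok]])
  }
  max(m)
}

#' Exact solver by dynamic programming
#'
#' Polynomial-time oracle returning the same optimum as
#' [solve_exact_bruteforce()]: over selections starting at each extreme
#' point, a suffix recursion maximizes (K, Z) lexicographically; the
#' reconstruction picks the lexicographically smallest optimal index
#' vector. Runs in O(N^2).
#'
#' @inheritParams solve_exact_bruteforce
#' @return a `mage_selection`, or `NULL` when no feasible selection exists.
#' @export
solve_exact_dp <- function(problem) {
  n <- length(problem$extreme_values)
  if (n < 2L) return(NULL)
  vals <- problem$extreme_values
  sgn <- ifelse(problem$extreme_kinds == "min", 1, -1)
  thr <- problem$threshold
  ge <- problem$comparator == "ge"
  # bestK[i], bestZ[i]: best (K, Z) over feasible selections starting at i
  bestK <- rep(1L, n)
  bestZ <- rep(0, n)
  for (i in seq.int(n - 1L, 1L)) {
    js <- seq.int(i + 1L, n)
    odd <- (js - i) %% 2L == 1L
    amp <- sgn[i] * (vals[js] - vals[i])
    ok <- odd & (if (ge) amp >= thr else amp > thr)
    if (!any(ok)) next
    js <- js[ok]; amp <- amp[ok]
    ks <- bestK[js] + 1L
    zs <- bestZ[js] + amp
    kmax <- max(ks)
    cand <- which(ks == kmax)
    zbest <- max(zs[cand])
    if (kmax > bestK[i] || (kmax == bestK[i] && zbest > bestZ[i] + .Z_TOL)) {
      bestK[i] <- kmax
      bestZ[i] <- zbest
    }
  }
  kstar <- max(bestK)
  if (kstar < 2L) return(NULL)
  zstar <- max(bestZ[bestK == kstar])
  starts <- which(bestK == kstar & abs(bestZ - zstar) <= .Z_TOL)
  i <- min(starts)
  sel <- i
  while (bestK[i] > 1L) {
    js <- seq.int(i + 1L, n)
    odd <- (js - i) %% 2L == 1L
    amp <- sgn[i] * (vals[js] - vals[i])
    ok <- odd & (if (ge) amp >= thr else amp > thr) &
      bestK[js] == bestK[i] - 1L &
      abs(bestZ[js] + amp - bestZ[i]) <= .Z_TOL
    j <- js[ok][1L]
    sel <- c(sel, j)
    i <- j
  }
  new_mage_selection(sel, bestZ[min(starts)])
}
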