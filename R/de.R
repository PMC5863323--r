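# Integer differential evolution over candidate selections, with
# penalty-function constraint handling. The population for a given K holds
# NP sorted integer vectors over {1..N}; mutation adds a rounded scaled
# difference of two donors to a third, crossover mixes mutant and target
# coordinates (binomial, with one guaranteed mutant coordinate), and greedy
# selection keeps whichever of trial/target has the smaller penalized
# objective. K is swept and the best vector at the largest feasible K wins.

# nearest integer, halves away from zero
nint <- function(x) trunc(x + sign(x) * 0.5)

#' Differential-evolution configuration
#'
#' The defaults were calibrated against the exact dynamic-programming oracle
#' on random selection problems. Sorted integer vectors make the coordinates
#' strongly coupled, so a near-full crossover is destructive: a small `cr`
#' with `f = 1` (difference vectors applied unrounded) searches far more
#' reliably, and a large population with duplicate reinitialization counters
#' the stagnation that integer rounding induces.
#'
#' @param np population size (>= 4: mutation draws three donors distinct
#'   from the target). Default 200.
#' @param f scale factor for the difference vector, in \[0, 1\]. Default 1.
#' @param cr crossover rate in \[0, 1\]. Default 0.1.
#' @param generations number of generations per K (default 200).
#' @param mu,lam penalty weights for amplitude and parity violations;
#'   `NULL` (default) uses `1e6 * max(threshold, 1)^2`, large enough that
#'   any violation outweighs every attainable amplitude total, so the sign
#'   of the best Y separates feasible from infeasible K.
#' @param seed RNG seed for a reproducible search (`NULL`: use the current
#'   RNG state).
#' @param k_min,k_max sweep bounds for the selection size K (defaults 2 and
#'   N).
#' @param warm number of warm-start vectors injected into the initial
#'   population of each K: single-index extensions of the best feasible
#'   vector found at K - 1 (0 disables; the rest of the population is drawn
#'   uniformly as usual). Default 20.
#' @param reinit_duplicates redraw population members that duplicate an
#'   earlier member after each generation (the first copy, and hence the
#'   incumbent best, is kept). Default `TRUE`.
#' @param early_stop end the K sweep at the first infeasible K that follows
#'   a feasible one. True feasibility is downward-closed in K (dropping
#'   trailing points of a feasible selection keeps it feasible), so the
#'   shortcut only saves time; because the per-K search is stochastic, a
#'   miss at one K would also end the sweep early, so the default (`FALSE`)
#'   sweeps every K.
#' @return an object of class `de_config`.
#' @export
de_config <- function(np = 200L, f = 1.0, cr = 0.1, generations = 200L,
                      mu = NULL, lam = NULL, seed = NULL,
                      k_min = 2L, k_max = Inf, warm = 20L,
                      reinit_duplicates = TRUE, early_stop = FALSE) {
  stopifnot(np >= 4L, f >= 0, f <= 1, cr >= 0, cr <= 1,
            generations >= 1L, k_min >= 2L, k_max >= k_min, warm >= 0L)
  structure(list(np = as.integer(np), f = f, cr = cr,
                 generations = as.integer(generations),
                 mu = mu, lam = lam, seed = seed,
                 k_min = as.integer(k_min), k_max = k_max,
                 warm = as.integer(warm),
                 reinit_duplicates = isTRUE(reinit_duplicates),
                 early_stop = isTRUE(early_stop)),
            class = "de_config")
}

.penalty_weights <- function(config, threshold) {
  w <- 1e6 * max(threshold, 1)^2
  list(mu = if (is.null(config$mu)) w else config$mu,
       lam = if (is.null(config$lam)) w else config$lam)
}

#' Initialize a DE population
#'
#' Each of the `np` vectors has K entries `1 + NINT(rho * (N - 1))` with
#' `rho ~ U[0, 1]`, sorted ascending, covering the index range uniformly.
#'
#' @param n_extremes number of extreme points N.
#' @param k selection size K (2 <= K <= N).
#' @param config a [de_config()].
#' @return integer matrix `np x k`, rows sorted ascending.
#' @export
initialize_population <- function(n_extremes, k, config = de_config()) {
  if (n_extremes < k) {
    stop("K = ", k, " exceeds the number of extreme points N = ",
         n_extremes, call. = FALSE)
  }
  m <- matrix(1L + as.integer(nint(runif(config$np * k) * (n_extremes - 1))),
              nrow = config$np)
  m <- t(apply(m, 1L, sort))
  storage.mode(m) <- "integer"
  m
}

#' DE mutation
#'
#' Draws three mutually distinct donor rows (all different from the target
#' row `i`) and forms `V = N_r1 + NINT(F * (N_r2 - N_r3))`, with entries
#' clamped into `[1, N]`.
#'
#' @param population integer matrix from [initialize_population()].
#' @param i target row index.
#' @param config a [de_config()].
#' @param n_extremes number of extreme points N (clamp bound).
#' @return integer mutant vector of length K (not yet sorted).
#' @export
de_mutate <- function(population, i, config, n_extremes) {
  np <- nrow(population)
  stopifnot(np >= 4L)
  r <- sample(setdiff(seq_len(np), i), 3L)
  v <- population[r[1L], ] +
    nint(config$f * (population[r[2L], ] - population[r[3L], ]))
  as.integer(pmin(pmax(v, 1L), n_extremes))
}

#' DE crossover
#'
#' Binomial crossover: coordinate j of the trial comes from the mutant when
#' `rand <= CR` or `j == j_rand` (a uniformly chosen coordinate guaranteeing
#' at least one mutant entry), otherwise from the target. The trial is
#' re-sorted ascending.
#'
#' @param target,mutant integer vectors of equal length K.
#' @param config a [de_config()].
#' @return sorted integer trial vector.
#' @export
de_crossover <- function(target, mutant, config) {
  k <- length(target)
  stopifnot(length(mutant) == k)
  jrand <- sample.int(k, 1L)
  take <- runif(k) <= config$cr
  take[jrand] <- TRUE
  sort(as.integer(ifelse(take, mutant, target)))
}

#' DE greedy selection
#'
#' The trial replaces the target iff its penalized objective is strictly
#' smaller.
#'
#' @param target,trial integer candidate vectors.
#' @param problem a [selection_problem()].
#' @param config a [de_config()].
#' @return the surviving vector.
#' @export
de_select <- function(target, trial, problem, config = de_config()) {
  w <- .penalty_weights(config, problem$threshold)
  yt <- penalty_objective_y(trial, problem, w$mu, w$lam)
  y0 <- penalty_objective_y(target, problem, w$mu, w$lam)
  if (yt < y0) trial else target
}

#' Solve the selection problem by integer differential evolution
#'
#' For each K in the sweep range (ascending), runs `generations` DE
#' generations on the penalty-relaxed objective and records the best vector
#' and its Y. When the previous K yielded a feasible vector, `config$warm`
#' single-index extensions of it are injected into the next K's initial
#' population (selections at consecutive K typically share most of their
#' points; the remainder of the population is drawn uniformly, so the search
#' space stays covered). A K is feasible when its best Y is strictly
#' negative and the best vector passes [is_feasible()] (with finite penalty
#' weights a vector with a vanishing amplitude shortfall can have Y < 0
#' while violating the comparator; the explicit check keeps the returned
#' selection feasible). The best vector at the largest feasible K is
#' returned. Deterministic under `config$seed`.
#'
#' @param problem a [selection_problem()].
#' @param config a [de_config()].
#' @return a `mage_selection` (with a `per_k` data frame of the sweep:
#'   columns `k`, `best_y`, `feasible`), or `NULL` when no K is feasible;
#'   `NULL` carries no sweep record.
#' @export
solve_de <- function(problem, config = de_config()) {
  n <- length(problem$extreme_values)
  if (n < 2L) return(NULL)
  if (!is.null(config$seed)) set.seed(config$seed)
  w <- .penalty_weights(config, problem$threshold)
  ks <- seq.int(config$k_min, min(config$k_max, n))
  if (!length(ks)) return(NULL)
  per_k <- data.frame(k = ks, best_y = NA_real_, feasible = FALSE)
  best <- NULL
  prev <- NULL
  for (r in seq_along(ks)) {
    k <- ks[r]
    warm <- NULL
    if (config$warm > 0L && !is.null(prev) && length(prev) == k - 1L) {
      warm <- t(vapply(seq_len(config$warm),
                       function(i) sort(c(prev, sample.int(n, 1L))),
                       integer(k)))
    }
    res <- de_solve_k_cpp(problem$extreme_values, problem$threshold,
                          k, config$np, config$f, config$cr,
                          config$generations, w$mu, w$lam,
                          config$reinit_duplicates, warm,
                          problem$extreme_kinds[1L] == "min")
    per_k$best_y[r] <- res$y
    feas <- res$y < 0 && isTRUE(is_feasible(res$indices, problem))
    per_k$feasible[r] <- feas
    if (feas) {
      best <- res$indices  # ascending sweep: largest feasible K wins
      prev <- res$indices
    } else {
      if (config$early_stop && !is.null(best)) {
        per_k <- per_k[seq_len(r), , drop = FALSE]
        break
      }
      prev <- NULL
    }
  }
  if (is.null(best)) return(NULL)
  new_mage_selection(best, objective_z(best, problem), per_k = per_k)
}
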