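test_that("population initialization covers [1, N], sorted and reproducible", {
  cfg <- de_config(np = 30)
  set.seed(9)
  pop <- initialize_population(12, 4, cfg)
  expect_identical(dim(pop), c(30L, 4L))
  expect_true(all(pop >= 1L & pop <= 12L))
  expect_true(all(apply(pop, 1, function(r) !is.unsorted(r))))
  set.seed(9)
  expect_identical(initialize_population(12, 4, cfg), pop)
  # the closed form at the extremes of rho
  expect_identical(magecalc:::nint(0 * (12 - 1)) + 1, 1)
  expect_identical(magecalc:::nint(1 * (12 - 1)) + 1, 12)
  expect_error(initialize_population(3, 4, cfg), "exceeds")
})

test_that("mutation adds a rounded scaled difference, clamped into [1, N]", {
  cfg0 <- de_config(np = 10, f = 0)
  set.seed(2)
  pop <- initialize_population(15, 5, cfg0)
  # F = 0: the mutant is one of the donor rows (r1) verbatim
  set.seed(3)
  m <- de_mutate(pop, 1L, cfg0, 15)
  expect_true(any(apply(pop[-1L, , drop = FALSE], 1,
                        function(r) all(r == m))))

  # identical population rows: difference vector is zero for any F
  popc <- matrix(rep(c(2L, 5L, 9L), each = 8), nrow = 8, byrow = FALSE)
  cfg <- de_config(np = 8, f = 0.7)
  expect_identical(de_mutate(popc, 2L, cfg, 10), c(2L, 5L, 9L))

  # entries stay in range over random populations
  set.seed(11)
  for (i in 1:25) {
    pop <- initialize_population(8, 3, de_config(np = 12, f = 1))
    v <- de_mutate(pop, sample(12, 1), de_config(np = 12, f = 1), 8)
    expect_true(all(v >= 1L & v <= 8L))
  }
})

test_that("crossover mixes mutant and target and returns a sorted trial", {
  target <- c(1L, 4L, 7L)
  mutant <- c(2L, 3L, 9L)
  set.seed(4)
  # CR = 1: the trial is the sorted mutant
  expect_identical(de_crossover(target, mutant, de_config(cr = 1)),
                   sort(mutant))
  # CR = 0: exactly one coordinate (j_rand) comes from the mutant
  for (i in 1:20) {
    tr <- de_crossover(target, mutant, de_config(cr = 0))
    expect_false(is.unsorted(tr))
    # multiset difference from the target is at most one element
    extra <- setdiff(tr, target)
    expect_lte(length(extra), 1L)
    if (length(extra)) expect_true(extra %in% mutant)
  }
})

test_that("greedy selection keeps the penalized-objective winner", {
  prob <- zigzag_problem()
  cfg <- de_config()
  # feasible full selection beats a parity-violating one
  expect_identical(de_select(c(1L, 3L), 1:5, prob, cfg), 1:5)
  # equal Y retains the target
  expect_identical(de_select(1:2, 1:2, prob, cfg), 1:2)
  # a worse trial is rejected: {1,2} has Z 3 < {4,5} Z 4
  expect_identical(de_select(c(4L, 5L), c(1L, 2L), prob, cfg), c(4L, 5L))
})

test_that("best penalized objective never worsens across generations", {
  # small all-R DE loop built from the exported operators
  prob <- generate_random_problem(8, 0.4, seed = 21)
  cfg <- de_config(np = 12, generations = 30)
  n <- length(prob$extreme_values)
  set.seed(22)
  pop <- initialize_population(n, 3, cfg)
  w <- magecalc:::.penalty_weights(cfg, prob$threshold)
  y_of <- function(v) penalty_objective_y(v, prob, w$mu, w$lam)
  best_trace <- numeric(cfg$generations)
  for (g in seq_len(cfg$generations)) {
    for (i in seq_len(cfg$np)) {
      mut <- de_mutate(pop, i, cfg, n)
      trial <- de_crossover(pop[i, ], mut, cfg)
      pop[i, ] <- de_select(pop[i, ], trial, prob, cfg)
    }
    best_trace[g] <- min(apply(pop, 1, y_of))
  }
  expect_true(all(diff(best_trace) <= 0))
})

test_that("DE matches the exact optimum on the canonical instance", {
  prob <- zigzag_problem()
  sel <- solve_de(prob, de_config(seed = 42))
  expect_identical(sel$k, 5L)
  expect_equal(sel$z, 16)
  expect_s3_class(sel$per_k, "data.frame")
  expect_true(all(sel$per_k$feasible[sel$per_k$k <= 5]))
})

test_that("DE output is always feasible and deterministic under a seed", {
  set.seed(83)
  for (i in 1:10) {
    prob <- generate_random_problem(sample(4:15, 1), runif(1))
    sel <- solve_de(prob, de_config(np = 40, seed = 1000 + i))
    if (!is.null(sel)) expect_true(is_feasible(sel$indices, prob))
  }
  prob <- generate_random_problem(12, 0.5, seed = 7)
  a <- solve_de(prob, de_config(seed = 99))
  b <- solve_de(prob, de_config(seed = 99))
  expect_identical(a$indices, b$indices)

  # early stop ends the sweep at the first infeasible K after a feasible
  # one and returns the same optimum here
  e <- solve_de(prob, de_config(seed = 99, early_stop = TRUE))
  expect_identical(e$indices, a$indices)
  expect_lte(nrow(e$per_k), nrow(a$per_k))
})

test_that("DE handles degenerate problems", {
  expect_null(solve_de(generate_random_problem(0), de_config(seed = 1)))
  expect_null(solve_de(generate_random_problem(1), de_config(seed = 1)))
  # flat trace: no extreme points at all
  flat <- find_extreme_points(make_trace(c(5, 5, 5)))
  expect_identical(flat$n, 0L)
  # threshold above all amplitudes: every K infeasible
  expect_null(solve_de(zigzag_problem(threshold = 6), de_config(seed = 2)))
})

test_that("DE recovers a planted staircase of six strong excursions", {
  pt <- generate_alternating_trace(rep(3, 6), baseline = 6,
                                   samples_per_leg = 4)
  r <- calculate_mage(pt$trace, solver = "de", config = de_config(seed = 5))
  expect_equal(r$selected_values, pt$truth$vertex_values)
  expect_equal(r$mage, pt$truth$mage)
})
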