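test_that("total amplitude Z sums adjacent absolute differences", {
  prob <- zigzag_problem()
  expect_equal(objective_z(1:5, prob), 16)
  expect_equal(objective_z(1:2, prob), 3)
  p0 <- selection_problem(c(4, 4), c("min", "max"), threshold = 0)
  expect_equal(objective_z(1:2, p0), 0)
  expect_error(objective_z(c(1L, 9L), prob), "out of range")
})

test_that("feasibility checks threshold and parity with a violation report", {
  prob <- zigzag_problem()
  expect_true(is_feasible(1:5, prob))

  # skipping to the same kind (even gap) is a parity violation (and the
  # signed directional amplitude of the step also falls short)
  f1 <- is_feasible(c(1L, 3L), prob)
  expect_false(f1)
  expect_true("parity" %in% attr(f1, "violations")$type)
  expect_identical(unique(attr(f1, "violations")$k), 1L)

  # amplitude below threshold
  f2 <- is_feasible(c(1L, 2L), zigzag_problem(threshold = 3.5))
  expect_false(f2)
  expect_identical(attr(f2, "violations")$type, "amplitude")

  # comparator: amp == threshold feasible under ge, not under gt
  expect_true(is_feasible(c(1L, 2L), zigzag_problem(threshold = 3)))
  expect_false(is_feasible(c(1L, 2L),
                           zigzag_problem(threshold = 3, comparator = "gt")))
})

test_that("penalty objective equals -Z exactly iff the selection is feasible", {
  prob <- zigzag_problem()
  mu <- 1e6; lam <- 1e6
  expect_identical(penalty_objective_y(1:5, prob, mu, lam),
                   -objective_z(1:5, prob))

  # even gap contributes lam * 4 (h = 2); the signed directional step from
  # the nadir at 5 to the nadir at 4 is d = -1 (it should rise)
  y <- penalty_objective_y(c(1L, 3L), prob, mu, lam)
  d <- 4 - 5
  expect_equal(y, -d + mu * (2.168 - d)^2 + lam * 4)

  # amplitude shortfall d contributes mu * d^2
  p <- zigzag_problem(threshold = 3.5)
  d <- 3.5 - 3
  expect_equal(penalty_objective_y(c(1L, 2L), p, mu, lam), -3 + mu * d^2)

  # property: sign of (Y + Z) discriminates feasibility
  set.seed(5)
  for (i in 1:200) {
    pr <- generate_random_problem(sample(2:12, 1), runif(1))
    n <- length(pr$extreme_values)
    k <- sample.int(n - 1L, 1L) + 1L  # 2..n even when n == 2
    sel <- sort(sample.int(n, k))
    y <- penalty_objective_y(sel, pr, mu, lam)
    z <- objective_z(sel, pr)
    if (isTRUE(is_feasible(sel, pr))) expect_identical(y, -z)
    else expect_gt(y, -z)
  }
})

test_that("brute force finds the documented optima", {
  expect_same_optimum(solve_exact_bruteforce(zigzag_problem()),
                      new_sel <- list(k = 5L, z = 16))
  sel <- solve_exact_bruteforce(zigzag_problem())
  expect_equal(sel$indices, 1:5)

  # threshold above every amplitude: no selection
  expect_null(solve_exact_bruteforce(zigzag_problem(threshold = 6)))

  # two alternating points with a qualifying amplitude
  p2 <- selection_problem(c(4, 7), c("min", "max"), threshold = 2)
  expect_equal(solve_exact_bruteforce(p2)$indices, 1:2)

  # the guard refuses exponentially large instances
  big <- generate_random_problem(25, seed = 1)
  expect_error(solve_exact_bruteforce(big), "refused")
})

test_that("dynamic program agrees with brute force on random instances", {
  set.seed(23)
  for (i in 1:60) {
    prob <- generate_random_problem(sample(0:12, 1), runif(1))
    expect_same_optimum(solve_exact_dp(prob), solve_exact_bruteforce(prob))
  }
  expect_null(solve_exact_dp(generate_random_problem(0)))
})

test_that("when every amplitude qualifies the optimum selects all N points", {
  set.seed(31)
  for (i in 1:20) {
    prob <- generate_random_problem(sample(3:12, 1), threshold_quantile = 0)
    n <- length(prob$extreme_values)
    sel <- solve_exact_dp(prob)
    expect_identical(sel$k, n)
    expect_equal(sel$z, sum(abs(diff(prob$extreme_values))))
  }
})

test_that("DP optima are feasible and K-feasibility is downward closed", {
  set.seed(47)
  for (i in 1:30) {
    prob <- generate_random_problem(sample(2:12, 1), runif(1))
    sel <- solve_exact_dp(prob)
    if (is.null(sel)) next
    expect_true(is_feasible(sel$indices, prob))
    # any prefix of a feasible selection (length >= 2) stays feasible,
    # so every K' <= K* admits a feasible selection
    for (kp in 2:sel$k) {
      expect_true(is_feasible(sel$indices[seq_len(kp)], prob))
    }
  }
})

test_that("the best K-1 selection can beat the best K selection in Z", {
  # parity forbids inserting one point into an odd gap, so restricting to a
  # larger K can lose total amplitude; the fixed-K optima are therefore not
  # monotone in K, and the selector must prioritize K over Z explicitly.
  prob <- selection_problem(c(0.1, 10, 9.9, 1009.9),
                            c("min", "max", "min", "max"), threshold = 0)
  # pairs: {1,4} (gap 3) has Z = 1009.8; triples: {2,3,4} has Z = 1000.1
  # ({1,2,4} and {1,3,4} contain even gaps and are infeasible)
  best_k2 <- solve_exact_bruteforce(prob, k_max = 2)
  best_k3 <- solve_exact_bruteforce(prob, k_max = 3)
  expect_identical(best_k2$k, 2L)
  expect_equal(best_k2$z, 1009.8)
  expect_identical(best_k3$k, 3L)
  expect_equal(best_k3$z, 1000.1)
  expect_gt(best_k2$z, best_k3$z)
  # the (K, Z)-lexicographic selector still prefers K = 4 here
  expect_identical(solve_exact_dp(prob)$k, 4L)
})

test_that("max_total_amplitude bounds every feasible selection's Z", {
  set.seed(59)
  for (i in 1:30) {
    prob <- generate_random_problem(sample(2:10, 1), runif(1))
    zmax <- max_total_amplitude(prob)
    n <- length(prob$extreme_values)
    # enumerate all feasible selections and check the bound is tight
    best <- 0
    for (mask in seq_len(2^n - 1)) {
      idx <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) != 0L)
      if (length(idx) < 2) next
      if (isTRUE(is_feasible(idx, prob))) {
        best <- max(best, objective_z(idx, prob))
      }
    }
    expect_equal(zmax, best)
  }
})
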