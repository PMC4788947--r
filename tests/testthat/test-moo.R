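test_that("dominance relation on elementary pairs", {
  expect_true(dominates(c(1, 1), c(2, 2)))
  expect_false(dominates(c(1, 2), c(2, 1)))
  expect_false(dominates(c(1, 1), c(1, 1)))
  expect_true(dominates(c(1, 2), c(1, 3)))
})

test_that("dominance filter is idempotent and correct on random sets", {
  set.seed(1)
  for (rep in 1:5) {
    J <- matrix(runif(60), ncol = 2)
    keep <- pareto_filter(J)
    # no survivor dominated by any point
    for (i in keep)
      expect_false(any(vapply(seq_len(nrow(J)), function(j)
        j != i && dominates(J[j, ], J[i, ]), logical(1))))
    # idempotent
    expect_equal(pareto_filter(J[keep, , drop = FALSE]),
                 seq_along(keep))
  }
})

test_that("spherical pruning keeps the smaller-norm point per sector", {
  # two points in the same angular sector: the closer to ideal survives
  J <- rbind(c(0.5, 0.5), c(0.9, 0.9), c(0.1, 1), c(1, 0.1))
  kept <- spherical_prune(J, sectors = 4)
  expect_true(1 %in% kept)
  expect_false(2 %in% kept)
  # points in distinct sectors all survive
  J2 <- rbind(c(0, 1), c(0.3, 0.65), c(0.7, 0.3), c(1, 0))
  expect_equal(spherical_prune(J2, sectors = 8), 1:4)
  expect_length(spherical_prune(J[0, , drop = FALSE], 10), 0)
})

test_that("pruned archives stay mutually non-dominated", {
  set.seed(7)
  for (rep in 1:5) {
    J <- matrix(runif(80, 0, 10), ncol = 2)
    nd <- J[pareto_filter(J), , drop = FALSE]
    kept <- nd[spherical_prune(nd, sectors = 12), , drop = FALSE]
    expect_setequal(pareto_filter(kept), seq_len(nrow(kept)))
  }
})

test_that("engine converges on the analytic benchmark", {
  prob <- make_fixture(fixture_spec("benchmark"))
  pa <- spmode(prob, mood_config(max_evals = 2000, seed = 3))
  f1 <- seq(0, 4, length.out = 2000)
  ref <- cbind(f1, prob$front(f1))
  expect_gt(nrow(pa$J), 20)
  expect_lt(generational_distance(pa$J, ref), 0.05)
  # front endpoints bracket the trade-off
  expect_lt(min(pa$J[, 1]), 0.05)
  expect_lt(min(pa$J[, 2]), 0.05)
})

test_that("runs are deterministic given the seed", {
  prob <- benchmark_problem()
  a <- spmode(prob, mood_config(max_evals = 600, seed = 11))
  b <- spmode(prob, mood_config(max_evals = 600, seed = 11))
  expect_identical(a$J, b$J)
  expect_identical(a$theta, b$theta)
  c <- spmode(prob, mood_config(max_evals = 600, seed = 12))
  expect_false(identical(a$J, c$J))
})

test_that("archive hypervolume grows, up to small pruning-induced dips", {
  prob <- benchmark_problem()   # carries a fixed hv reference point
  pa <- spmode(prob, mood_config(max_evals = 2000, seed = 4))
  hv <- pa$hv_history
  # elitist pooling can only add dominated area; spherical pruning may
  # trade a sector occupant for a slightly smaller-volume one
  expect_gt(tail(hv, 1), hv[1])
  expect_true(all(diff(hv) >= -0.02 * max(hv)))
  expect_gte(tail(hv, 1), 0.98 * max(hv))
})

test_that("the archive is mutually non-dominated and admissible", {
  pa <- cached_small_pareto()
  expect_gt(nrow(pa$J), 1)
  expect_setequal(pareto_filter(pa$J), seq_len(nrow(pa$J)))
  box <- pertinency_box()
  expect_true(all(pa$J[, 1] > box$J1[1] & pa$J[, 1] < box$J1[2]))
  expect_true(all(pa$J[, 2] > box$J2[1] & pa$J[, 2] < box$J2[2]))
  expect_true(all(pa$P > box$P[1] & pa$P < box$P[2]))
  # decision vectors respect their bounds
  b <- decision_bounds()
  for (j in seq_len(nrow(b)))
    expect_true(all(pa$theta[, j] >= b$lower[j] &
                      pa$theta[, j] <= b$upper[j]))
})

test_that("brute force front: idempotent filter, benchmark convergence", {
  prob <- benchmark_problem()
  bf <- brute_force_front(prob, "random", N = 3000, seed = 2)
  # applying the dominance filter again changes nothing
  expect_setequal(pareto_filter(bf$J), seq_len(nrow(bf$J)))
  f1 <- seq(0, 4, length.out = 2000)
  expect_lt(generational_distance(bf$J, cbind(f1, prob$front(f1))), 0.05)
  bg <- brute_force_front(prob, "grid", N = 500)
  expect_lt(generational_distance(bg$J, cbind(f1, prob$front(f1))), 0.05)
})

test_that("hypervolume of a known front", {
  J <- rbind(c(1, 3), c(2, 2), c(3, 1))
  # ref (4,4): rectangles 3*1 + 2*1 + 1*1 = 6
  expect_equal(hypervolume_2d(J, c(4, 4)), 6)
  expect_equal(hypervolume_2d(J[0, , drop = FALSE], c(4, 4)), 0)
  # dominated points do not add volume
  expect_equal(hypervolume_2d(rbind(J, c(3, 3)), c(4, 4)), 6)
})

test_that("infeasible-only problems return an empty archive", {
  prob <- list(lower = 0, upper = 1,
               eval = function(theta)
                 list(J = c(theta, 1 - theta), P = 0, violation = 1,
                      pertinent = FALSE, feasible = FALSE))
  pa <- spmode(prob, mood_config(np = 10, max_evals = 200, seed = 1))
  expect_equal(nrow(pa$J), 0)
  expect_error(spmode(prob, mood_config(np = 10, max_evals = 15,
                                        seed = 1)),
               "budget")
})
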