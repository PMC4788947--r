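pulse_traj <- function(h = 100, delta = 50, residual = 0) {
  make_fixture(fixture_spec("pulse", size = 41,
                            effect = list(h = h, delta = delta,
                                          residual = residual)))
}

test_that("total variation of elementary paths", {
  ramp <- data.frame(time = 0:10, x8 = seq(2, 7, length.out = 11))
  expect_equal(total_variation(ramp, "x8"), 5)
  const <- data.frame(time = 0:10, x8 = rep(3, 11))
  expect_equal(total_variation(const, "x8"), 0)
  pulse <- data.frame(time = 0:10, x8 = c(0:5, 4:0))
  expect_equal(total_variation(pulse, "x8"), 10)  # up h then down h = 2h
  expect_error(total_variation(ramp, "x5"), "species")
})

test_that("quadrature accumulator takes precedence over differences", {
  tr <- simulate_circuit(reference_theta(),
                         control = solver_control(n_out = 11))
  # coarse sampling underestimates the discrete variation; the quadrature
  # value must not depend on the output grid
  tr2 <- simulate_circuit(reference_theta(),
                          control = solver_control(n_out = 201))
  expect_equal(attr(tr, "tv_x8"), attr(tr2, "tv_x8"), tolerance = 1e-6)
  expect_gt(attr(tr, "tv_x8"), sum(abs(diff(tr$x8))) - 1e-9)
})

test_that("analytic pulses give J1 = delta/h and J2 = residual/delta", {
  ob <- evaluate_objectives(pulse_traj(h = 100, delta = 50))
  expect_equal(ob$J1, 50 / 100)
  expect_equal(ob$J2, 0)   # exact adaptation
  ob2 <- evaluate_objectives(pulse_traj(h = 80, delta = 40, residual = 8))
  expect_equal(ob2$J2, 8 / 40)
  expect_equal(ob2$J1, 2 * 40 / (80 + 72))  # TV = up 80 + down 72
})

test_that("doubling the peak halves J1 (scale check)", {
  j1a <- evaluate_objectives(pulse_traj(h = 60, delta = 30))$J1
  j1b <- evaluate_objectives(pulse_traj(h = 120, delta = 30))$J1
  expect_equal(j1a, 2 * j1b)
})

test_that("J2 is positive exactly when the output ends above baseline", {
  up <- evaluate_objectives(pulse_traj(residual = 5))
  flat <- evaluate_objectives(pulse_traj(residual = 0))
  expect_gt(up$J2, 0)
  expect_equal(flat$J2, 0)
})

test_that("degenerate trajectories hit the guards", {
  # flat output: J1 sentinel and not pertinent
  tr <- pulse_traj(h = 0, delta = 50)
  ob <- evaluate_objectives(tr)
  expect_identical(ob$J1, Inf)
  expect_false(ob$pertinent)
  # no stimulus: error
  tr0 <- pulse_traj(h = 10, delta = 0)
  expect_error(evaluate_objectives(tr0), "no stimulus")
})

test_that("evaluation is deterministic on identical trajectories", {
  tr <- simulate_circuit(reference_theta())
  a <- evaluate_objectives(tr)
  b <- evaluate_objectives(tr)
  expect_identical(a, b)
})

test_that("admissibility follows the pertinency box", {
  box <- pertinency_box()
  ok <- list(J1 = 100, J2 = 1, P = 10)
  expect_equal(is_admissible(ok, box),
               c(pertinent = TRUE, feasible = TRUE))
  expect_false(is_admissible(list(J1 = 250, J2 = 1, P = 10),
                             box)[["pertinent"]])
  expect_false(is_admissible(list(J1 = 100, J2 = 1, P = 0.5),
                             box)[["feasible"]])
  expect_error(pertinency_box(J1 = c(2, 1)), "range")
})
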