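test_that("monomer concentration solves its quadratic (polyroot oracle)", {
  p <- circuit_parameters()
  # independent root: 2*k3*M^2 + (dAI + k_2)*M - k2*x2*x3 = 0
  roots <- polyroot(c(-p$k2 * 10 * 10, p$dAI + p$k_2, 2 * p$k3))
  oracle <- max(Re(roots[abs(Im(roots)) < 1e-9]))
  expect_equal(monomer_concentration(10, 10, 0, p), oracle,
               tolerance = 1e-12)
  expect_equal(monomer_concentration(0, 5, 0, p), 0)
  expect_equal(monomer_concentration(5, 0, 0, p), 0)
  expect_error(monomer_concentration(-1, 1, 0, p), "non-negative")
})

test_that("monomer root residual is below 1e-9 on random states", {
  p <- circuit_parameters()
  st <- random_states(10000, seed = 42)
  M <- monomer_concentration(st[, 1], st[, 2], st[, 3], p)
  resid <- abs(2 * p$k3 * M^2 + (p$dAI + p$k_2) * M -
                 (p$k2 * st[, 1] * st[, 2] + 2 * p$k_3 * st[, 3]))
  expect_true(all(M >= 0))
  expect_lt(max(resid), 1e-9)
})

test_that("rhs reproduces the structural identities of the model", {
  p <- expand_decision(reference_theta())
  # all-zero state: only the constitutive gA transcription fires
  d0 <- circuit_rhs(numeric(9), p)
  expect_equal(unname(d0["x1"]), p$kmA_CgA)
  expect_equal(unname(d0[paste0("x", 3:9)]), rep(0, 7))
  # load binding conserves the load pool exactly
  ld <- load_parameters()
  dl <- circuit_rhs(c(runif(9, 0, 100), 500, 300), p, load = ld)
  expect_identical(unname(dl["x10"] + dl["x11"]), 0)
  expect_error(circuit_rhs(c(NaN, numeric(8)), p), "finite")
  expect_error(circuit_rhs(numeric(5), p), "length")
})

test_that("compiled rhs and R reference rhs integrate to the same path", {
  th <- reference_theta()
  ctl_c <- solver_control(n_out = 41)
  ctl_r <- solver_control(n_out = 41, compiled = FALSE)
  tr_c <- simulate_circuit(th, control = ctl_c)
  tr_r <- simulate_circuit(th, control = ctl_r)
  for (v in c("x4", "x6", "x8", "x9"))
    expect_equal(tr_c[[v]], tr_r[[v]], tolerance = 1e-6)
  expect_equal(attr(tr_c, "tv_x8"), attr(tr_r, "tv_x8"),
               tolerance = 1e-6)
})

test_that("pre-equilibration reaches the analytic zero-inducer fixed point", {
  p <- expand_decision(reference_theta())
  eq <- pre_equilibrate(p)
  expect_equal(unname(eq["x1"]), p$kmA_CgA / p$dmA, tolerance = 1e-6)
  expect_equal(unname(eq["x2"]), p$kpA * p$kmA_CgA / p$dmA / p$dA,
               tolerance = 1e-6)
  expect_lt(max(abs(eq[3:9])), 1e-8)
  # residual postcondition
  expect_lt(max(abs(circuit_rhs(eq, p, hold_x9 = TRUE))), 1e-8)
  expect_lt(attr(eq, "residual"), 1e-8)
})

test_that("loaded equilibrium keeps the load pool at (LT, 0)", {
  p <- expand_decision(reference_theta())
  ld <- load_parameters(LT = 800)
  eq <- pre_equilibrate(p, load = ld)
  expect_equal(unname(eq["x10"]), 800)
  expect_equal(unname(eq["x11"]), 0)
  expect_lt(max(abs(circuit_rhs(eq, p, load = ld, hold_x9 = TRUE))), 1e-8)
})
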