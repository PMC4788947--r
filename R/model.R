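#' Quasi-steady-state monomer concentration
#'
#' The A-inducer monomer is assumed at quasi-steady state with respect to
#' the slower circuit dynamics, giving the quadratic
#' `2*k3*M^2 + (dAI + k_2)*M - (k2*x2*x3 + 2*k_3*x4) = 0`;
#' the non-negative root is returned.
#'
#' @param x2 free protein A (nM).
#' @param x3 intracellular inducer (nM).
#' @param x4 dimer (A.I)2 (nM).
#' @param params [circuit_parameters()].
#' @return Monomer concentration M (nM), vectorized over the states.
#' @export
#' @examples
#' monomer_concentration(10, 10, 0)
monomer_concentration <- function(x2, x3, x4, params = circuit_parameters()) {
  if (any(x2 < 0) || any(x3 < 0) || any(x4 < 0))
    stop("monomer_concentration(): states must be non-negative",
         call. = FALSE)
  a <- params$dAI + params$k_2
  s <- params$k2 * x2 * x3 + 2 * params$k_3 * x4
  (-a + sqrt(a^2 + 8 * params$k3 * s)) / (4 * params$k3)
}

#' Time derivatives of the reduced I1-FFL model
#'
#' Reference (pure R) implementation of the model right-hand side.  The
#' integrator itself uses an equivalent compiled version; this function is
#' the readable ground truth, used for equilibration checks, Newton
#' polishing and cross-validation of the compiled code.
#'
#' States (all nM): `x1` mRNA-gA, `x2` protein A, `x3` intracellular
#' inducer, `x4` dimer (A.I)2, `x5` mRNA-gB, `x6` protein B, `x7` mRNA-gC,
#' `x8` protein C, `x9` extracellular inducer; with a load, `x10` free load
#' and `x11` C-load complex are appended.
#'
#' @param state numeric vector of length 9, or 11 when `load` is given.
#' @param params [circuit_parameters()].
#' @param load optional [load_parameters()]; when present the binding flux
#'   `-K1*x8*x10 + K2*x11` is added to the `x8` equation and the load
#'   equations are appended.
#' @param hold_x9 freeze the extracellular inducer (used during
#'   pre-equilibration).
#' @return Named vector of time derivatives (nM/min).
#' @export
circuit_rhs <- function(state, params = circuit_parameters(), load = NULL,
                        hold_x9 = FALSE) {
  n_exp <- if (is.null(load)) 9L else 11L
  if (length(state) != n_exp)
    stop("circuit_rhs(): state must have length ", n_exp, call. = FALSE)
  if (any(!is.finite(state)))
    stop("circuit_rhs(): non-finite state", call. = FALSE)
  p <- params
  x <- unname(state)
  M <- monomer_concentration(max(x[2], 0), max(x[3], 0), max(x[4], 0), p)
  hillB <- x[4] / (p$gamma1 + x[4])
  numC <- x[4] + p$beta1 * p$gamma4 * x[6] + p$beta2 * p$gamma5 * x[4] * x[6]
  denC <- p$gamma2 + p$gamma3 * x[4] + p$gamma4 * x[6] +
    p$gamma5 * x[4] * x[6]
  kc <- compute_kcells(p$Vcell, p$Ncells, p$Vmedium)
  bind <- if (is.null(load)) 0 else -load$K1 * x[8] * x[10] + load$K2 * x[11]
  d <- c(
    x1 = p$kmA_CgA - p$dmA * x[1],
    x2 = p$kpA * x[1] - p$dA * x[2] - p$k2 * x[2] * x[3] + p$k_2 * M,
    x3 = -p$k2 * x[2] * x[3] + p$k_2 * M + p$kd * (x[9] - x[3]) -
      p$dI * x[3],
    x4 = p$k3 * M^2 - p$k_3 * x[4] - p$dAI2 * x[4],
    x5 = p$kmB_CgB * hillB - p$dmB * x[5],
    x6 = p$kpB * x[5] - p$dB * x[6],
    x7 = p$kmC_CgC * numC / denC - p$dmC * x[7],
    x8 = p$kpC * x[7] - p$dC * x[8] + bind,
    x9 = if (hold_x9) 0 else kc * p$kd * (x[3] - x[9]) - p$dIe * x[9]
  )
  if (!is.null(load)) d <- c(d, x10 = bind, x11 = -bind)
  d
}

#' Stimulus protocol for the adaptation experiment
#'
#' The circuit is first equilibrated with no inducer, then a step of
#' extracellular inducer is applied at `t0` and the response recorded until
#' `tf`.  The extracellular inducer decays (rate `dIe`), so `tf` should be
#' chosen such that an informative fraction of the step survives at the end
#' of the experiment while leaving the transient pulse ample time to
#' complete.  The default 100 min is about 2.4 inducer half-lives: roughly
#' 19% of the step survives at tf, so the precision index measures genuine
#' feed-forward adaptation rather than stimulus withdrawal.
#'
#' @param Ie_step step amplitude of extracellular inducer (nM, default
#'   1000).
#' @param t0 stimulus time (min; fixed at 0, the end of equilibration).
#' @param tf experiment length (min, default 100).
#' @param t_eq equilibration horizon (min, default 5000).
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(Ie_step = 1000, t0 = 0, tf = 100,
                              t_eq = 5000) {
  if (!is.finite(Ie_step) || Ie_step < 0)
    stop("stimulus_protocol(): Ie_step must be >= 0", call. = FALSE)
  if (!is.finite(tf) || tf <= t0)
    stop("stimulus_protocol(): need t0 < tf", call. = FALSE)
  if (!is.finite(t_eq) || t_eq <= 0)
    stop("stimulus_protocol(): equilibration horizon must be positive",
         call. = FALSE)
  structure(list(Ie_step = Ie_step, t0 = t0, tf = tf, t_eq = t_eq),
            class = "stimulus_protocol")
}

#' Integrator and tolerance settings
#'
#' @param rtol relative tolerance of the stiff integrator (default 1e-8).
#' @param atol absolute tolerance (nM, default 1e-10).
#' @param eq_tol maximum rhs residual accepted after pre-equilibration
#'   (nM/min, default 1e-8).
#' @param neg_tol concentrations in `(-neg_tol, 0)` are clipped to zero;
#'   anything more negative is a solver error (nM, default 1e-6).
#' @param n_out number of output samples of the trajectory (default 201).
#' @param maxsteps maximum internal integrator steps per call.
#' @param compiled use the compiled right-hand side (default `TRUE`); the R
#'   reference rhs is used when `FALSE`.
#' @return A list of class `solver_control`.
#' @export
solver_control <- function(rtol = 1e-8, atol = 1e-10, eq_tol = 1e-8,
                           neg_tol = 1e-6, n_out = 201, maxsteps = 50000,
                           compiled = TRUE) {
  structure(list(rtol = rtol, atol = atol, eq_tol = eq_tol,
                 neg_tol = neg_tol, n_out = as.integer(n_out),
                 maxsteps = as.integer(maxsteps), compiled = isTRUE(compiled)),
            class = "solver_control")
}

# deSolve-compatible R rhs with the two total-variation quadrature states
# appended (and the load states when `load` is given).
.rhs_desolve <- function(t, y, parms) {
  load <- parms$load
  n <- if (is.null(load)) 9L else 11L
  d <- circuit_rhs(y[seq_len(n)], parms$params, load = load,
                   hold_x9 = parms$hold_x9)
  list(c(d, abs(d[8]), abs(d[6])))
}

.integrate <- function(y0, times, params, load = NULL, hold_x9 = FALSE,
                       control = solver_control()) {
  if (control$compiled) {
    func <- if (is.null(load)) "derivs" else "derivs_load"
    out <- deSolve::lsoda(y = y0, times = times, func = func,
                          parms = .i1ffl_parms(params, load, hold_x9),
                          dllname = "moodtune", initfunc = "initmod",
                          rtol = control$rtol, atol = control$atol,
                          maxsteps = control$maxsteps)
  } else {
    out <- deSolve::lsoda(y = y0, times = times, func = .rhs_desolve,
                          parms = list(params = params, load = load,
                                       hold_x9 = hold_x9),
                          rtol = control$rtol, atol = control$atol,
                          maxsteps = control$maxsteps)
  }
  di <- attr(out, "istate")
  if (nrow(out) < length(times))
    stop("integration failed (solver stopped early, istate = ", di[1], ")",
         call. = FALSE)
  out
}

# Clip tiny negative concentrations; larger negativity is a solver error.
.clip_negative <- function(m, neg_tol) {
  vals <- m[, -1, drop = FALSE]
  if (any(vals < -neg_tol))
    stop("integration produced concentrations below -", neg_tol,
         " nM; tighten tolerances", call. = FALSE)
  vals[vals < 0] <- 0
  m[, -1] <- vals
  m
}

# Newton polish of a steady state using the R reference rhs with a
# finite-difference Jacobian; brings the residual down to rounding level
# even for states of order 1e6 nM.  The extracellular inducer is held at
# zero; its held equation is identically 0, so it is excluded from the
# solve to keep the Jacobian non-singular.
.newton_polish <- function(y, params, iters = 8L) {
  f <- function(s8) {
    d <- circuit_rhs(c(s8, 0), params, hold_x9 = TRUE)
    unname(d[1:8])
  }
  y8 <- y[1:8]
  for (it in seq_len(iters)) {
    f0 <- f(y8)
    if (max(abs(f0)) < 1e-12) break
    J <- matrix(0, 8, 8)
    for (j in 1:8) {
      h <- max(1e-8, 1e-8 * abs(y8[j]))
      yp <- y8; yp[j] <- yp[j] + h
      J[, j] <- (f(yp) - f0) / h
    }
    step <- tryCatch(solve(J, -f0), error = function(e) NULL)
    if (is.null(step)) break
    y_new <- y8 + step
    y_new[y_new < 0 & y_new > -1e-6] <- 0
    if (any(!is.finite(y_new))) break
    y8 <- y_new
  }
  c(y8, 0)
}

#' Pre-equilibrate the circuit without inducer
#'
#' Integrates the model from the empty state with the extracellular inducer
#' held at zero over the equilibration horizon, then polishes the endpoint
#' with a damped Newton step so the steady-state residual is at rounding
#' level.  With zero inducer the fixed point has `x1 = kmA_CgA/dmA`,
#' `x2 = kpA*x1/dA` and all other circuit species at zero.
#'
#' @param params [circuit_parameters()].
#' @param protocol [stimulus_protocol()] (supplies the horizon).
#' @param load optional [load_parameters()]; the load pool is equilibrated
#'   jointly (at zero output the loaded fixed point has `x10 = LT`,
#'   `x11 = 0`).
#' @param control [solver_control()].
#' @return Named steady-state vector (length 9, or 11 with load) with
#'   attribute `residual`, the max-norm of the rhs at the returned state.
#' @export
pre_equilibrate <- function(params = circuit_parameters(),
                            protocol = stimulus_protocol(), load = NULL,
                            control = solver_control()) {
  nm <- paste0("x", 1:9)
  y0 <- setNames(numeric(11), c(nm, "q8", "q6"))  # quadratures unused here
  out <- .integrate(y0, c(0, protocol$t_eq / 2, protocol$t_eq),
                    params, load = NULL, hold_x9 = TRUE,
                    control = control)
  y <- out[nrow(out), 1 + seq_len(9)]
  y[y < 0] <- 0
  y <- .newton_polish(unname(y), params)
  y <- setNames(y, nm)
  if (!is.null(load)) y <- c(y, x10 = load$LT, x11 = 0)
  res <- max(abs(circuit_rhs(y, params, load = load, hold_x9 = TRUE)))
  if (!is.finite(res) || res > control$eq_tol)
    stop(sprintf(
      "pre-equilibration did not converge (residual %.3g > %.3g nM/min)",
      res, control$eq_tol), call. = FALSE)
  attr(y, "residual") <- res
  y
}

#' Simulate the stimulus-response experiment
#'
#' Expands the decision vector into full parameters (tying `kmA_CgA` to
#' `kmC_CgC`), pre-equilibrates without inducer, applies the extracellular
#' inducer step at `t0 = 0` and integrates to `tf`.  Two quadrature states
#' accumulate the total variations `int |dx8/dt| dt` and `int |dx6/dt| dt`
#' alongside the solution so the objectives inherit the integrator's error
#' control.
#'
#' @param theta named decision vector ([decision_bounds()]); alternatively
#'   `params` may be passed directly with `theta = NULL`.
#' @param protocol [stimulus_protocol()].
#' @param params base [circuit_parameters()].
#' @param load optional [load_parameters()].
#' @param control [solver_control()].
#' @param tie_kmA,check passed to [expand_decision()].
#' @return A `circuit_trajectory`: a data.frame with columns `time`,
#'   `x1`..`x9` (and `x10`, `x11` under load) and the algebraic monomer `M`,
#'   with attributes `tv_x8`, `tv_x6` (quadrature totals), `x9_prestep`,
#'   `x8_baseline`, `protocol`, `params` and `load`.
#' @export
simulate_circuit <- function(theta = NULL, protocol = stimulus_protocol(),
                             params = circuit_parameters(), load = NULL,
                             control = solver_control(), tie_kmA = TRUE,
                             check = TRUE) {
  if (!is.null(theta))
    params <- expand_decision(theta, params, tie_kmA = tie_kmA,
                              check = check)
  y_eq <- pre_equilibrate(params, protocol, load = load, control = control)
  x9_prestep <- unname(y_eq["x9"])
  x8_baseline <- unname(y_eq["x8"])
  y0 <- unname(y_eq)
  y0[9] <- y0[9] + protocol$Ie_step
  nm <- names(y_eq)
  y0 <- setNames(c(y0, 0, 0), c(nm, "q8", "q6"))
  times <- seq(protocol$t0, protocol$tf, length.out = control$n_out)
  out <- .integrate(y0, times, params, load = load, hold_x9 = FALSE,
                    control = control)
  out <- .clip_negative(out, control$neg_tol)
  traj <- as.data.frame(out[, c("time", nm)])
  traj$M <- monomer_concentration(traj$x2, traj$x3, traj$x4, params)
  structure(traj,
            class = c("circuit_trajectory", "data.frame"),
            tv_x8 = unname(out[nrow(out), "q8"]),
            tv_x6 = unname(out[nrow(out), "q6"]),
            x9_prestep = x9_prestep,
            x8_baseline = x8_baseline,
            protocol = protocol, params = params, load = load)
}

#' @export
print.circuit_trajectory <- function(x, ...) {
  cat(sprintf("<circuit_trajectory> %d samples over [%g, %g] min, %s\n",
              nrow(x), x$time[1], x$time[nrow(x)],
              if ("x10" %in% names(x)) "with downstream load" else
                "no load"))
  cat(sprintf("  TV(x8) = %.4g nM, TV(x6) = %.4g nM, x8(tf) = %.4g nM\n",
              attr(x, "tv_x8"), attr(x, "tv_x6"), x$x8[nrow(x)]))
  invisible(x)
}

#' Write a trajectory as CSV
#'
#' @param traj a `circuit_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
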