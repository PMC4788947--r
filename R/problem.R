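#' The I1-FFL adaptation tuning problem
#'
#' Builds the objective evaluator optimized by [spmode()]: each candidate
#' decision vector is expanded into full circuit parameters, the
#' stimulus-response experiment is simulated, and the adaptation indexes are
#' computed.  The repressor constraint `P` enters the evaluator as a Deb
#' violation (distance outside its band); the pertinency box gates archive
#' membership inside the engine.  Simulation failures are scored as heavily
#' infeasible rather than aborting a run.
#'
#' @param protocol [stimulus_protocol()].
#' @param params base [circuit_parameters()] (Table of fixed constants).
#' @param box [pertinency_box()].
#' @param control [solver_control()].
#' @param load optional [load_parameters()] to optimize the loaded circuit.
#' @param free character vector of decision-variable names left free
#'   (default: all ten).  The remaining variables are pinned.
#' @param at named values for the pinned variables; defaults to the
#'   midpoints of their bounds.
#' @return A problem object for [spmode()] / [brute_force_front()]: list
#'   with `lower`, `upper`, `names` and `eval`.
#' @export
i1ffl_problem <- function(protocol = stimulus_protocol(),
                          params = circuit_parameters(),
                          box = pertinency_box(),
                          control = solver_control(),
                          load = NULL,
                          free = decision_bounds()$parameter,
                          at = NULL) {
  b <- decision_bounds()
  if (!all(free %in% b$parameter))
    stop("i1ffl_problem(): unknown decision variable(s): ",
         paste(setdiff(free, b$parameter), collapse = ", "), call. = FALSE)
  free <- b$parameter[b$parameter %in% free]   # canonical order
  pinned <- setdiff(b$parameter, free)
  base <- setNames((b$lower + b$upper) / 2, b$parameter)
  if (!is.null(at)) {
    if (!all(names(at) %in% pinned))
      stop("i1ffl_problem(): `at` may only name pinned variables",
           call. = FALSE)
    base[names(at)] <- at
  }
  idx <- match(free, b$parameter)
  eval_fn <- function(theta) {
    full <- base
    full[free] <- theta
    res <- tryCatch({
      traj <- simulate_circuit(full, protocol = protocol, params = params,
                               load = load, control = control,
                               check = FALSE)
      evaluate_objectives(traj, box = box)
    }, error = function(e) NULL)
    if (is.null(res) || !is.finite(res$J1) || !is.finite(res$J2))
      return(list(J = c(1e12, 1e12), P = NA_real_, violation = 1e9,
                  pertinent = FALSE, feasible = FALSE))
    viol <- max(0, box$P[1] - res$P) + max(0, res$P - box$P[2])
    list(J = c(res$J1, res$J2), P = res$P, violation = viol,
         pertinent = res$pertinent, feasible = res$feasible)
  }
  list(lower = b$lower[idx], upper = b$upper[idx], names = free,
       eval = eval_fn, box = box, protocol = protocol, params = params,
       load = load, pinned = base[pinned])
}

#' Analytic bi-objective benchmark problem
#'
#' The classic convex one-variable benchmark `f1 = theta^2`,
#' `f2 = (theta - 2)^2` over `theta in [-5, 10]`.  Its Pareto set is
#' `theta in [0, 2]` and the front satisfies `f2 = (sqrt(f1) - 2)^2`, which
#' makes it an exact oracle for engine convergence.
#'
#' @return A problem object for [spmode()], carrying `front(f1)` (the
#'   closed-form front) and a fixed hypervolume reference `hv_ref`.
#' @export
benchmark_problem <- function() {
  list(
    lower = -5, upper = 10, names = "theta",
    eval = function(theta) {
      list(J = c(theta^2, (theta - 2)^2), P = NA_real_, violation = 0,
           pertinent = TRUE, feasible = TRUE)
    },
    front = function(f1) (sqrt(f1) - 2)^2,
    hv_ref = c(5, 5)
  )
}

#' A reference adapted decision vector
#'
#' A hand-picked decision vector in the region the tuning guidelines point
#' to (slow B degradation, weak B expression, strong gC transcription, fast
#' C turnover).  Used as a nominal operating point in examples and
#' convergence checks.
#'
#' @return Named decision vector of length 10.
#' @export
reference_theta <- function() {
  c(kmB_CgB = 1.2, kmC_CgC = 10, kpB = 1.1, kpC = 3, dB = 0.012,
    dC = 0.29, gamma1 = 195, gamma3 = 2e-4, gamma4 = 0.3, gamma5 = 1.1)
}
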