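#' Single-parameter tuning-knob sweep
#'
#' Starting from a chosen Pareto solution, one decision variable is swept
#' over a grid while everything else is held fixed, and the adaptation
#' objectives are re-evaluated at each grid value.  This emulates the
#' wet-lab situation where only one part (an RBS, a promoter, a degradation
#' tag) is exchanged: a good tuning knob moves the implementation almost
#' along the Pareto front.
#'
#' @param theta0 named base decision vector (within bounds).
#' @param name the decision variable to sweep.
#' @param grid numeric grid of values; default 20 points logarithmically
#'   spaced over the variable's bounds.
#' @param protocol [stimulus_protocol()].
#' @param params,box,control passed to the simulation and scoring.
#' @return An object of class `sweep_result`: data.frame with columns
#'   `value`, `J1`, `J2`, `P`, `pertinent`, `feasible`, `in_bounds`, `ok`
#'   (simulation success), plus attributes `parameter`, `theta0` and
#'   `base` (the objectives at `theta0`).
#' @export
knob_sweep <- function(theta0, name, grid = NULL,
                       protocol = stimulus_protocol(),
                       params = circuit_parameters(),
                       box = pertinency_box(),
                       control = solver_control()) {
  b <- decision_bounds()
  if (!name %in% b$parameter)
    stop("knob_sweep(): unknown decision variable '", name, "'",
         call. = FALSE)
  theta0 <- check_decision(theta0)
  if (is.null(grid)) {
    i <- match(name, b$parameter)
    grid <- exp(seq(log(b$lower[i]), log(b$upper[i]), length.out = 20))
  }
  eval_theta <- function(th) {
    tryCatch({
      traj <- simulate_circuit(th, protocol = protocol, params = params,
                               control = control, check = FALSE)
      ob <- evaluate_objectives(traj, box = box)
      c(J1 = ob$J1, J2 = ob$J2, P = ob$P,
        pertinent = as.numeric(ob$pertinent),
        feasible = as.numeric(ob$feasible), ok = 1)
    }, error = function(e) c(J1 = NA, J2 = NA, P = NA, pertinent = 0,
                             feasible = 0, ok = 0))
  }
  base <- eval_theta(theta0)
  i <- match(name, b$parameter)
  rows <- t(vapply(grid, function(v) {
    th <- theta0
    th[name] <- v
    eval_theta(th)
  }, numeric(6)))
  out <- data.frame(value = grid, rows)
  out$pertinent <- out$pertinent == 1
  out$feasible <- out$feasible == 1
  out$ok <- out$ok == 1
  out$in_bounds <- grid >= b$lower[i] & grid <= b$upper[i]
  structure(out, class = c("sweep_result", "data.frame"),
            parameter = name, theta0 = theta0, base = base)
}

#' Margin by which swept points fall behind a Pareto front
#'
#' For each point, the dominance excess relative to a stored front in
#' min-max normalized objective space: the largest `m` such that some front
#' member improves on the point by at least `m` in *both* objectives.
#' Points on or ahead of the front get a non-positive excess.  A sweep
#' stays "almost on top of the front" when all its excesses are below a
#' small margin (5% by convention here).
#'
#' @param J matrix of swept objective vectors (n x 2).
#' @param front matrix of front objective vectors (m x 2).
#' @return Numeric vector of excesses, one per row of `J`.
#' @export
dominance_excess <- function(J, front) {
  J <- as.matrix(J); front <- as.matrix(front)
  lo <- apply(front, 2, min)
  rng <- apply(front, 2, max) - lo
  rng[rng <= 0] <- 1
  Jn <- sweep(sweep(J, 2, lo), 2, rng, "/")
  Fn <- sweep(sweep(front, 2, lo), 2, rng, "/")
  vapply(seq_len(nrow(Jn)), function(i) {
    gaps <- pmin(Jn[i, 1] - Fn[, 1], Jn[i, 2] - Fn[, 2])
    max(gaps)
  }, numeric(1))
}

#' Re-evaluate a Pareto set under a downstream binding load
#'
#' Each Pareto solution is re-simulated with the load extension (the output
#' protein C binds a conserved pool of downstream sites) and its objectives
#' recomputed.  Only the front solutions are touched -- `|pareto|`
#' simulations in total, no re-optimization -- which is what makes the
#' retroactivity analysis cheap.
#'
#' @param pareto a `pareto_approx` of the unloaded circuit.
#' @param load [load_parameters()].
#' @param protocol,params,box,control as in [knob_sweep()].
#' @return An object of class `load_comparison`: data.frame with one row
#'   per solution (`solution`, `J1_unloaded`, `J2_unloaded`, `J1_loaded`,
#'   `J2_loaded`, `adaptation_retained`, `ok`), attribute `n_sims` counting
#'   the simulations performed.
#' @export
load_analysis <- function(pareto, load = load_parameters(),
                          protocol = stimulus_protocol(),
                          params = circuit_parameters(),
                          box = pertinency_box(),
                          control = solver_control()) {
  n <- nrow(pareto$J)
  if (!n) stop("load_analysis(): empty Pareto set", call. = FALSE)
  n_sims <- 0L
  rows <- lapply(seq_len(n), function(i) {
    th <- pareto$theta[i, ]
    res <- tryCatch({
      traj <- simulate_circuit(th, protocol = protocol, params = params,
                               load = load, control = control,
                               check = FALSE)
      ob <- evaluate_objectives(traj, box = box)
      data.frame(solution = i,
                 J1_unloaded = pareto$J[i, 1], J2_unloaded = pareto$J[i, 2],
                 J1_loaded = ob$J1, J2_loaded = ob$J2,
                 adaptation_retained = ob$pertinent, ok = TRUE)
    }, error = function(e)
      data.frame(solution = i,
                 J1_unloaded = pareto$J[i, 1], J2_unloaded = pareto$J[i, 2],
                 J1_loaded = NA_real_, J2_loaded = NA_real_,
                 adaptation_retained = FALSE, ok = FALSE))
    n_sims <<- n_sims + 1L
    res
  })
  structure(do.call(rbind, rows),
            class = c("load_comparison", "data.frame"),
            n_sims = n_sims, load = load)
}
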