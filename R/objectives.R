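#' Pertinency box for the adaptation objectives
#'
#' Designer-imposed objective-space bounds beyond which a response no longer
#' counts as adaptive: outside them either the output barely moves relative
#' to the input (no sensitivity) or it fails to return towards baseline (no
#' precision).  The protein-B excursion `P` is constrained separately to
#' keep repressor concentrations realistic.
#'
#' @param J1 range for inverse sensitivity (default `c(1e-3, 200)`).
#' @param J2 range for inverse precision (default `c(1e-4, 20)`).
#' @param P range for the repressor total-variation constraint (default
#'   `c(1, 1e4)`; the upper bound is the one stated with the constraint's
#'   rationale, and is configurable up to looser published variants).
#' @return An object of class `pertinency_box`.
#' @export
pertinency_box <- function(J1 = c(1e-3, 200), J2 = c(1e-4, 20),
                           P = c(1, 1e4)) {
  for (nm in c("J1", "J2", "P")) {
    r <- get(nm)
    if (length(r) != 2 || !all(is.finite(r)) || r[1] >= r[2])
      stop("pertinency_box(): ", nm, " must be an increasing range",
           call. = FALSE)
  }
  structure(list(J1 = J1, J2 = J2, P = P), class = "pertinency_box")
}

#' Total variation of a trajectory species
#'
#' `int_{t0}^{tf} |dx/dt| dt` for a state series.  For `x8` and `x6` of a
#' simulated trajectory the value comes from the quadrature states
#' integrated alongside the solution; for trajectories without accumulators
#' (e.g. synthetic test pulses) the discrete variation `sum |diff(x)|` is
#' used, which is exact for piecewise-monotone sampled paths.
#'
#' @param traj a `circuit_trajectory` (or any data.frame with the species
#'   column).
#' @param species column name, e.g. `"x8"`.
#' @return Total variation (nM), non-negative.
#' @export
total_variation <- function(traj, species = "x8") {
  acc <- switch(species, x8 = attr(traj, "tv_x8"), x6 = attr(traj, "tv_x6"),
                NULL)
  if (!is.null(acc)) return(acc)
  if (!species %in% names(traj))
    stop("total_variation(): no accumulator or series for species '",
         species, "'", call. = FALSE)
  sum(abs(diff(traj[[species]])))
}

#' Evaluate the adaptation objectives on a trajectory
#'
#' Computes the two design indexes of the adaptation problem and the
#' repressor constraint:
#' \describe{
#'   \item{J1 (inverse sensitivity)}{`2 * (x9(tf) - x9(t0-)) / int|dx8/dt|dt`
#'     where `x9(t0-)` is the pre-step extracellular inducer (zero after
#'     equilibration); the total absolute variation of the output is half
#'     the accumulated absolute derivative, hence the factor 2.  Small J1
#'     means a large output excursion per unit of input change.}
#'   \item{J2 (inverse precision)}{`(x8(tf) - x8(t0)) / (x9(tf) - x9(t0-))`:
#'     the normalized residual output error at the end of the experiment.
#'     J2 = 0 is perfect adaptation.}
#'   \item{P (constraint)}{`int|dx6/dt|dt`, the total excursion of the
#'     repressor B, kept within a realistic band.}
#' }
#'
#' @param traj a `circuit_trajectory` (simulated, or synthetic with the
#'   `x9_prestep`/`x8_baseline` attributes; missing attributes default to
#'   zero baselines).
#' @param box [pertinency_box()] used for the admissibility flags.
#' @param tv_floor denominator floor (nM); an output variation below it
#'   yields the `J1 = Inf` sentinel and `pertinent = FALSE`, an input change
#'   below it is an error (no stimulus was applied).
#' @return An object of class `objective_result`: list with `J1`, `J2`, `P`,
#'   `pertinent`, `feasible` and a `diagnostics` list (`tv_x8`, `dx9`).
#' @export
evaluate_objectives <- function(traj, box = pertinency_box(),
                                tv_floor = 1e-9) {
  n <- nrow(traj)
  x9_pre <- attr(traj, "x9_prestep")
  if (is.null(x9_pre)) x9_pre <- 0
  x8_0 <- attr(traj, "x8_baseline")
  if (is.null(x8_0)) x8_0 <- traj$x8[1]
  dx9 <- traj$x9[n] - x9_pre
  if (!is.finite(dx9) || abs(dx9) < tv_floor)
    stop("evaluate_objectives(): input change below floor - no stimulus",
         call. = FALSE)
  tv8 <- total_variation(traj, "x8")
  P <- total_variation(traj, "x6")
  if (tv8 < tv_floor) {
    J1 <- Inf
  } else {
    J1 <- 2 * dx9 / tv8
  }
  J2 <- (traj$x8[n] - x8_0) / dx9
  res <- structure(list(J1 = J1, J2 = J2, P = P,
                        pertinent = NA, feasible = NA,
                        diagnostics = list(tv_x8 = tv8, dx9 = dx9)),
                   class = "objective_result")
  adm <- is_admissible(res, box)
  res$pertinent <- adm[["pertinent"]]
  res$feasible <- adm[["feasible"]]
  res
}

#' Admissibility of an objective result
#'
#' A solution is *pertinent* when both objectives fall inside the pertinency
#' box, and *feasible* when additionally the repressor constraint `P` lies
#' in its band.  Infinite sentinels are never admissible.
#'
#' @param result an `objective_result` (or any list with `J1`, `J2`, `P`).
#' @param box [pertinency_box()].
#' @return Named logical vector `c(pertinent = , feasible = )`.
#' @export
is_admissible <- function(result, box = pertinency_box()) {
  inside <- function(v, r) is.finite(v) && v > r[1] && v < r[2]
  pert <- inside(result$J1, box$J1) && inside(result$J2, box$J2)
  feas <- pert && inside(result$P, box$P)
  c(pertinent = pert, feasible = feas)
}

#' @export
print.objective_result <- function(x, ...) {
  cat(sprintf(
    "<objective_result> J1 = %.4g, J2 = %.4g, P = %.4g (%s, %s)\n",
    x$J1, x$J2, x$P,
    if (isTRUE(x$pertinent)) "pertinent" else "not pertinent",
    if (isTRUE(x$feasible)) "feasible" else "infeasible"))
  invisible(x)
}
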