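#' Pareto dominance (minimization)
#'
#' @param a,b numeric objective vectors of equal length, finite.
#' @return `TRUE` iff `a` is no worse than `b` in every objective and
#'   strictly better in at least one.
#' @export
#' @examples
#' dominates(c(1, 1), c(2, 2))  # TRUE
#' dominates(c(1, 2), c(2, 1))  # FALSE (incomparable)
dominates <- function(a, b) {
  all(a <= b) && any(a < b)
}

# Indices of the mutually non-dominated rows of an objective matrix.
.nondominated <- function(J) {
  n <- nrow(J)
  if (n <= 1) return(seq_len(n))
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    for (j in seq_len(n)) {
      if (i == j || !keep[j]) next
      if (dominates(J[j, ], J[i, ])) { keep[i] <- FALSE; break }
    }
  }
  which(keep)
}

#' Dominance filter
#'
#' Reduces a set of solutions to its mutually non-dominated subset.
#' Idempotent.  Exact duplicates in objective space are all retained (none
#' dominates the other).
#'
#' @param J numeric matrix, one row per solution, one column per objective.
#' @return Integer indices of the surviving rows.
#' @export
pareto_filter <- function(J) {
  J <- as.matrix(J)
  .nondominated(J)
}

#' Spherical pruning of a non-dominated archive
#'
#' Enforces spread along a bi-objective front: objectives are normalized to
#' the archive's ideal/nadir points, each solution is mapped to the angular
#' sector of its normalized objective vector, and at most one solution per
#' occupied sector is kept -- the one closest (Euclidean norm) to the ideal
#' point.
#'
#' @param J numeric matrix (n x 2) of mutually non-dominated objectives.
#' @param sectors number of angular sectors spanning the quarter circle.
#' @return Integer indices of the retained rows (subset of `1:nrow(J)`).
#' @export
spherical_prune <- function(J, sectors = 100) {
  J <- as.matrix(J)
  n <- nrow(J)
  if (n == 0) return(integer(0))
  if (ncol(J) != 2)
    stop("spherical_prune(): implemented for two objectives", call. = FALSE)
  ideal <- apply(J, 2, min)
  nadir <- apply(J, 2, max)
  rng <- nadir - ideal
  rng[rng <= 0] <- 1
  Jn <- sweep(sweep(J, 2, ideal), 2, rng, "/")
  ang <- atan2(Jn[, 2], Jn[, 1])          # in [0, pi/2] for normalized J
  sec <- pmin(pmax(floor(ang / (pi / 2) * sectors), 0), sectors - 1)
  norm2 <- sqrt(rowSums(Jn^2))
  keep <- vapply(split(seq_len(n), sec),
                 function(idx) idx[which.min(norm2[idx])], integer(1))
  sort(unname(keep))
}

#' Optimizer configuration
#'
#' Settings for the differential-evolution multi-objective engine.  The
#' published description of the algorithm family fixes the mechanisms
#' (external archive, spherical pruning, objective-space bound) but not the
#' scalar hyperparameters; the defaults here are the conventional choices
#' for DE/rand/1/bin.
#'
#' @param np population size (default 50).
#' @param F differential weight in `(0, 2]` (default 0.5).
#' @param CR crossover rate in `[0, 1]` (default 0.9).
#' @param max_evals objective-evaluation budget (default 15000).
#' @param sectors angular sectors for [spherical_prune()] (default 100).
#' @param box [pertinency_box()] gating archive entry.
#' @param seed RNG seed driving the whole run.
#' @return A list of class `mood_config`.
#' @export
mood_config <- function(np = 50, F = 0.5, CR = 0.9, max_evals = 15000,
                        sectors = 100, box = pertinency_box(), seed = 1) {
  if (np < 4) stop("mood_config(): population must be >= 4", call. = FALSE)
  if (!(F > 0 && F <= 2)) stop("mood_config(): need 0 < F <= 2",
                               call. = FALSE)
  if (!(CR >= 0 && CR <= 1)) stop("mood_config(): need 0 <= CR <= 1",
                                  call. = FALSE)
  if (max_evals <= np)
    stop("mood_config(): evaluation budget must exceed the population",
         call. = FALSE)
  structure(list(np = as.integer(np), F = F, CR = CR,
                 max_evals = as.integer(max_evals),
                 sectors = as.integer(sectors), box = box,
                 seed = as.integer(seed)),
            class = "mood_config")
}

# Wrap a raw evaluator result into the engine's individual bookkeeping.
.as_individual <- function(theta, ev) {
  J <- ev$J
  bad <- is.null(J) || length(J) != 2 || any(!is.finite(J))
  if (bad) {
    J <- c(1e12, 1e12)
    ev$violation <- max(ev$violation %||% 0, 1e9)
    ev$pertinent <- FALSE
    ev$feasible <- FALSE
  }
  list(theta = theta, J = unname(J), P = ev$P %||% NA_real_,
       violation = ev$violation %||% 0,
       pertinent = isTRUE(ev$pertinent), feasible = isTRUE(ev$feasible))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Archive update: pool current archive with admissible candidates, apply the
# dominance filter, then spherical pruning.
.update_archive <- function(archive, candidates, sectors) {
  adm <- Filter(function(ind) ind$pertinent && ind$feasible &&
                  ind$violation == 0, candidates)
  pool <- c(archive, adm)
  if (!length(pool)) return(pool)
  J <- do.call(rbind, lapply(pool, `[[`, "J"))
  pool <- pool[.nondominated(J)]
  J <- do.call(rbind, lapply(pool, `[[`, "J"))
  pool[spherical_prune(J, sectors)]
}

# Deb-rule pairwise selection: does the trial replace the target?
.deb_wins <- function(trial, target) {
  tf <- trial$violation == 0
  gf <- target$violation == 0
  if (tf && !gf) return(TRUE)
  if (!tf && gf) return(FALSE)
  if (!tf && !gf) return(trial$violation < target$violation)
  # both feasible: trial survives unless the target dominates it
  !dominates(target$J, trial$J)
}

#' Run the multi-objective differential-evolution optimizer
#'
#' DE/rand/1/bin evolution over a bounded decision space with Deb-rule
#' constraint handling, an external archive of pertinent non-dominated
#' solutions, spherical pruning for spread, and an objective-space
#' pertinency bound: candidates outside the box are barred from the archive
#' but may stay in the population so the search gradient towards the box is
#' preserved.  Mutants falling outside the decision bounds are reflected
#' back inside.  The run is deterministic given the seed.
#'
#' @param problem a problem object as built by [i1ffl_problem()] or
#'   [benchmark_problem()]: a list with numeric `lower`, `upper`, optional
#'   `names`, and `eval(theta)` returning `list(J = c(J1, J2), P,
#'   violation, pertinent, feasible)`.
#' @param config [mood_config()].
#' @return An object of class `pareto_approx`: list with objective matrix
#'   `J` (columns `J1`, `J2`), decision matrix `theta`, constraint values
#'   `P`, `evals` used, `seed`, `config` and the per-generation archive
#'   hypervolume `hv_history` (reference point: 1.1 times the running
#'   nadir).
#' @export
spmode <- function(problem, config = mood_config()) {
  d <- length(problem$lower)
  lb <- problem$lower
  ub <- problem$upper
  if (config$max_evals < 2 * config$np)
    stop("spmode(): budget smaller than one generation", call. = FALSE)
  set.seed(config$seed)
  np <- config$np
  pop <- lapply(seq_len(np), function(i) lb + runif(d) * (ub - lb))
  inds <- lapply(pop, function(th) .as_individual(th, problem$eval(th)))
  evals <- np
  archive <- .update_archive(list(), inds, config$sectors)
  hv_hist <- .archive_hv(archive, problem$hv_ref)
  reflect <- function(v) {
    # reflect into [lb, ub]; repeat in case of large excursions
    for (k in 1:10) {
      lo <- v < lb; v[lo] <- 2 * lb[lo] - v[lo]
      hi <- v > ub; v[hi] <- 2 * ub[hi] - v[hi]
      if (!any(v < lb | v > ub)) break
    }
    pmin(pmax(v, lb), ub)
  }
  while (evals + np <= config$max_evals) {
    trials <- vector("list", np)
    # archive members join the evolutionary process as mutation bases
    elites <- lapply(archive, `[[`, "theta")
    for (i in seq_len(np)) {
      r <- sample(setdiff(seq_len(np), i), 3)
      base_th <- if (length(elites) && runif(1) < 0.5)
        elites[[sample.int(length(elites), 1)]] else inds[[r[1]]]$theta
      v <- base_th +
        config$F * (inds[[r[2]]]$theta - inds[[r[3]]]$theta)
      v <- reflect(v)
      jrand <- sample.int(d, 1)
      cross <- runif(d) <= config$CR
      cross[jrand] <- TRUE
      u <- inds[[i]]$theta
      u[cross] <- v[cross]
      trials[[i]] <- u
    }
    new_inds <- lapply(trials, function(th)
      .as_individual(th, problem$eval(th)))
    evals <- evals + np
    for (i in seq_len(np))
      if (.deb_wins(new_inds[[i]], inds[[i]])) inds[[i]] <- new_inds[[i]]
    archive <- .update_archive(archive, new_inds, config$sectors)
    hv_hist <- c(hv_hist, .archive_hv(archive, problem$hv_ref))
  }
  .pareto_approx(archive, problem, evals, config, hv_hist)
}

# Hypervolume of the archive w.r.t. a fixed conservative reference point;
# used only as a progress diagnostic.
.archive_hv <- function(archive, ref = NULL) {
  if (!length(archive)) return(0)
  J <- do.call(rbind, lapply(archive, `[[`, "J"))
  if (is.null(ref)) ref <- c(max(J[, 1]), max(J[, 2])) * 1.1 + 1e-12
  hypervolume_2d(J, ref)
}

#' Dominated hypervolume of a bi-objective front
#'
#' @param J n x 2 matrix of objective vectors (minimization).
#' @param ref reference point, componentwise worse than every row.
#' @return The area dominated by the front within the reference box.
#' @export
hypervolume_2d <- function(J, ref) {
  J <- as.matrix(J)
  J <- J[.nondominated(J), , drop = FALSE]
  J <- J[J[, 1] < ref[1] & J[, 2] < ref[2], , drop = FALSE]
  if (!nrow(J)) return(0)
  o <- order(J[, 1], J[, 2])
  J <- J[o, , drop = FALSE]
  prev_y <- ref[2]
  hv <- 0
  for (i in seq_len(nrow(J))) {
    hv <- hv + (ref[1] - J[i, 1]) * (prev_y - J[i, 2])
    prev_y <- J[i, 2]
  }
  hv
}

.pareto_approx <- function(archive, problem, evals, config, hv_hist = NULL) {
  nms <- problem$names %||% paste0("theta", seq_along(problem$lower))
  if (length(archive)) {
    J <- do.call(rbind, lapply(archive, `[[`, "J"))
    th <- do.call(rbind, lapply(archive, `[[`, "theta"))
    o <- order(J[, 1], J[, 2])
    J <- J[o, , drop = FALSE]
    th <- th[o, , drop = FALSE]
    P <- vapply(archive, `[[`, numeric(1), "P")[o]
  } else {
    J <- matrix(numeric(0), 0, 2)
    th <- matrix(numeric(0), 0, length(problem$lower))
    P <- numeric(0)
  }
  colnames(J) <- c("J1", "J2")
  colnames(th) <- nms
  structure(list(J = J, theta = th, P = P, evals = evals,
                 seed = config$seed, config = config,
                 hv_history = hv_hist),
            class = "pareto_approx")
}

#' @export
print.pareto_approx <- function(x, ...) {
  cat(sprintf(
    "<pareto_approx> %d solutions after %d evaluations (seed %d)\n",
    nrow(x$J), x$evals, x$seed))
  if (nrow(x$J))
    cat(sprintf("  J1 in [%.4g, %.4g], J2 in [%.4g, %.4g]\n",
                min(x$J[, 1]), max(x$J[, 1]), min(x$J[, 2]),
                max(x$J[, 2])))
  invisible(x)
}

#' @export
as.data.frame.pareto_approx <- function(x, ...) {
  cbind(data.frame(J1 = x$J[, 1], J2 = x$J[, 2], P = x$P),
        as.data.frame(x$theta))
}

#' Brute-force Pareto front approximation
#'
#' Samples the decision space (uniform random or full grid), evaluates every
#' sample, keeps the feasible and pertinent ones, and applies the dominance
#' filter.  Serves as the Monte-Carlo comparison baseline and as an
#' exhaustive oracle on low-dimensional problems.
#'
#' @param problem as for [spmode()].
#' @param sampler `"random"` or `"grid"`.
#' @param N number of samples (for `"grid"`, rounded down to the nearest
#'   per-dimension resolution `floor(N^(1/d))^d`).
#' @param seed RNG seed (random sampler only).
#' @param box unused placeholder kept for symmetry; admissibility is taken
#'   from the problem evaluator.
#' @return A `pareto_approx` of the surviving set.
#' @export
brute_force_front <- function(problem, sampler = c("random", "grid"),
                              N = 1000, seed = 1, box = NULL) {
  sampler <- match.arg(sampler)
  d <- length(problem$lower)
  if (N < 1) stop("brute_force_front(): N must be >= 1", call. = FALSE)
  if (sampler == "random") {
    set.seed(seed)
    thetas <- lapply(seq_len(N), function(i)
      problem$lower + runif(d) * (problem$upper - problem$lower))
  } else {
    m <- max(1L, floor(N^(1 / d)))
    axes <- lapply(seq_len(d), function(j)
      seq(problem$lower[j], problem$upper[j], length.out = m))
    grid <- as.matrix(expand.grid(axes))
    thetas <- lapply(seq_len(nrow(grid)), function(i) unname(grid[i, ]))
  }
  inds <- lapply(thetas, function(th) .as_individual(th, problem$eval(th)))
  adm <- Filter(function(ind) ind$pertinent && ind$feasible &&
                  ind$violation == 0, inds)
  if (length(adm)) {
    J <- do.call(rbind, lapply(adm, `[[`, "J"))
    adm <- adm[.nondominated(J)]
  }
  cfg <- mood_config(np = 4, max_evals = max(length(thetas), 5), seed = seed)
  .pareto_approx(adm, problem, length(thetas), cfg)
}

#' Generational distance to a reference front
#'
#' Mean Euclidean distance from each obtained front point to its nearest
#' point on a (densely sampled) reference front.
#'
#' @param J n x 2 matrix of obtained objectives.
#' @param reference m x 2 matrix sampling the true front.
#' @return Non-negative scalar; 0 iff every point lies on the reference.
#' @export
generational_distance <- function(J, reference) {
  J <- as.matrix(J); reference <- as.matrix(reference)
  if (!nrow(J)) return(Inf)
  d <- vapply(seq_len(nrow(J)), function(i) {
    sqrt(min((reference[, 1] - J[i, 1])^2 + (reference[, 2] - J[i, 2])^2))
  }, numeric(1))
  mean(d)
}
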