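#' Specification of a deterministic test fixture
#'
#' @param id `"benchmark"` (the analytic bi-objective problem),
#'   `"planted_clusters"` (a synthetic Pareto front/set with two objective
#'   blobs and a subset of parameters shifted between them) or `"pulse"` (a
#'   synthetic trajectory with analytically known objectives).
#' @param size number of solutions / samples (where applicable).
#' @param effect planted between-cluster shift, as a fraction of each
#'   shifted parameter's range (planted_clusters), or pulse geometry list
#'   with `h` (peak height, nM), `delta` (input change, nM) and `residual`
#'   (final output offset, nM) for `"pulse"`.
#' @param seed RNG seed; generation is seed-deterministic.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(id = c("benchmark", "planted_clusters", "pulse"),
                         size = 60, effect = NULL, seed = 1) {
  id <- match.arg(id)
  structure(list(id = id, size = size, effect = effect, seed = seed),
            class = "fixture_spec")
}

#' Generate a deterministic test fixture
#'
#' Fixtures back the test suite with problems whose answers are known in
#' closed form, independently of the circuit model:
#' \describe{
#'   \item{benchmark}{[benchmark_problem()]: convex bi-objective problem
#'     with front `f2 = (sqrt(f1) - 2)^2`.}
#'   \item{planted_clusters}{`size` solutions whose objectives form two
#'     well-separated blobs; the first 3 decision variables are shifted
#'     between blobs by `effect` (default 0.5) times their range, the other
#'     7 are iid uniform.  Returns `J`, `theta`, `labels_true`,
#'     `shifted`, `bounds`.}
#'   \item{pulse}{a synthetic `circuit_trajectory` whose output rises
#'     linearly from 0 to the peak `h` and back to `residual` while the
#'     input sits at `delta`; by construction `J1 = delta / h` (total
#'     variation `2h - residual`, halved by the index definition when
#'     `residual = 0`) and `J2 = residual / delta`.}
#' }
#'
#' @param spec a [fixture_spec()].
#' @return Fixture data, see Details.
#' @export
make_fixture <- function(spec = fixture_spec()) {
  switch(spec$id,
    benchmark = benchmark_problem(),
    planted_clusters = .fixture_planted(spec),
    pulse = .fixture_pulse(spec),
    stop("make_fixture(): unknown fixture id '", spec$id, "'",
         call. = FALSE))
}

.fixture_planted <- function(spec) {
  set.seed(spec$seed)
  n <- spec$size
  effect <- spec$effect %||% 0.5
  b <- decision_bounds()
  p <- nrow(b)
  labels <- rep(1:2, length.out = n)
  # two tight blobs at opposite ends of the normalized objective square
  centers <- rbind(c(0.2, 0.8), c(0.8, 0.2))
  J <- centers[labels, ] + matrix(stats::rnorm(2 * n, sd = 0.05), n, 2)
  colnames(J) <- c("J1", "J2")
  theta <- matrix(runif(n * p), n, p)
  shifted <- 1:3
  for (j in shifted) {
    # cluster 2 sits `effect` higher within [0,1], both clusters tight
    theta[, j] <- 0.15 + (labels - 1) * effect +
      (theta[, j] - 0.5) * 0.2
  }
  theta <- pmin(pmax(theta, 0), 1)
  theta <- sweep(sweep(theta, 2, b$upper - b$lower, "*"), 2, b$lower, "+")
  colnames(theta) <- b$parameter
  list(J = J, theta = theta, labels_true = labels,
       shifted = b$parameter[shifted], bounds = b)
}

.fixture_pulse <- function(spec) {
  geom <- spec$effect %||% list()
  h <- geom$h %||% 100
  delta <- geom$delta %||% 50
  residual <- geom$residual %||% 0
  n <- max(5L, as.integer(spec$size))
  tt <- seq(0, 100, length.out = 2 * (n %/% 2) + 1)
  half <- (length(tt) + 1) %/% 2
  up <- seq(0, h, length.out = half)
  down <- seq(h, residual, length.out = half)
  x8 <- c(up, down[-1])
  traj <- data.frame(time = tt, x8 = x8, x9 = rep(delta, length(tt)),
                     x6 = rep(0, length(tt)))
  structure(traj, class = c("circuit_trajectory", "data.frame"),
            x9_prestep = 0, x8_baseline = 0)
}
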