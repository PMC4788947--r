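#' Run the full MOOD workflow
#'
#' Drives the complete pipeline from one configuration: build the tuning
#' problem, approximate the Pareto front, cluster it and select the cluster
#' count, extract the tuning guidelines, and compute the Level-Diagram
#' table.  One seed drives every stochastic step.
#'
#' @param cfg a `run_config` (default [default_run_config()]).
#' @param quiet suppress progress messages.
#' @return A list of class `mood_run`: `pareto`, `clustering` (`NULL` when
#'   the front has fewer than 3 solutions), `guidelines`, `ld`, `cfg`.
#' @export
run_mood <- function(cfg = default_run_config(), quiet = FALSE) {
  obj <- .config_objects(cfg)
  say <- function(...) if (!quiet) message(sprintf(...))
  say("optimizing (budget %d evaluations, seed %d) ...",
      obj$moo$max_evals, obj$moo$seed)
  problem <- i1ffl_problem(protocol = obj$protocol, params = obj$params,
                           box = obj$box, control = obj$control)
  pareto <- spmode(problem, obj$moo)
  say("archive: %d pertinent non-dominated solutions", nrow(pareto$J))
  clustering <- NULL
  guidelines <- NULL
  ld <- NULL
  if (nrow(pareto$J) >= 3) {
    tree <- cluster_tree(pareto$J,
                         features = cfg$guidelines$features,
                         theta = pareto$theta)
    clustering <- select_k(tree, pareto$theta,
                           alpha = cfg$guidelines$alpha,
                           k_max = cfg$guidelines$k_max)
    say("clustering: k = %d", clustering$k)
    guidelines <- extract_guidelines(clustering, pareto$theta,
                                     bounds = cfg$bounds,
                                     alpha = cfg$guidelines$alpha,
                                     shrink = cfg$guidelines$shrink)
    ld <- level_diagram(pareto, clustering)
  } else {
    say("front too small for clustering; guidelines skipped")
  }
  structure(list(pareto = pareto, clustering = clustering,
                 guidelines = guidelines, ld = ld, cfg = cfg),
            class = "mood_run")
}

#' @export
print.mood_run <- function(x, ...) {
  print(x$pareto)
  if (!is.null(x$clustering)) print(x$clustering)
  if (!is.null(x$guidelines)) print(x$guidelines)
  invisible(x)
}
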