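# Shared, lazily computed optimization runs.  Helpers are sourced once per
# test session, so expensive full-budget runs are reused across files.
.run_cache <- new.env(parent = emptyenv())

cached_full_run <- function(seed) {
  key <- paste0("full", seed)
  if (is.null(.run_cache[[key]])) {
    cfg <- default_run_config()
    cfg$seed <- as.integer(seed)
    .run_cache[[key]] <- run_mood(cfg, quiet = TRUE)
  }
  .run_cache[[key]]
}

cached_small_pareto <- function() {
  if (is.null(.run_cache$small)) {
    .run_cache$small <- spmode(
      i1ffl_problem(), mood_config(max_evals = 1500, seed = 99))
  }
  .run_cache$small
}

# random valid circuit states for property tests
random_states <- function(n, seed = 1) {
  set.seed(seed)
  matrix(stats::runif(3 * n, 0, 1000), ncol = 3,
         dimnames = list(NULL, c("x2", "x3", "x4")))
}
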