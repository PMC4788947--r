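#' Default run configuration
#'
#' The full set of settings driving a MOOD run, with every default taken
#' from the published model constants and the package's documented
#' conventions.  The object is a plain nested list so it round-trips
#' through YAML.
#'
#' @return A list of class `run_config` with components `parameters`
#'   (overrides for [circuit_parameters()]), `bounds` (data.frame),
#'   `protocol`, `box`, `moo` (population, F, CR, max_evals, sectors),
#'   `guidelines` (alpha, shrink, k_max, features), `load`, `solver`,
#'   `outdir` and `seed`.
#' @export
default_run_config <- function() {
  structure(list(
    parameters = list(),
    bounds = decision_bounds(),
    protocol = unclass(stimulus_protocol()),
    box = unclass(pertinency_box()),
    moo = list(np = 50, F = 0.5, CR = 0.9, max_evals = 15000,
               sectors = 100),
    guidelines = list(alpha = 0.05, shrink = 0.6, k_max = 10,
                      features = "objectives"),
    load = unclass(load_parameters()),
    solver = unclass(solver_control()),
    outdir = "mood-results",
    seed = 1L
  ), class = "run_config")
}

#' Load and validate a run configuration
#'
#' Reads a YAML file and merges it over [default_run_config()].  An empty
#' file yields all defaults.  Unknown keys (at the top level or within a
#' section) and inconsistent bounds are rejected with descriptive errors.
#'
#' @param path YAML file.
#' @return A validated `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path))
    stop("load_run_config(): no such file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw))
    stop("load_run_config(): malformed configuration file", call. = FALSE)
  cfg <- default_run_config()
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown))
    stop("load_run_config(): unknown key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  for (section in names(raw)) {
    val <- raw[[section]]
    if (section %in% c("outdir", "seed")) {
      cfg[[section]] <- val
    } else if (section == "bounds") {
      cfg$bounds <- .merge_bounds(cfg$bounds, val)
    } else if (section == "parameters") {
      cfg$parameters <- val
    } else {
      sub_unknown <- setdiff(names(val), names(cfg[[section]]))
      if (length(sub_unknown))
        stop("load_run_config(): unknown key(s) in '", section, "': ",
             paste(sub_unknown, collapse = ", "), call. = FALSE)
      cfg[[section]] <- modifyList(cfg[[section]], val)
    }
  }
  validate_run_config(cfg)
}

.merge_bounds <- function(bounds, val) {
  for (nm in names(val)) {
    if (!nm %in% bounds$parameter)
      stop("load_run_config(): unknown decision variable in bounds: ", nm,
           call. = FALSE)
    r <- unlist(val[[nm]])
    if (length(r) != 2)
      stop("load_run_config(): bounds for ", nm, " must be [lower, upper]",
           call. = FALSE)
    bounds[bounds$parameter == nm, c("lower", "upper")] <- as.list(r)
  }
  bounds
}

#' @rdname load_run_config
#' @param cfg a `run_config` to validate.
#' @export
validate_run_config <- function(cfg) {
  bad <- cfg$bounds$lower >= cfg$bounds$upper
  if (any(bad))
    stop("run_config: lower >= upper for decision variable(s): ",
         paste(cfg$bounds$parameter[bad], collapse = ", "), call. = FALSE)
  # constructors re-validate every sectioned setting
  do.call(circuit_parameters, cfg$parameters)
  do.call(stimulus_protocol, cfg$protocol)
  do.call(pertinency_box, lapply(cfg$box, as.numeric))
  do.call(load_parameters, cfg$load)
  do.call(solver_control, cfg$solver)
  mood_config(np = cfg$moo$np, F = cfg$moo$F, CR = cfg$moo$CR,
              max_evals = cfg$moo$max_evals, sectors = cfg$moo$sectors,
              seed = as.integer(cfg$seed))
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1)
    stop("run_config: seed must be a single integer", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Save a run configuration as YAML
#'
#' @param cfg a `run_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_run_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$bounds <- setNames(
    lapply(seq_len(nrow(cfg$bounds)),
           function(i) c(cfg$bounds$lower[i], cfg$bounds$upper[i])),
    cfg$bounds$parameter)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Stable hash of a run configuration
#'
#' Polynomial rolling hash over the canonical JSON rendering; any change to
#' any setting changes the hash.  Used to stamp persisted results.
#'
#' @param cfg a `run_config` (or any jsonlite-serializable object).
#' @return 8-character hex string.
#' @export
config_hash <- function(cfg) {
  txt <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(txt))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

# Build the module-level objects from a run_config.
.config_objects <- function(cfg) {
  list(
    params = do.call(circuit_parameters, cfg$parameters),
    protocol = do.call(stimulus_protocol, cfg$protocol),
    box = do.call(pertinency_box, lapply(cfg$box, as.numeric)),
    load = do.call(load_parameters, cfg$load),
    control = do.call(solver_control, cfg$solver),
    moo = mood_config(np = cfg$moo$np, F = cfg$moo$F, CR = cfg$moo$CR,
                      max_evals = cfg$moo$max_evals,
                      sectors = cfg$moo$sectors,
                      box = do.call(pertinency_box,
                                    lapply(cfg$box, as.numeric)),
                      seed = as.integer(cfg$seed))
  )
}
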