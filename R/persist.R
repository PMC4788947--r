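SCHEMA_VERSION <- "1"

#' Write a Pareto approximation as CSV + JSON metadata
#'
#' One row per solution: `J1`, `J2`, `P` and the decision variables.  A
#' sibling `<stem>.json` records the schema version, seed, evaluation count
#' and optimizer settings.
#'
#' @param pareto a `pareto_approx`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_pareto <- function(pareto, path) {
  write.csv(as.data.frame(pareto), path, row.names = FALSE)
  meta <- list(schema = SCHEMA_VERSION, seed = pareto$seed,
               evals = pareto$evals,
               config = unclass(pareto$config[c("np", "F", "CR",
                                                "max_evals", "sectors")]))
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a Pareto approximation written by [write_pareto()]
#'
#' @param path CSV file path.
#' @return A `pareto_approx` (metadata restored from the JSON sidecar when
#'   present).
#' @export
read_pareto <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("J1", "J2", "P") %in% names(df)))
  th <- as.matrix(df[, setdiff(names(df), c("J1", "J2", "P")),
                     drop = FALSE])
  J <- as.matrix(df[, c("J1", "J2")])
  meta_path <- sub("\\.csv$", ".json", path)
  seed <- 0L; evals <- nrow(df)
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    seed <- meta$seed %||% 0L
    evals <- meta$evals %||% evals
  }
  cfg <- mood_config(seed = as.integer(seed))
  structure(list(J = J, theta = th, P = df$P, evals = evals, seed = seed,
                 config = cfg, hv_history = NULL),
            class = "pareto_approx")
}

#' Persist the artifacts of a MOOD run
#'
#' Writes whatever artifacts are supplied (Pareto front/set, guideline
#' report, Level-Diagram table, sweep and load comparisons) as CSV files
#' under `outdir`, plus a JSON manifest recording the schema version, seed,
#' configuration hash and every file written.
#'
#' @param outdir output directory (created if needed).
#' @param cfg the `run_config` of the run (hashed into the manifest).
#' @param pareto optional `pareto_approx`.
#' @param guidelines optional `guideline_report`.
#' @param ld optional `level_diagram`.
#' @param sweep optional `sweep_result`.
#' @param load_cmp optional `load_comparison`.
#' @return The manifest (list), invisibly; written as `manifest.json`.
#' @export
persist_results <- function(outdir, cfg = default_run_config(),
                            pareto = NULL, guidelines = NULL, ld = NULL,
                            sweep = NULL, load_cmp = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir))
    stop("persist_results(): cannot create directory ", outdir,
         call. = FALSE)
  files <- character(0)
  add <- function(name) files <<- c(files, name)
  if (!is.null(pareto)) {
    write_pareto(pareto, file.path(outdir, "pareto.csv"))
    add("pareto.csv"); add("pareto.json")
  }
  if (!is.null(guidelines)) {
    write.csv(format_guidelines(guidelines),
              file.path(outdir, "guidelines.csv"), row.names = FALSE)
    add("guidelines.csv")
  }
  if (!is.null(ld)) {
    write_level_diagram(ld, file.path(outdir, "ld.csv"))
    add("ld.csv")
  }
  if (!is.null(sweep)) {
    write.csv(as.data.frame(sweep), file.path(outdir, "sweep.csv"),
              row.names = FALSE)
    add("sweep.csv")
  }
  if (!is.null(load_cmp)) {
    write.csv(as.data.frame(load_cmp), file.path(outdir, "load.csv"),
              row.names = FALSE)
    add("load.csv")
  }
  save_run_config(cfg, file.path(outdir, "config.yaml"))
  add("config.yaml")
  manifest <- list(schema = SCHEMA_VERSION, seed = cfg$seed,
                   config_hash = config_hash(cfg), files = files)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
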