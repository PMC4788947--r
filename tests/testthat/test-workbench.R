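test_that("an empty config file yields all published defaults", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", f)
  cfg <- load_run_config(f)
  p <- do.call(circuit_parameters, cfg$parameters)
  expect_equal(p$kd, 0.06)
  expect_equal(p$dmB, 0.3624)
  expect_equal(cfg$moo$max_evals, 15000)
  expect_equal(cfg$box$J1, c(1e-3, 200))
  expect_equal(cfg$load$LT, 800)
})

test_that("malformed configs produce descriptive errors", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("bounds:\n  dB: [0.3, 0.01]", f)
  expect_error(load_run_config(f), "dB")
  writeLines("nonesuch: 1", f)
  expect_error(load_run_config(f), "unknown key")
  writeLines("moo:\n  warp: 9", f)
  expect_error(load_run_config(f), "warp")
  expect_error(load_run_config(tempfile()), "no such file")
})

test_that("configs round-trip through YAML", {
  cfg <- default_run_config()
  cfg$seed <- 42L
  cfg$moo$max_evals <- 2000
  f <- withr::local_tempfile(fileext = ".yaml")
  save_run_config(cfg, f)
  back <- load_run_config(f)
  expect_equal(back$moo, cfg$moo)
  expect_equal(back$seed, cfg$seed)
  expect_equal(back$bounds, cfg$bounds)
  expect_equal(config_hash(back), config_hash(cfg))
})

test_that("the config hash reacts to any setting change", {
  a <- default_run_config()
  b <- a
  b$moo$F <- 0.6
  c <- a
  c$seed <- 2L
  expect_false(config_hash(a) == config_hash(b))
  expect_false(config_hash(a) == config_hash(c))
  expect_equal(config_hash(a), config_hash(default_run_config()))
})

test_that("pareto fronts round-trip through CSV to machine precision", {
  pa <- cached_small_pareto()
  f <- withr::local_tempfile(fileext = ".csv")
  write_pareto(pa, f)
  back <- read_pareto(f)
  expect_equal(back$J, pa$J, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$theta, pa$theta, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$seed, pa$seed)
})

test_that("the manifest enumerates every written artifact", {
  pa <- cached_small_pareto()
  run_dir <- withr::local_tempdir()
  cfg <- default_run_config()
  m <- persist_results(run_dir, cfg, pareto = pa,
                       ld = level_diagram(pa))
  expect_setequal(m$files, c("pareto.csv", "pareto.json", "ld.csv",
                             "config.yaml"))
  expect_true(all(file.exists(file.path(run_dir, m$files))))
  expect_equal(m$config_hash, config_hash(cfg))
  written <- jsonlite::read_json(file.path(run_dir, "manifest.json"),
                                 simplifyVector = TRUE)
  expect_equal(sort(written$files), sort(m$files))
})

test_that("SBML export has the ten model variables and the model math", {
  f <- withr::local_tempfile(fileext = ".xml")
  p <- expand_decision(reference_theta())
  export_sbml(p, f)
  x <- xml2::read_xml(f)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(x), d1 = "s")
  species <- xml2::xml_find_all(x, ".//s:species", ns)
  expect_length(species, 10)
  expect_setequal(xml2::xml_attr(species, "id"),
                  c(paste0("x", 1:9), "M"))
  rules <- xml2::xml_find_all(x, ".//s:rateRule", ns)
  expect_length(rules, 9)
  expect_length(xml2::xml_find_all(x, ".//s:assignmentRule", ns), 1)
  # parameter values match the expanded decision vector
  pars <- xml2::xml_find_all(x, ".//s:parameter", ns)
  vals <- setNames(as.numeric(xml2::xml_attr(pars, "value")),
                   xml2::xml_attr(pars, "id"))
  expect_equal(vals[["dB"]], p$dB)
  expect_equal(vals[["Kcells"]], 2.4e-4)
  expect_error(export_sbml(p, file.path(tempdir(), "no", "dir", "x.xml")),
               "cannot write")
})

test_that("fixtures are deterministic in their seed", {
  a <- make_fixture(fixture_spec("planted_clusters", seed = 4))
  b <- make_fixture(fixture_spec("planted_clusters", seed = 4))
  c <- make_fixture(fixture_spec("planted_clusters", seed = 5))
  expect_identical(a, b)
  expect_false(identical(a$J, c$J))
  # analytic benchmark front: f1 = 1 -> f2 = 1
  bench <- make_fixture(fixture_spec("benchmark"))
  expect_equal(bench$front(1), 1)
  expect_equal(bench$front(4), 0)
})

test_that("the CLI dispatches, logs, and signals errors by status", {
  run_dir <- withr::local_tempdir()
  status <- suppressMessages(mood_main(c("export-sbml", "--out", run_dir)))
  expect_equal(status, 0L)
  expect_true(file.exists(file.path(run_dir, "i1ffl.xml")))
  expect_true(file.exists(file.path(run_dir, "run.log")))
  expect_equal(suppressMessages(mood_main(c("frobnicate"))), 1L)
  expect_equal(suppressMessages(
    mood_main(c("sweep", "--out", run_dir))), 1L)  # missing --parameter
})
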