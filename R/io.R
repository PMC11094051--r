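# Readers, writers, run configuration, and the top-level experiment runner.
# CSV dialect throughout: comma-separated, UTF-8, "." decimal, explicit
# header. Counts are serialized in a single `count_or_X` column ("X" marks
# presence-only records).

#' Write checklists to CSV
#'
#' Columns: survey_id, x_m, y_m, jday, min_since_dawn, duration_min,
#' protocol, location_type, observer_id, complete, count_or_X.
#'
#' @param checklists checklist data.frame.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_checklists <- function(checklists, path) {
  out <- checklists[, setdiff(checklist_columns, c("count", "presence_x"))]
  out$count_or_X <- ifelse(checklists$presence_x, "X",
                           as.character(checklists$count))
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read checklists from CSV
#'
#' Validates the documented column dictionary, parses `count_or_X` ("X"
#' becomes a presence-only flag), and enforces row invariants (positive
#' duration, non-negative counts) with row numbers in error messages.
#'
#' @param path CSV file written by [write_checklists()] or matching its
#'   dictionary.
#' @return checklist data.frame.
#' @export
read_checklists <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: %s", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c(setdiff(checklist_columns, c("count", "presence_x")), "count_or_X")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop_invalid("checklist file lacks columns: %s", paste(missing, collapse = ", "))
  cx <- trimws(as.character(raw$count_or_X))
  is_x <- toupper(cx) == "X"
  count <- suppressWarnings(as.integer(cx))
  bad <- !is_x & (is.na(count) | count < 0)
  if (any(bad))
    stop_invalid("unparseable or negative count in row(s): %s",
                 paste(head(which(bad), 5), collapse = ", "))
  if (any(raw$duration_min <= 0))
    stop_invalid("non-positive duration in row(s): %s",
                 paste(head(which(raw$duration_min <= 0), 5), collapse = ", "))
  raw$count <- ifelse(is_x, NA_integer_, count)
  raw$presence_x <- is_x
  raw$complete <- as.logical(raw$complete)
  raw[, checklist_columns]
}

#' Write individual detection records to CSV
#' @param detections data.frame (`survey_id`, `removal_interval`,
#'   `distance_bin`).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_detections <- function(detections, path) {
  write.csv(detections[, c("survey_id", "removal_interval", "distance_bin")],
            path, row.names = FALSE)
  invisible(path)
}

#' Read individual detection records from CSV
#' @param path CSV file.
#' @return detections data.frame.
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: %s", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("survey_id", "removal_interval", "distance_bin")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop_invalid("detections file lacks columns: %s", paste(missing, collapse = ", "))
  d
}

#' Serialize a landscape (gridded CSV plus JSON sidecar)
#'
#' The CSV holds one row per cell with the raw standardized layers; the
#' sidecar records grid dimensions, cell size, covariate names, and focal
#' radii. Focal means are recomputed on read.
#'
#' @param landscape a `landscape`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return the path, invisibly.
#' @export
write_landscape <- function(landscape, path) {
  tab <- covariate_table(landscape)
  write.csv(tab[, c("cell_id", landscape$covariate_names)], path,
            row.names = FALSE)
  jsonlite::write_json(list(n_x = landscape$n_x, n_y = landscape$n_y,
                            cell_m = landscape$cell_m,
                            covariate_names = landscape$covariate_names,
                            radii_m = landscape$radii_m),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a landscape written by [write_landscape()]
#' @param path CSV path (expects `<path>.json` sidecar).
#' @return a `landscape` with focal means recomputed.
#' @export
read_landscape <- function(path) {
  if (!file.exists(path) || !file.exists(paste0(path, ".json")))
    stop_invalid("landscape file or sidecar missing at %s", path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tab <- read.csv(path)
  raw <- lapply(setNames(meta$covariate_names, meta$covariate_names),
                function(nm) matrix(tab[[nm]], meta$n_x, meta$n_y))
  focal <- lapply(raw, function(m) {
    lapply(setNames(meta$radii_m, paste0("f", meta$radii_m)),
           function(r) focal_mean(m, r, meta$cell_m))
  })
  structure(list(n_x = meta$n_x, n_y = meta$n_y, cell_m = meta$cell_m,
                 cell_area_ha = (meta$cell_m / 100)^2,
                 radii_m = meta$radii_m,
                 covariate_names = meta$covariate_names,
                 raw = raw, focal = focal),
            class = "landscape")
}

## ---- run configuration -----------------------------------------------------

default_run_config <- function() {
  list(scenario = "common", framework = "benchmark", n_occ = 30,
       pooling = FALSE, iterations = 10, seed = 1, radius_m = 200,
       grid_m = 200, learner = "glmnet", tree_range = c(1000, 5000),
       depth = 3, bag_fraction = 0.75, nfolds = 10,
       out_dir = "results", log_level = "info")
}

#' Validate (and complete) a run configuration
#'
#' Checks the configuration against the schema before any computation or
#' I/O: known scenario and framework names, valid calibration size,
#' positive iterations and seed, known learner type.
#'
#' @param config named list of settings; missing entries take defaults.
#' @return the completed configuration list.
#' @export
validate_run_config <- function(config) {
  cfg <- utils::modifyList(default_run_config(), config)
  frameworks <- c("benchmark", "fixed", "independent", "calibration")
  if (!cfg$framework %in% frameworks)
    stop_invalid("unknown framework `%s` (expected one of %s)",
                 cfg$framework, paste(frameworks, collapse = ", "))
  scenarios <- c("common", "uncommon", "rare", "aurally_cryptic", "homogeneous")
  if (!cfg$scenario %in% scenarios)
    stop_invalid("unknown scenario `%s`", cfg$scenario)
  if (cfg$framework == "calibration") {
    assert_scalar_number(cfg$n_occ, "n_occ", positive = TRUE)
    if (!is.logical(cfg$pooling)) stop_invalid("pooling must be TRUE/FALSE")
  }
  assert_scalar_number(cfg$iterations, "iterations", positive = TRUE)
  assert_scalar_number(cfg$seed, "seed")
  if (!cfg$learner %in% c("glmnet", "xgboost"))
    stop_invalid("unknown learner `%s`", cfg$learner)
  cfg
}

#' Read a YAML run configuration
#' @param path YAML file whose keys mirror [validate_run_config()].
#' @return validated configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_invalid("no such config file: %s", path)
  validate_run_config(yaml::read_yaml(path))
}

log_msg <- function(cfg, fmt, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[densitycal] %s", sprintf(fmt, ...)))
}

#' Run a configured experiment and write result artifacts
#'
#' Generates the configured scenario, filters and geographically samples
#' the community data, builds the benchmark split, runs the configured
#' framework, and writes `results.csv` (one row per iteration),
#' `summary.json` (endpoint medians), and `manifest.json` (configuration,
#' seed, package version, config hash) into the output directory. With the
#' deterministic fallback learner, rerunning the same configuration and
#' seed reproduces the artifacts bit-for-bit.
#'
#' @param config named list (see [validate_run_config()]) or a YAML path.
#' @return invisibly, a list with `results` and the artifact paths.
#' @export
run_experiment <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config)
  else validate_run_config(config)
  lc <- learner_config(type = cfg$learner, depth = cfg$depth,
                       bag_fraction = cfg$bag_fraction,
                       tree_range = cfg$tree_range, nfolds = cfg$nfolds)
  seeds <- child_seeds(cfg$seed, 3L)

  log_msg(cfg, "scenario `%s` (seed %d)", cfg$scenario, seeds[1])
  t0 <- Sys.time()
  scen <- make_fixture_scenario(cfg$scenario, seed = seeds[1])
  cs <- scenario_community_filtered(scen, seed = seeds[2])
  split <- make_benchmark_dataset(scen$structured,
                                  n_match = min(nrow(cs),
                                                nrow(scen$structured$checklists)),
                                  seed = seeds[2])
  log_msg(cfg, "data ready in %.1fs: %d community, %d benchmark, %d test",
          as.numeric(Sys.time() - t0, units = "secs"), nrow(cs),
          nrow(split$benchmark$checklists), nrow(split$test$checklists))

  t1 <- Sys.time()
  results <- switch(cfg$framework,
    benchmark = run_benchmark(split$benchmark, split$test, scen$landscape,
                              lc, seeds[3], cfg$iterations),
    fixed = run_fixed(cs, split$test, scen$landscape, cfg$radius_m,
                      lc, seeds[3], cfg$iterations),
    independent = run_independent(cs, scen$structured, split$test,
                                  scen$landscape, lc, seeds[3],
                                  cfg$iterations),
    calibration = run_calibration(cs, split$benchmark, split$test,
                                  scen$landscape, cfg$n_occ, cfg$pooling,
                                  lc, seeds[3], cfg$iterations))
  log_msg(cfg, "%s framework: %d iterations in %.1fs", cfg$framework,
          cfg$iterations, as.numeric(Sys.time() - t1, units = "secs"))

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  results_path <- file.path(cfg$out_dir, "results.csv")
  write.csv(results, results_path, row.names = FALSE)
  medians <- lapply(setNames(endpoint_names, endpoint_names),
                    function(ep) median(results[[ep]], na.rm = TRUE))
  summary_path <- file.path(cfg$out_dir, "summary.json")
  jsonlite::write_json(c(list(framework = cfg$framework,
                              iterations = cfg$iterations), medians),
                       summary_path, auto_unbox = TRUE, digits = NA)
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(list(config = cfg,
                            config_md5 = unname(tools::md5sum(tmp)),
                            package_version = as.character(packageVersion("densitycal")),
                            true_population = scen$truth$population),
                       manifest_path, auto_unbox = TRUE, digits = NA)
  unlink(tmp)
  invisible(list(results = results, scenario = scen,
                 paths = c(results = results_path, summary = summary_path,
                           manifest = manifest_path)))
}

#' Compare saved framework results against saved benchmark results
#'
#' Reads two `results.csv` files written by [run_experiment()] and writes
#' the percent-of-benchmark summary.
#'
#' @param framework_csv,benchmark_csv paths to results files.
#' @param out_json optional path for the JSON summary.
#' @return the `framework_comparison`, invisibly.
#' @export
compare_result_files <- function(framework_csv, benchmark_csv,
                                 out_json = NULL) {
  fr <- read.csv(framework_csv)
  br <- read.csv(benchmark_csv)
  cmp <- compare(fr, br)
  if (!is.null(out_json))
    jsonlite::write_json(cmp$summary, out_json, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  invisible(cmp)
}
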