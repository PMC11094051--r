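# Framework orchestration. All four analyses share the zero-inflated
# pipeline (occurrence stage -> prevalence threshold -> detection models
# within suitable habitat -> offset-adjusted count stage); they differ only
# in which data inform each stage:
#   benchmark    structured data end to end (best practices),
#   fixed        community data, constant pi r^2 offsets, perfect detection,
#   independent  community data, offsets from the full structured dataset,
#   calibration  community data, offsets from a small resampled structured
#                subset, optionally pooled into the training data.

endpoint_names <- c("auc", "suitable_area_ha", "mean_density", "population")

#' Split structured surveys into a benchmark set and an independent test set
#'
#' Uniform sample without replacement of `n_match` surveys (matching the
#' community dataset size); the remainder becomes the independent test set
#' used for AUC and predictive correlation.
#'
#' @param structured structured survey bundle: list with `checklists` and
#'   `detections`.
#' @param n_match benchmark size; at most the number of structured surveys.
#' @param seed integer seed.
#' @return list with `benchmark` and `test`, each a list of `checklists`
#'   and `detections`.
#' @export
make_benchmark_dataset <- function(structured, n_match, seed = 1) {
  cl <- structured$checklists
  if (n_match > nrow(cl))
    stop_invalid("n_match (%d) exceeds available structured surveys (%d)",
                 n_match, nrow(cl))
  if (n_match == nrow(cl))
    warning("n_match equals the number of structured surveys; test set is empty")
  take <- withr::with_seed(as.integer(seed),
                           sample.int(nrow(cl), n_match, replace = FALSE))
  split_det <- function(ids) structured$detections[
    structured$detections$survey_id %in% ids, , drop = FALSE]
  bench_cl <- cl[sort(take), , drop = FALSE]
  test_cl <- cl[-take, , drop = FALSE]
  list(benchmark = list(checklists = bench_cl,
                        detections = split_det(bench_cl$survey_id)),
       test = list(checklists = test_cl,
                   detections = split_det(test_cl$survey_id)))
}

#' Sample a calibration dataset from the benchmark set
#'
#' Shuffles the benchmark surveys uniformly and takes them in order until
#' exactly `n_occ` surveys with at least one detection have accumulated;
#' the negatives drawn en route are kept (they carry environmental
#' variation into the detection models).
#'
#' @param benchmark_checklists benchmark survey checklists.
#' @param n_occ required number of surveys with >= 1 detection.
#' @param seed integer seed.
#' @return the calibration subset of the checklists.
#' @export
sample_calibration <- function(benchmark_checklists, n_occ, seed = 1) {
  assert_scalar_number(n_occ, "n_occ", positive = TRUE)
  pos <- benchmark_checklists$count > 0
  if (sum(pos) < n_occ)
    stop_infeasible(
      "calibration size %d infeasible: only %d surveys with detections available",
      n_occ, sum(pos))
  ord <- withr::with_seed(as.integer(seed),
                          sample.int(nrow(benchmark_checklists)))
  stop_at <- which(cumsum(pos[ord]) == n_occ)[1L]
  benchmark_checklists[sort(ord[seq_len(stop_at)]), , drop = FALSE]
}

# Fit detection models on `det` (checklists + detections) restricted to the
# suitable mask, falling back to the unrestricted set if no survey lies in
# suitable habitat. Returns top removal and distance models.
fit_detection_models <- function(det, mask, landscape, seed,
                                 min_detections = 20) {
  keep <- in_suitable(det$checklists, mask, landscape)
  cl <- det$checklists[keep, , drop = FALSE]
  dd <- det$detections[det$detections$survey_id %in% cl$survey_id, , drop = FALSE]
  if (nrow(dd) < min_detections &&
      nrow(det$detections) > nrow(dd)) {
    # detection probability is not suitability-dependent, so when the
    # mask-restricted subset is too sparse to identify the detection
    # parameters we borrow the full survey set
    if (!any(keep))
      warning("no detection surveys in suitable habitat; using the full set")
    cl <- det$checklists
    dd <- det$detections
  }
  if (!nrow(dd))
    stop_estimation("detection stage: no individual detections available")
  am <- fit_removal_set(removal_data(dd, cl), seed = seed)[[1L]]
  pm <- fit_distance_set(distance_data(dd, cl, landscape), seed = seed)[[1L]]
  list(availability = am, perceptibility = pm)
}

wrap_stage <- function(stage, expr) {
  withCallingHandlers(
    tryCatch(expr, error = function(e) {
      stop(errorCondition(sprintf("[%s stage] %s", stage, conditionMessage(e)),
                          class = class(e)))
    }),
    warning = function(w) {
      # keep stage context on undefined-result signals, then continue
      if (inherits(w, "densitycal_undefined_result")) {
        message(sprintf("[%s stage] %s", stage, conditionMessage(w)))
      }
    })
}

# One zero-inflated iteration shared by all frameworks.
zi_iteration <- function(train, test, landscape, detection, config, seed) {
  seeds <- child_seeds(seed, 3L)
  occ <- wrap_stage("occurrence",
                    fit_occurrence(train, test$checklists, landscape, config,
                                   seed = seeds[1]))
  mask <- threshold_by_prevalence(occ, landscape)

  offsets_for <- if (detection$mode == "fixed") {
    function(cl) fixed_offsets(cl, radius_m = detection$radius)
  } else {
    models <- wrap_stage("detection",
                         fit_detection_models(detection$data, mask, landscape,
                                              seed = seeds[2]))
    function(cl) compute_offsets(cl, models$availability,
                                 models$perceptibility, landscape)
  }

  count_train <- train[in_suitable(train, mask, landscape) &
                         !is.na(train$count), , drop = FALSE]
  if (!nrow(count_train))
    stop_estimation("[count stage] no training surveys in suitable habitat")
  offs <- wrap_stage("offset", offsets_for(count_train))
  dfit <- wrap_stage("count",
                     fit_density(count_train, offs, mask, landscape, config,
                                 seed = seeds[3]))
  pred_r <- NA_real_
  if (!is.null(test) && nrow(test$checklists)) {
    toffs <- offsets_for(test$checklists)
    pred_r <- predictive_correlation(dfit, test$checklists, toffs, landscape)
  }

  res <- data.frame(auc = occ$auc, suitable_area_ha = mask$area_ha,
                    mean_density = dfit$mean_density,
                    population = dfit$population,
                    predictive_r = pred_r,
                    median_C = median(offs$C),
                    n_count_train = nrow(count_train))
  bad <- !is.finite(unlist(res[endpoint_names[-1]])) |
    unlist(res[endpoint_names[-1]]) < 0
  if (any(bad)) stop_estimation("non-finite or negative endpoint produced")
  res
}

run_framework <- function(framework, train_fun, detection_fun, test,
                          landscape, config, seed, iterations) {
  seeds <- child_seeds(seed, iterations)
  rows <- lapply(seq_len(iterations), function(i) {
    it_seeds <- child_seeds(seeds[i], 2L)
    train <- train_fun(it_seeds[1])
    detection <- detection_fun(it_seeds[1])
    cbind(data.frame(framework = framework, iteration = i),
          zi_iteration(train, test, landscape, detection, config,
                       seed = it_seeds[2]))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("iteration_results", class(out))
  out
}

#' Run the structured-data benchmark analysis
#'
#' Best-practices pipeline on the benchmark structured surveys: occurrence
#' stage and prevalence threshold from benchmark data, detection models fit
#' on benchmark surveys within suitable habitat, offsets for the benchmark
#' surveys (5-min counts), offset-adjusted count stage.
#'
#' @param benchmark benchmark bundle from [make_benchmark_dataset()].
#' @param test independent test bundle.
#' @param landscape the `landscape`.
#' @param config a [learner_config()].
#' @param seed master seed; per-iteration child seeds are derived from it.
#' @param iterations number of iterations (default 10).
#' @return an `iteration_results` data.frame (one row per iteration).
#' @export
run_benchmark <- function(benchmark, test, landscape,
                          config = learner_config(), seed = 1,
                          iterations = 10) {
  if (!nrow(benchmark$detections))
    stop_invalid("benchmark set has no removal/distance records")
  run_framework("benchmark",
                function(s) benchmark$checklists,
                function(s) list(mode = "fit", data = benchmark),
                test, landscape, config, seed, iterations)
}

#' Run the Fixed framework
#'
#' Community counts are converted to densities with a constant assumed
#' survey radius and perfect detection: every offset is `pi radius^2`
#' (about 12.566 ha at the default 200 m) with `p = q = 1`. No structured
#' data enter.
#'
#' @param cs filtered community checklists.
#' @param test independent structured test bundle.
#' @param radius_m assumed survey radius (m), default 200.
#' @inheritParams run_benchmark
#' @return an `iteration_results` data.frame.
#' @export
run_fixed <- function(cs, test, landscape, radius_m = 200,
                      config = learner_config(), seed = 1, iterations = 10) {
  run_framework("fixed",
                function(s) cs,
                function(s) list(mode = "fixed", radius = radius_m),
                test, landscape, config, seed, iterations)
}

#' Run the Independent framework
#'
#' Occurrence and count stages use community data only; detection models
#' are fit per iteration on the complete structured dataset restricted to
#' that iteration's suitable habitat, and the resulting offsets are applied
#' to the community surveys at their own durations and covariates.
#'
#' @param cs filtered community checklists.
#' @param structured_full the complete structured bundle (checklists +
#'   detections).
#' @inheritParams run_benchmark
#' @return an `iteration_results` data.frame.
#' @export
run_independent <- function(cs, structured_full, test, landscape,
                            config = learner_config(), seed = 1,
                            iterations = 10) {
  if (is.null(structured_full$checklists) || !nrow(structured_full$checklists))
    stop_invalid("Independent framework requires a non-empty structured dataset")
  if (!nrow(structured_full$detections))
    stop_invalid("Independent framework requires structured detection records")
  run_framework("independent",
                function(s) cs,
                function(s) list(mode = "fit", data = structured_full),
                test, landscape, config, seed, iterations)
}

#' Run the Calibration framework
#'
#' Per iteration, a fresh calibration dataset is drawn from the benchmark
#' set ([sample_calibration()]); detection models are fit on it within the
#' iteration's suitable habitat. With `pooling`, the calibration surveys
#' (carrying their own offsets) join the community data in both the
#' occurrence and count stages; without pooling they inform only the
#' detection models.
#'
#' @param cs filtered community checklists.
#' @param benchmark benchmark bundle the calibration sets are drawn from.
#' @param n_occ calibration size: required surveys with >= 1 detection
#'   (10, 30, 100, or 250 in the standard design).
#' @param pooling logical; pool calibration surveys into the density model.
#' @inheritParams run_benchmark
#' @return an `iteration_results` data.frame.
#' @export
run_calibration <- function(cs, benchmark, test, landscape, n_occ,
                            pooling = FALSE, config = learner_config(),
                            seed = 1, iterations = 10) {
  run_framework(
    sprintf("calibration_%d%s", n_occ, if (pooling) "_pooled" else ""),
    train_fun = function(s) {
      cal <- sample_calibration(benchmark$checklists, n_occ, seed = s)
      if (pooling) rbind(cs, cal) else cs
    },
    detection_fun = function(s) {
      cal <- sample_calibration(benchmark$checklists, n_occ, seed = s)
      det <- benchmark$detections[
        benchmark$detections$survey_id %in% cal$survey_id, , drop = FALSE]
      list(mode = "fit", data = list(checklists = cal, detections = det))
    },
    test, landscape, config, seed, iterations)
}

#' Percent-of-benchmark comparison
#'
#' For each endpoint (AUC, suitable area, mean density, population) the
#' benchmark value is the median over the benchmark's iterations; every
#' framework iteration is converted to `100 x estimate / benchmark median`
#' and the median percent is reported.
#'
#' @param framework_results `iteration_results` from a framework run.
#' @param benchmark_results `iteration_results` from [run_benchmark()].
#' @return a `framework_comparison`: `summary` (per endpoint: benchmark
#'   median, median percent) and `percents` (per iteration x endpoint).
#' @export
compare <- function(framework_results, benchmark_results) {
  if (!nrow(framework_results) || !nrow(benchmark_results))
    stop_invalid("both result sets must be non-empty")
  summary_rows <- list()
  percent_rows <- list()
  for (ep in endpoint_names) {
    bench_med <- median(benchmark_results[[ep]], na.rm = TRUE)
    if (is.na(bench_med) || bench_med == 0) {
      pct <- rep(signal_undefined(
        "benchmark median for `%s` is zero or undefined", ep),
        nrow(framework_results))
    } else {
      pct <- 100 * framework_results[[ep]] / bench_med
    }
    summary_rows[[ep]] <- data.frame(endpoint = ep,
                                     benchmark_median = bench_med,
                                     median_percent = median(pct, na.rm = FALSE))
    percent_rows[[ep]] <- data.frame(
      iteration = framework_results$iteration, endpoint = ep, percent = pct)
  }
  structure(list(summary = do.call(rbind, summary_rows),
                 percents = do.call(rbind, percent_rows)),
            class = "framework_comparison")
}

#' @export
print.framework_comparison <- function(x, ...) {
  cat("percent-of-benchmark summary:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
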