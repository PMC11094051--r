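# Survey simulation. A present bird is detected on a point count iff (a) it
# first gives a cue within the count duration (first-cue time exponential
# with the availability rate phi) and (b) a single Bernoulli perceptibility
# trial at its distance r succeeds, with half-normal probability
# g(r) = exp(-r^2 / tau^2). Availability and perceptibility are independent
# given distance, matching the removal + distance estimators fitted later.

DEFAULT_BIN_EDGES <- c(0, 50, 100, 150, 200, Inf)

checklist_columns <- c("survey_id", "x_m", "y_m", "jday", "min_since_dawn",
                       "duration_min", "protocol", "location_type",
                       "observer_id", "complete", "count", "presence_x")

empty_checklists <- function() {
  data.frame(survey_id = character(0), x_m = numeric(0), y_m = numeric(0),
             jday = numeric(0), min_since_dawn = numeric(0),
             duration_min = numeric(0), protocol = character(0),
             location_type = character(0), observer_id = character(0),
             complete = logical(0), count = integer(0),
             presence_x = logical(0))
}

# Bernoulli detection outcomes for all birds audible from a point.
# Returns first-cue time and exact distance of each detected bird.
detect_from_point <- function(x_m, y_m, birds, phi, tau, duration) {
  r_max <- 4 * tau
  dx <- birds$x_m - x_m; dy <- birds$y_m - y_m
  r2 <- dx * dx + dy * dy
  near <- which(r2 <= r_max^2)
  if (!length(near))
    return(data.frame(r_m = numeric(0), t_first = numeric(0)))
  r <- sqrt(r2[near])
  t_first <- rexp(length(near), rate = phi)
  perceived <- runif(length(near)) < exp(-(r / tau)^2)
  det <- t_first <= duration & perceived
  data.frame(r_m = r[det], t_first = t_first[det])
}

#' Simulate one structured point count
#'
#' Five-minute (by default) stationary count with a time-of-detection
#' (removal) history over `n_intervals` equal intervals and distance-band
#' records with an unbounded last band.
#'
#' @param landscape a `landscape`.
#' @param birds realized bird locations from [generate_population()].
#' @param truth the `species_truth`.
#' @param x_m,y_m survey location (meters).
#' @param jday Julian day of the survey.
#' @param tod minutes since nautical dawn.
#' @param duration count duration in minutes (> 0).
#' @param n_intervals number of equal removal intervals.
#' @param bin_edges strictly increasing distance-bin edges (m), last `Inf`.
#' @param seed integer seed.
#' @param survey_id identifier for the output records.
#' @return list with `checklist` (one-row data.frame) and `detections`
#'   (one row per detected individual: `survey_id`, `removal_interval`,
#'   `distance_bin`, `r_m` exact distance kept for diagnostics only).
#' @export
simulate_structured_survey <- function(landscape, birds, truth, x_m, y_m,
                                       jday, tod, duration = 5,
                                       n_intervals = 5,
                                       bin_edges = DEFAULT_BIN_EDGES,
                                       seed = 1, survey_id = "s1") {
  assert_scalar_number(duration, "duration", positive = TRUE)
  if (any(diff(bin_edges) <= 0) || !is.infinite(bin_edges[length(bin_edges)]))
    stop_invalid("bin_edges must be strictly increasing with an infinite last edge")
  phi <- true_phi(truth, jday, tod)
  tau <- true_tau(truth, landscape, x_m, y_m)
  det <- withr::with_seed(as.integer(seed),
                          detect_from_point(x_m, y_m, birds, phi, tau, duration))
  interval <- ceiling(det$t_first / (duration / n_intervals))
  bin <- findInterval(det$r_m, bin_edges, left.open = FALSE)
  checklist <- data.frame(
    survey_id = survey_id, x_m = x_m, y_m = y_m, jday = jday,
    min_since_dawn = tod, duration_min = duration, protocol = "stationary",
    location_type = "personal", observer_id = "structured", complete = TRUE,
    count = nrow(det), presence_x = FALSE
  )
  detections <- data.frame(
    survey_id = rep(survey_id, nrow(det)),
    removal_interval = as.integer(interval),
    distance_bin = as.integer(bin),
    r_m = det$r_m
  )
  list(checklist = checklist, detections = detections)
}

#' Simulate a set of structured surveys at random locations
#'
#' Survey points are uniform over the landscape inset by `buffer_m` (so the
#' audible disc stays inside the simulated bird population); dates are
#' uniform over the breeding season (Julian day 120-190) and start times
#' over the 0-420 min post-dawn window.
#'
#' @inheritParams simulate_structured_survey
#' @param n_surveys number of counts.
#' @param buffer_m inset from the landscape edge for survey placement.
#' @param id_prefix prefix for survey ids.
#' @return list with `checklists` and `detections` data.frames.
#' @export
simulate_structured_surveys <- function(landscape, birds, truth, n_surveys,
                                        duration = 5, n_intervals = 5,
                                        bin_edges = DEFAULT_BIN_EDGES,
                                        buffer_m = 300, seed = 1,
                                        id_prefix = "str") {
  assert_scalar_number(n_surveys, "n_surveys", positive = TRUE)
  ext_x <- landscape$n_x * landscape$cell_m
  ext_y <- landscape$n_y * landscape$cell_m
  if (2 * buffer_m >= min(ext_x, ext_y))
    stop_invalid("buffer_m too large for this landscape")
  seeds <- child_seeds(seed, n_surveys + 1L)
  pts <- withr::with_seed(seeds[1L], data.frame(
    x_m = runif(n_surveys, buffer_m, ext_x - buffer_m),
    y_m = runif(n_surveys, buffer_m, ext_y - buffer_m),
    jday = round(runif(n_surveys, 120, 190)),
    tod = round(runif(n_surveys, 0, 420))
  ))
  out <- lapply(seq_len(n_surveys), function(i) {
    simulate_structured_survey(landscape, birds, truth,
                               pts$x_m[i], pts$y_m[i], pts$jday[i], pts$tod[i],
                               duration, n_intervals, bin_edges,
                               seed = seeds[i + 1L],
                               survey_id = sprintf("%s%04d", id_prefix, i))
  })
  list(checklists = do.call(rbind, lapply(out, `[[`, "checklist")),
       detections = do.call(rbind, lapply(out, `[[`, "detections")))
}

#' Simulate opportunistic community checklists
#'
#' Checklist locations are a mixture of hotspot clusters and uniform
#' background; effort, protocol, and completeness vary as in raw community
#' data. Detection follows the structured mechanism with the observer's
#' `kappa` shrinking the perceptibility scale, binomial count thinning, and
#' presence-only "X" substitution; no removal or distance records are kept
#' (community data lack them).
#'
#' @inheritParams simulate_structured_surveys
#' @param observers non-empty list of [observer_profile()] objects.
#' @param n_checklists number of checklists to generate.
#' @param hotspot_fraction fraction of checklists clustered at hotspots.
#' @param n_hotspots number of hotspot centers.
#' @param duration_range min/max checklist duration (minutes).
#' @param p_stationary,p_traveling probabilities of those protocols (the
#'   remainder is incidental).
#' @param p_hotspot_label probability a clustered checklist is tagged with
#'   the hotspot location type (others are personal locations).
#' @param p_complete probability a checklist is complete.
#' @return data.frame of checklists (see [simulate_structured_survey()]
#'   for columns); `count` is `NA` where `presence_x` is `TRUE`.
#' @export
simulate_community_checklists <- function(landscape, birds, truth, observers,
                                          n_checklists, hotspot_fraction = 0.35,
                                          n_hotspots = 6,
                                          duration_range = c(3, 30),
                                          buffer_m = 300, seed = 1,
                                          p_stationary = 0.65,
                                          p_traveling = 0.25,
                                          p_hotspot_label = 0.5,
                                          p_complete = 0.95) {
  if (!length(observers)) stop_invalid("observers must be non-empty")
  if (hotspot_fraction < 0 || hotspot_fraction > 1)
    stop_invalid("hotspot_fraction must be in [0, 1]")
  observers <- lapply(observers, function(o) {
    if (!inherits(o, "observer_profile")) stop_invalid("observers must be observer_profile objects")
    o
  })
  ext_x <- landscape$n_x * landscape$cell_m
  ext_y <- landscape$n_y * landscape$cell_m
  seeds <- child_seeds(seed, 2L)

  meta <- withr::with_seed(seeds[1L], {
    hx <- runif(n_hotspots, buffer_m, ext_x - buffer_m)
    hy <- runif(n_hotspots, buffer_m, ext_y - buffer_m)
    clustered <- runif(n_checklists) < hotspot_fraction
    h <- sample.int(n_hotspots, n_checklists, replace = TRUE)
    x <- runif(n_checklists, buffer_m, ext_x - buffer_m)
    y <- runif(n_checklists, buffer_m, ext_y - buffer_m)
    x[clustered] <- pmin(pmax(hx[h[clustered]] + rnorm(sum(clustered), 0, 120),
                              buffer_m), ext_x - buffer_m)
    y[clustered] <- pmin(pmax(hy[h[clustered]] + rnorm(sum(clustered), 0, 120),
                              buffer_m), ext_y - buffer_m)
    proto <- sample(c("stationary", "traveling", "incidental"), n_checklists,
                    replace = TRUE,
                    prob = c(p_stationary, p_traveling,
                             max(0, 1 - p_stationary - p_traveling)))
    loc <- ifelse(clustered & runif(n_checklists) < p_hotspot_label,
                  "hotspot", "personal")
    data.frame(
      x_m = x, y_m = y,
      jday = round(runif(n_checklists, 120, 190)),
      tod = round(runif(n_checklists, -60, 480)),
      duration = runif(n_checklists, duration_range[1L], duration_range[2L]),
      protocol = proto, location_type = loc,
      obs_idx = sample.int(length(observers), n_checklists, replace = TRUE),
      complete = runif(n_checklists) < p_complete
    )
  })

  det_seeds <- child_seeds(seeds[2L], n_checklists)
  rows <- lapply(seq_len(n_checklists), function(i) {
    ob <- observers[[meta$obs_idx[i]]]
    phi <- true_phi(truth, meta$jday[i], meta$tod[i])
    tau <- true_tau(truth, landscape, meta$x_m[i], meta$y_m[i]) * ob$kappa
    withr::with_seed(det_seeds[i], {
      det <- detect_from_point(meta$x_m[i], meta$y_m[i], birds, phi, tau,
                               meta$duration[i])
      n_det <- rbinom(1L, nrow(det), ob$thinning)
      as_x <- n_det > 0 && runif(1) < ob$x_prob
      data.frame(
        survey_id = sprintf("cs%04d", i),
        x_m = meta$x_m[i], y_m = meta$y_m[i], jday = meta$jday[i],
        min_since_dawn = meta$tod[i], duration_min = meta$duration[i],
        protocol = meta$protocol[i], location_type = meta$location_type[i],
        observer_id = ob$observer_id, complete = meta$complete[i],
        count = if (as_x) NA_integer_ else as.integer(n_det),
        presence_x = as_x
      )
    })
  })
  do.call(rbind, rows)
}
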