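# Detection models in the offset (QPAD-style) approach: a removal
# (time-of-detection) conditional multinomial estimates the availability
# rate phi; a binned distance-sampling conditional multinomial estimates the
# half-normal perceptibility scale tau. Both are log-linear in covariates,
# selected by AICc, and combined into per-survey correction factors
# C = (effective area) x (availability) x 1 that enter count models as
# log-offsets.

#' Removal-interval cell probabilities
#'
#' Probability that an individual first detected within the count is first
#' detected in interval j, for first-cue times exponential with rate `phi`:
#' `pi_j = (exp(-phi t_{j-1}) - exp(-phi t_j)) / (1 - exp(-phi t_J))`.
#'
#' @param phi availability (cue) rate per minute, > 0.
#' @param boundaries interval boundaries `t_0 = 0 < ... < t_J` (minutes).
#' @return probability vector of length J (sums to 1).
#' @export
removal_cell_probs <- function(phi, boundaries = 0:5) {
  assert_scalar_number(phi, "phi", positive = TRUE)
  if (any(diff(boundaries) <= 0)) stop_invalid("boundaries must be strictly increasing")
  e <- exp(-phi * boundaries)
  (e[-length(e)] - e[-1]) / (1 - e[length(e)])
}

#' Distance-band cell probabilities under a half-normal detection function
#'
#' For `g(r) = exp(-r^2/tau^2)` and an unbounded last band, the probability
#' a detected individual falls in band k is
#' `pi_k = exp(-r_{k-1}^2/tau^2) - exp(-r_k^2/tau^2)`, which equals the
#' integral of `2 pi r g(r)` over the band divided by `pi tau^2`.
#'
#' @param tau half-normal scale in meters, > 0.
#' @param bin_edges edges `r_0 = 0 < ... < r_K = Inf` (meters).
#' @return probability vector of length K (sums to 1).
#' @export
distance_cell_probs <- function(tau, bin_edges = DEFAULT_BIN_EDGES) {
  assert_scalar_number(tau, "tau", positive = TRUE)
  if (any(diff(bin_edges) <= 0) || !is.infinite(bin_edges[length(bin_edges)]))
    stop_invalid("bin_edges must be strictly increasing with an infinite last edge")
  e <- exp(-(bin_edges / tau)^2)
  e[is.infinite(bin_edges)] <- 0
  e[-length(e)] - e[-1]
}

#' Small-sample corrected AIC
#'
#' `AICc = -2 loglik + 2k + 2k(k+1)/(n-k-1)`, with `n` the number of
#' likelihood terms (detected individuals).
#'
#' @param loglik maximized log-likelihood.
#' @param k number of parameters.
#' @param n number of individuals.
#' @return AICc value.
#' @export
aicc <- function(loglik, k, n) {
  assert_scalar_number(loglik, "loglik")
  if (n <= k + 1) stop_invalid("AICc requires n > k + 1 (n = %d, k = %d)", n, k)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

## ---- design-matrix helpers ------------------------------------------------

# Availability covariates use fixed season/time scalings (see scale_jday,
# scale_tod) so no data-dependent centering needs to be stored.
removal_design <- function(data, terms) {
  js <- scale_jday(data$jday); ts <- scale_tod(data$tod)
  cols <- list(`(Intercept)` = rep(1, nrow(data)),
               jday = js, jday2 = js^2, tod = ts, tod2 = ts^2)
  do.call(cbind, cols[c("(Intercept)", terms)])
}

#' Default removal candidate model set
#'
#' The 9 combinations of Julian date and time of day with optional
#' quadratic terms per included linear term, plus the null.
#' @return named list of term vectors.
#' @export
removal_candidates_default <- function() {
  jf <- list(none = character(0), lin = "jday", quad = c("jday", "jday2"))
  tf <- list(none = character(0), lin = "tod", quad = c("tod", "tod2"))
  out <- list()
  for (jn in names(jf)) for (tn in names(tf)) {
    terms <- c(jf[[jn]], tf[[tn]])
    lbl <- if (!length(terms)) "null" else paste(terms, collapse = " + ")
    out[[lbl]] <- terms
  }
  out
}

# Distance covariates are standardized with training-data moments that are
# stored on the fitted model for prediction.
distance_scaling <- function(data, vars_log) {
  cols <- list()
  for (v in names(vars_log)) {
    x <- data[[v]]
    if (is.null(x)) stop_invalid("missing distance-model covariate `%s`", v)
    cols[[paste0(v, "_s")]] <- c(mean(x), max(sd(x), 1e-12))
    if (vars_log[[v]]) {
      if (any(x <= 0)) stop_invalid("`%s` must be positive for log forms", v)
      lx <- log(x)
      cols[[paste0(v, "_log")]] <- c(mean(lx), max(sd(lx), 1e-12))
    }
  }
  cols
}

distance_design <- function(data, terms, scaling) {
  n <- nrow(data)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (tm in terms) {
    base <- sub("2$", "", tm)
    raw_var <- sub("_(s|log)$", "", base)
    x <- data[[raw_var]]
    if (is.null(x)) stop_invalid("missing distance-model covariate `%s`", raw_var)
    sc <- scaling[[base]]
    v <- if (endsWith(base, "_log")) (log(x) - sc[1]) / sc[2] else (x - sc[1]) / sc[2]
    if (endsWith(tm, "2")) v <- v^2
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- tm
  }
  X
}

## ---- likelihoods ----------------------------------------------------------

removal_nll <- function(beta, X, j, boundaries) {
  phi <- exp(drop(X %*% beta))
  E <- exp(-outer(phi, boundaries))           # n x (J+1)
  pick <- (E[cbind(seq_along(j), j)] - E[cbind(seq_along(j), j + 1L)]) /
    (1 - E[, length(boundaries)])
  -sum(log(pmax(pick, 1e-300)))
}

distance_nll <- function(gamma, Z, k, bin_edges) {
  tau <- pmin(pmax(exp(drop(Z %*% gamma)), 1e-8), 1e8)
  E <- exp(-outer(1 / tau^2, bin_edges^2))    # n x (K+1)
  E[, bin_edges == 0] <- 1                    # guard Inf * 0 at the origin
  E[, is.infinite(bin_edges)] <- 0            # exp(-Inf) = 0
  pick <- E[cbind(seq_along(k), k)] - E[cbind(seq_along(k), k + 1L)]
  -sum(log(pmax(pick, 1e-300)))
}

# Quasi-Newton fit with seeded jittered restarts on failure.
fit_conditional_multinomial <- function(nll, start, seed = 1, max_retries = 3) {
  attempt <- function(par0) {
    tryCatch(optim(par0, nll, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-12)),
             error = function(e) NULL)
  }
  fit <- attempt(start)
  if (is.null(fit) || fit$convergence != 0) {
    jit_seeds <- child_seeds(seed, max_retries)
    for (s in jit_seeds) {
      par0 <- withr::with_seed(s, start + rnorm(length(start), 0, 0.5))
      fit2 <- attempt(par0)
      if (!is.null(fit2) && fit2$convergence == 0 &&
          (is.null(fit) || fit2$value < fit$value)) {
        fit <- fit2
        break
      }
      if (!is.null(fit2) && (is.null(fit) || fit2$value < fit$value)) fit <- fit2
    }
  }
  if (is.null(fit)) stop_estimation("detection-model optimization failed")
  fit
}

rank_by_aicc <- function(models) {
  models[order(vapply(models, `[[`, numeric(1), "aicc"))]
}

## ---- availability (removal) models ---------------------------------------

#' Fit the removal (availability) candidate model set
#'
#' Each candidate models `log phi` as linear in scaled Julian day and/or
#' time of day (with optional quadratics); the default set is the 9
#' combinations including the null. Models are fitted by maximizing the
#' conditional multinomial removal likelihood and ranked by AICc with `n` =
#' number of individuals.
#'
#' @param data data.frame with one row per detected individual: columns
#'   `interval` (1..J), `jday`, `tod`.
#' @param boundaries removal interval boundaries (minutes).
#' @param candidates named list of term vectors over
#'   `jday, jday2, tod, tod2`; default [removal_candidates_default()].
#' @param seed seed for optimizer restarts.
#' @return list of `availability_model` objects sorted by AICc (best first).
#' @export
fit_removal_set <- function(data, boundaries = 0:5, candidates = NULL,
                            seed = 1, min_n_per_param = 15) {
  if (!nrow(data)) stop_estimation("no individuals to fit removal models")
  if (any(data$interval < 1 | data$interval > length(boundaries) - 1))
    stop_invalid("removal intervals out of range")
  candidates <- candidates %||% removal_candidates_default()
  n <- nrow(data)
  models <- list()
  for (lbl in names(candidates)) {
    terms <- candidates[[lbl]]
    kpar <- length(terms) + 1L
    # sparse-data guard: covariate effects need enough individuals to be
    # identified; the null model is always entertained
    if (length(terms) && n < min_n_per_param * length(terms)) next
    if (n <= kpar + 1) {
      warning(sprintf("removal candidate `%s` skipped: n = %d too small", lbl, n))
      next
    }
    X <- removal_design(data, terms)
    start <- c(log(2 / max(boundaries)), rep(0, length(terms)))
    nll <- function(b) removal_nll(b, X, as.integer(data$interval), boundaries)
    fit <- fit_conditional_multinomial(nll, start, seed = seed)
    coefs <- setNames(fit$par, colnames(X))
    models[[lbl]] <- structure(list(
      label = lbl, terms = terms, coefs = coefs,
      loglik = -fit$value, k = kpar, n = n,
      aicc = aicc(-fit$value, kpar, n), boundaries = boundaries
    ), class = "availability_model")
  }
  if (!length(models)) stop_estimation("all removal candidates were skipped")
  rank_by_aicc(models)
}

#' Predict the availability rate phi from a fitted removal model
#' @param model an `availability_model`.
#' @param newdata data.frame with `jday`, `tod`.
#' @return phi per row (per minute).
#' @export
predict_phi <- function(model, newdata) {
  stopifnot(inherits(model, "availability_model"))
  X <- removal_design(newdata, model$terms)
  # clamp to a physical range so sparse fits cannot overflow downstream
  exp(pmin(pmax(drop(X %*% model$coefs), log(1e-4)), log(100)))
}

#' Availability probability for a count of given duration
#'
#' `p = 1 - exp(-phi T)` with the checklist's actual duration.
#'
#' @param model an `availability_model`.
#' @param newdata survey covariates (`jday`, `tod`).
#' @param duration count duration(s) in minutes, > 0.
#' @return availability probability in (0, 1].
#' @export
availability_prob <- function(model, newdata, duration) {
  if (any(duration <= 0)) stop_invalid("duration must be > 0")
  1 - exp(-predict_phi(model, newdata) * duration)
}

## ---- perceptibility (distance) models -------------------------------------

distance_forms <- function(var) {
  list(lin = paste0(var, "_s"),
       quad = c(paste0(var, "_s"), paste0(var, "_s2")),
       log = paste0(var, "_log"))
}

distance_stage1_default <- function(vars = c("d_river", "d_highway")) {
  out <- list(null = character(0))
  f1 <- distance_forms(vars[1]); f2 <- distance_forms(vars[2])
  for (a in names(f1)) out[[paste(vars[1], a)]] <- f1[[a]]
  for (b in names(f2)) out[[paste(vars[2], b)]] <- f2[[b]]
  for (a in names(f1)) for (b in names(f2))
    out[[paste(vars[1], a, "+", vars[2], b)]] <- c(f1[[a]], f2[[b]])
  out
}

distance_stage2_default <- function() {
  list("canopy" = "canopy_f75_s",
       "urban_hdmd" = "urban_hdmd_f75_s",
       "urban_total" = "urban_total_f75_s",
       "canopy + urban_hdmd" = c("canopy_f75_s", "urban_hdmd_f75_s"),
       "canopy + urban_total" = c("canopy_f75_s", "urban_total_f75_s"))
}

fit_distance_one <- function(data, terms, lbl, scaling, bin_edges, seed,
                             min_n_per_param = 15) {
  n <- nrow(data)
  kpar <- length(terms) + 1L
  if (length(terms) && n < min_n_per_param * length(terms)) return(NULL)
  if (n <= kpar + 1) {
    warning(sprintf("distance candidate `%s` skipped: n = %d too small", lbl, n))
    return(NULL)
  }
  Z <- distance_design(data, terms, scaling)
  finite <- bin_edges[is.finite(bin_edges)]
  mids <- c((finite[-length(finite)] + finite[-1]) / 2, 1.25 * max(finite))
  obs_mid <- mids[pmin(as.integer(data$bin), length(mids))]
  start <- c(log(sqrt(mean(obs_mid^2))), rep(0, length(terms)))
  nll <- function(g) distance_nll(g, Z, as.integer(data$bin), bin_edges)
  fit <- fit_conditional_multinomial(nll, start, seed = seed)
  structure(list(
    label = lbl, terms = terms, coefs = setNames(fit$par, colnames(Z)),
    scaling = scaling, loglik = -fit$value, k = kpar, n = n,
    aicc = aicc(-fit$value, kpar, n), bin_edges = bin_edges
  ), class = "perceptibility_model")
}

#' Fit the two-stage distance-sampling (perceptibility) model set
#'
#' Stage 1 screens noise covariates (distance to river / highway) in linear,
#' quadratic, and log-transformed forms including two-variable combinations,
#' against the null by AICc; stage 2 keeps the winning noise structure and
#' adds vegetation/urban cover terms. `log tau` is linear in the selected
#' design; the likelihood is the conditional multinomial over distance bands
#' with an unbounded last band.
#'
#' @param data data.frame with one row per detected individual: `bin`
#'   (1..K) plus covariate columns `d_river`, `d_highway`, `canopy_f75`,
#'   `urban_hdmd_f75`, `urban_total_f75`.
#' @param bin_edges distance band edges (m), last `Inf`.
#' @param stage1_candidates,stage2_candidates named lists of term vectors;
#'   defaults as described.
#' @param seed seed for optimizer restarts.
#' @return list of `perceptibility_model` objects from the stage-2 ranking
#'   (stage-1 winner included), sorted by AICc.
#' @export
fit_distance_set <- function(data, bin_edges = DEFAULT_BIN_EDGES,
                             stage1_candidates = NULL,
                             stage2_candidates = NULL, seed = 1,
                             min_n_per_param = 15) {
  if (!nrow(data)) stop_estimation("no individuals to fit distance models")
  if (any(data$bin < 1 | data$bin > length(bin_edges) - 1))
    stop_invalid("distance bins out of range")
  stage1_candidates <- stage1_candidates %||% distance_stage1_default()
  stage2_candidates <- stage2_candidates %||% distance_stage2_default()

  vars_log <- list(d_river = TRUE, d_highway = TRUE, canopy_f75 = FALSE,
                   urban_hdmd_f75 = FALSE, urban_total_f75 = FALSE)
  vars_log <- vars_log[names(vars_log) %in% names(data)]
  scaling <- distance_scaling(data, vars_log)

  stage1 <- list()
  for (lbl in names(stage1_candidates)) {
    m <- fit_distance_one(data, stage1_candidates[[lbl]], lbl, scaling,
                          bin_edges, seed, min_n_per_param)
    if (!is.null(m)) stage1[[lbl]] <- m
  }
  if (!length(stage1)) stop_estimation("all distance candidates were skipped")
  stage1 <- rank_by_aicc(stage1)
  winner <- stage1[[1L]]

  stage2 <- list(winner)
  names(stage2) <- winner$label
  for (lbl in names(stage2_candidates)) {
    terms <- unique(c(winner$terms, stage2_candidates[[lbl]]))
    full_lbl <- if (winner$label == "null") lbl else paste(winner$label, "+", lbl)
    m <- fit_distance_one(data, terms, full_lbl, scaling, bin_edges, seed,
                          min_n_per_param)
    if (!is.null(m)) stage2[[full_lbl]] <- m
  }
  rank_by_aicc(stage2)
}

#' Predict the half-normal scale tau from a fitted distance model
#' @param model a `perceptibility_model`.
#' @param newdata data.frame with the model's covariates on their raw scale.
#' @return tau per row (meters).
#' @export
predict_tau <- function(model, newdata) {
  stopifnot(inherits(model, "perceptibility_model"))
  Z <- distance_design(newdata, model$terms, model$scaling)
  # clamp to a physical range so sparse fits cannot overflow downstream
  exp(pmin(pmax(drop(Z %*% model$coefs), log(1)), log(5000)))
}

#' Effective detection radius
#'
#' The radius at which the expected number of individuals missed inside
#' equals the number detected outside; for a half-normal detection function
#' with unlimited distance this equals tau. [edr_from_integral()] exposes
#' the defining balance solved numerically.
#'
#' @param model a `perceptibility_model`.
#' @param newdata survey covariates.
#' @return EDR in meters.
#' @export
edr <- function(model, newdata) {
  predict_tau(model, newdata)
}

#' Solve the EDR defining balance numerically
#'
#' Finds `rho` such that `integral_0^rho (1 - g(r)) 2 pi r dr` equals
#' `integral_rho^Inf g(r) 2 pi r dr` for `g(r) = exp(-r^2/tau^2)`,
#' equivalently `pi rho^2 = integral_0^Inf 2 pi r g(r) dr`.
#'
#' @param tau half-normal scale (m).
#' @param tol relative tolerance for the quadrature and root.
#' @return rho in meters (equals tau up to `tol` for the half-normal).
#' @export
edr_from_integral <- function(tau, tol = 1e-9) {
  assert_scalar_number(tau, "tau", positive = TRUE)
  g <- function(r) exp(-(r / tau)^2)
  missed_inside <- function(rho)
    integrate(function(r) (1 - g(r)) * 2 * pi * r, 0, rho, rel.tol = tol)$value
  detected_outside <- function(rho)
    integrate(function(r) g(r) * 2 * pi * r, rho, Inf, rel.tol = tol)$value
  uniroot(function(rho) missed_inside(rho) - detected_outside(rho),
          interval = c(tau * 1e-3, tau * 10), tol = tau * tol)$root
}

## ---- offsets ---------------------------------------------------------------

offset_columns <- c("survey_id", "p", "q", "edr_m", "area_ha", "C", "logC")

#' Per-survey detection offsets (correction factors)
#'
#' For each survey, the correction factor `C = A p q` (hectares) links the
#' expected count to density: availability `p = 1 - exp(-phi T)` uses the
#' survey's actual duration; the effective area `A = pi rho^2` uses the EDR
#' at the survey's covariates; perceptibility `q` is 1 by definition within
#' the effective area. `log C` enters Poisson count models as an offset.
#'
#' @param surveys checklist data.frame (needs `survey_id`, `x_m`, `y_m`,
#'   `jday`, `min_since_dawn`, `duration_min`).
#' @param avail_model fitted `availability_model`.
#' @param percep_model fitted `perceptibility_model`.
#' @param landscape the `landscape` supplying distance-model covariates.
#' @return data.frame with columns `survey_id`, `p`, `q`, `edr_m`,
#'   `area_ha`, `C`, `logC`.
#' @export
compute_offsets <- function(surveys, avail_model, percep_model, landscape) {
  need <- c("survey_id", "x_m", "y_m", "jday", "min_since_dawn", "duration_min")
  missing <- setdiff(need, names(surveys))
  if (length(missing))
    stop_invalid("surveys lack columns: %s", paste(missing, collapse = ", "))
  avail_cov <- data.frame(jday = surveys$jday, tod = surveys$min_since_dawn)
  p <- availability_prob(avail_model, avail_cov, surveys$duration_min)
  dist_cov <- detection_covariates(landscape, surveys$x_m, surveys$y_m)
  rho <- edr(percep_model, dist_cov)
  area_ha <- pi * rho^2 / 1e4
  C <- area_ha * p
  data.frame(survey_id = surveys$survey_id, p = p, q = 1, edr_m = rho,
             area_ha = area_ha, C = C, logC = log(C))
}

#' Fixed-radius offsets (perfect-detection assumption)
#'
#' Every survey gets `p = q = 1` and `A = pi radius^2`; with the default
#' 200 m radius `C = pi * 200^2 m^2` (about 12.566 ha) for all surveys.
#'
#' @param surveys checklist data.frame.
#' @param radius_m assumed survey radius (m).
#' @return offsets data.frame as in [compute_offsets()].
#' @export
fixed_offsets <- function(surveys, radius_m = 200) {
  assert_scalar_number(radius_m, "radius_m", positive = TRUE)
  area_ha <- pi * radius_m^2 / 1e4
  data.frame(survey_id = surveys$survey_id, p = 1, q = 1, edr_m = radius_m,
             area_ha = area_ha, C = area_ha, logC = log(area_ha))
}

#' Assemble removal-model data from structured survey records
#' @param detections individual detections (`survey_id`, `removal_interval`).
#' @param checklists matching structured checklists.
#' @return data.frame with `interval`, `jday`, `tod` per individual.
#' @export
removal_data <- function(detections, checklists) {
  idx <- match(detections$survey_id, checklists$survey_id)
  if (anyNA(idx)) stop_invalid("detections reference unknown surveys")
  data.frame(interval = detections$removal_interval,
             jday = checklists$jday[idx],
             tod = checklists$min_since_dawn[idx])
}

#' Assemble distance-model data from structured survey records
#' @param detections individual detections (`survey_id`, `distance_bin`).
#' @param checklists matching structured checklists.
#' @param landscape the `landscape` supplying covariates.
#' @return data.frame with `bin` plus detection-stage covariates.
#' @export
distance_data <- function(detections, checklists, landscape) {
  idx <- match(detections$survey_id, checklists$survey_id)
  if (anyNA(idx)) stop_invalid("detections reference unknown surveys")
  cov <- detection_covariates(landscape, checklists$x_m[idx], checklists$y_m[idx])
  cbind(data.frame(bin = detections$distance_bin), cov)
}
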