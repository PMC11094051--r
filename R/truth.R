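# Ground truth for a simulated species: where it can occur, how dense it is,
# and how detectable it is. The truth side mirrors the quantities the
# estimation side targets (density D, availability rate phi, half-normal
# perceptibility scale tau) so that oracle checks can compare estimates to
# known values.

linear_predictor <- function(coefs, data) {
  eta <- rep(coefs[["intercept"]] %||% 0, nrow(data))
  for (nm in setdiff(names(coefs), "intercept")) {
    if (!nm %in% names(data)) stop_invalid("truth references unknown column `%s`", nm)
    eta <- eta + coefs[[nm]] * data[[nm]]
  }
  eta
}

# Standardizations used for the availability covariates: Julian day over the
# simulated season (120-190) and minutes since dawn over the 0-420 window.
scale_jday <- function(jday) (jday - 155) / 35
scale_tod <- function(tod) (tod - 210) / 210

#' Define the true state of a simulated species
#'
#' Suitability is logistic in landscape covariates and thresholded to a
#' truly-suitable cell set; density (birds/ha) is log-linear in covariates
#' within suitable cells and exactly 0 elsewhere. The availability (cue)
#' rate `phi` (per minute) is log-linear in scaled Julian day and time of
#' day; the half-normal perceptibility scale `tau` (meters) is log-linear in
#' landscape covariates.
#'
#' @param landscape a `landscape`.
#' @param suit_coefs named list/vector of logistic coefficients over columns
#'   of [covariate_table()] (plus `intercept`).
#' @param suit_threshold probability cutoff defining truly suitable cells.
#' @param dens_coefs named coefficients for log density within suitable cells.
#' @param phi_coefs coefficients for log phi over `intercept`, `jday`, `tod`
#'   (and `jday2`, `tod2`), with jday/tod pre-scaled internally.
#' @param tau_coefs named coefficients for log tau over covariate columns.
#' @return object of class `species_truth` with the per-cell density surface,
#'   suitable mask, and true population (sum of density times cell area).
#' @export
species_truth <- function(landscape,
                          suit_coefs = list(intercept = 0, canopy_f615 = 6),
                          suit_threshold = 0.5,
                          dens_coefs = list(intercept = 0),
                          phi_coefs = list(intercept = log(0.4)),
                          tau_coefs = list(intercept = log(80))) {
  stopifnot(inherits(landscape, "landscape"))
  tab <- covariate_table(landscape)
  suit_prob <- plogis(linear_predictor(suit_coefs, tab))
  suitable <- suit_prob >= suit_threshold
  density <- exp(linear_predictor(dens_coefs, tab)) * suitable
  structure(list(
    suit_coefs = suit_coefs, suit_threshold = suit_threshold,
    dens_coefs = dens_coefs, phi_coefs = phi_coefs, tau_coefs = tau_coefs,
    suitable = suitable, density = density,
    cell_area_ha = landscape$cell_area_ha,
    population = sum(density) * landscape$cell_area_ha,
    covariate_table = tab
  ), class = "species_truth")
}

#' @export
print.species_truth <- function(x, ...) {
  cat(sprintf(
    "species_truth: %.0f of %d cells suitable, population %.1f birds, mean density %.3f birds/ha (suitable cells)\n",
    sum(x$suitable), length(x$suitable), x$population,
    mean(x$density[x$suitable])))
  invisible(x)
}

#' True availability rate at given survey conditions
#' @param truth a `species_truth`.
#' @param jday Julian day (vector).
#' @param tod minutes since nautical dawn (vector).
#' @return cue rate per minute (> 0).
#' @export
true_phi <- function(truth, jday, tod) {
  sj <- scale_jday(jday); st <- scale_tod(tod)
  d <- data.frame(jday = sj, tod = st, jday2 = sj^2, tod2 = st^2)
  exp(linear_predictor(truth$phi_coefs, d))
}

#' True half-normal perceptibility scale at locations
#' @param truth a `species_truth`.
#' @param landscape the landscape the truth was built on.
#' @param x_m,y_m locations.
#' @return tau in meters (> 0).
#' @export
true_tau <- function(truth, landscape, x_m, y_m) {
  cc <- cell_covariates(landscape, x_m, y_m, truth$covariate_table)
  exp(linear_predictor(truth$tau_coefs, cc))
}

#' Observer behaviour profile for community checklists
#'
#' `kappa = 1`, `thinning = 1`, `x_prob = 0` reproduces structured-observer
#' behaviour exactly; `kappa < 1` shrinks the perceptibility scale (the
#' detection-discrepancy mechanism), `thinning < 1` under-reports counts,
#' `x_prob > 0` substitutes a presence-only "X" for positive counts.
#'
#' @param observer_id identifier.
#' @param kappa detection-scale multiplier in (0, 1].
#' @param thinning per-bird reporting probability in (0, 1].
#' @param x_prob probability a positive count is reported as "X".
#' @return object of class `observer_profile`.
#' @export
observer_profile <- function(observer_id, kappa = 1, thinning = 1, x_prob = 0) {
  if (kappa <= 0 || kappa > 1) stop_invalid("kappa must be in (0, 1]")
  if (thinning <= 0 || thinning > 1) stop_invalid("thinning must be in (0, 1]")
  if (x_prob < 0 || x_prob > 1) stop_invalid("x_prob must be in [0, 1]")
  structure(list(observer_id = observer_id, kappa = kappa,
                 thinning = thinning, x_prob = x_prob),
            class = "observer_profile")
}

#' Realize a bird population from the true density surface
#'
#' Inhomogeneous Poisson point process: each cell receives
#' `Poisson(D_true x cell area)` birds placed uniformly within the cell.
#'
#' @param landscape a `landscape`.
#' @param truth a `species_truth` defined on it.
#' @param seed integer seed.
#' @return data.frame with columns `x_m`, `y_m`, `cell_id` (possibly 0 rows).
#' @export
generate_population <- function(landscape, truth, seed = 1) {
  stopifnot(inherits(landscape, "landscape"), inherits(truth, "species_truth"))
  withr::with_seed(as.integer(seed), {
    n <- rpois(length(truth$density), truth$density * landscape$cell_area_ha)
    total <- sum(n)
    if (total == 0)
      return(data.frame(x_m = numeric(0), y_m = numeric(0), cell_id = integer(0)))
    cell <- rep(seq_along(n), n)
    ix <- (cell - 1) %% landscape$n_x + 1
    iy <- (cell - 1) %/% landscape$n_x + 1
    data.frame(
      x_m = (ix - 1 + runif(total)) * landscape$cell_m,
      y_m = (iy - 1 + runif(total)) * landscape$cell_m,
      cell_id = cell
    )
  })
}
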