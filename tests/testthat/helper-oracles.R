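# Independent oracles and shared fixtures for the test suite.

# Monte-Carlo removal-interval frequencies: first-cue times Exponential(phi)
# truncated to the count duration, binned by interval.
mc_removal_freqs <- function(phi, boundaries, n_draws, seed) {
  withr::with_seed(seed, {
    t_max <- max(boundaries)
    t <- rexp(n_draws * 3, phi)
    t <- t[t <= t_max][seq_len(n_draws)]
    tabulate(findInterval(t, boundaries, left.open = TRUE),
             nbins = length(boundaries) - 1) / n_draws
  })
}

# Quadrature oracle for half-normal distance-band probabilities:
# integral of 2 pi r g(r) over the band divided by pi tau^2.
quad_distance_probs <- function(tau, edges) {
  g <- function(r) exp(-(r / tau)^2)
  vapply(seq_len(length(edges) - 1), function(k) {
    stats::integrate(function(r) 2 * pi * r * g(r), edges[k],
                     min(edges[k + 1], 50 * tau),
                     rel.tol = 1e-12)$value / (pi * tau^2)
  }, numeric(1))
}

# Draw removal data directly from the conditional mechanism (first-cue time
# exponential, conditioned on detection within the count).
sim_removal_data <- function(n, seed, boundaries = 0:5,
                             phi_fun = function(jday, tod) 0.4) {
  withr::with_seed(seed, {
    jday <- round(runif(n, 120, 190))
    tod <- round(runif(n, 0, 420))
    phi <- phi_fun(jday, tod)
    t_max <- max(boundaries)
    u <- runif(n)
    # inverse CDF of Exponential(phi) truncated to [0, t_max]
    t <- -log(1 - u * (1 - exp(-phi * t_max))) / phi
    data.frame(interval = findInterval(t, boundaries, left.open = TRUE),
               jday = jday, tod = tod)
  })
}

# Draw distance data from the conditional half-normal mechanism:
# r = tau sqrt(E), E ~ Exponential(1) gives density 2 r exp(-r^2/tau^2)/tau^2.
sim_distance_data <- function(n, seed, edges = c(0, 50, 100, 150, 200, Inf),
                              tau_fun = function(cov) 80) {
  withr::with_seed(seed, {
    cov <- data.frame(d_river = 800 * exp(0.5 * rnorm(n)),
                      d_highway = 800 * exp(0.5 * rnorm(n)),
                      canopy_f75 = rnorm(n), urban_hdmd_f75 = rnorm(n),
                      urban_total_f75 = rnorm(n))
    tau <- tau_fun(cov)
    r <- tau * sqrt(rexp(n))
    cbind(data.frame(bin = findInterval(r, edges)), cov)
  })
}

# Hand-built detection models with known constant parameters.
constant_availability_model <- function(phi) {
  structure(list(label = "fixed", terms = character(0),
                 coefs = c(`(Intercept)` = log(phi)), loglik = 0, k = 1,
                 n = 1000, aicc = 0, boundaries = 0:5),
            class = "availability_model")
}

constant_perceptibility_model <- function(tau) {
  structure(list(label = "fixed", terms = character(0),
                 coefs = c(`(Intercept)` = log(tau)), scaling = list(),
                 loglik = 0, k = 1, n = 1000, aicc = 0,
                 bin_edges = c(0, 50, 100, 150, 200, Inf)),
            class = "perceptibility_model")
}

# Scenario bundles are expensive; memoize them across test files.
.scenario_cache <- new.env(parent = emptyenv())
get_scenario <- function(name, seed) {
  key <- paste(name, seed, sep = "_")
  if (is.null(.scenario_cache[[key]]))
    .scenario_cache[[key]] <- make_fixture_scenario(name, seed = seed)
  .scenario_cache[[key]]
}

# Filtered community data + benchmark split, memoized alongside.
get_prepared <- function(name, seed) {
  key <- paste("prep", name, seed, sep = "_")
  if (is.null(.scenario_cache[[key]])) {
    s <- get_scenario(name, seed)
    cs <- scenario_community_filtered(s, seed = seed)
    split <- make_benchmark_dataset(s$structured, n_match = nrow(cs),
                                    seed = seed)
    .scenario_cache[[key]] <- list(scenario = s, cs = cs,
                                   benchmark = split$benchmark,
                                   test = split$test)
  }
  .scenario_cache[[key]]
}

# Small flat landscape + truth with every cell suitable and constant
# density/detectability, for mechanism checks.
make_constant_world <- function(density = 2, tau = 80, phi = -log(0.2) / 5,
                                n_x = 30, n_y = 30, seed = 1) {
  landscape <- generate_landscape(n_x, n_y, 100, smoothness = 400, seed = seed)
  truth <- species_truth(landscape,
                         suit_coefs = list(intercept = 10),
                         dens_coefs = list(intercept = log(density)),
                         phi_coefs = list(intercept = log(phi)),
                         tau_coefs = list(intercept = log(tau)))
  list(landscape = landscape, truth = truth)
}
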