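EDGES <- c(0, 50, 100, 150, 200, Inf)

test_that("removal cell probabilities match theory at the boundaries", {
  p <- removal_cell_probs(1e6, 0:5)
  expect_equal(p, c(1, 0, 0, 0, 0), tolerance = 1e-12)
  # small-rate limit: uniform over interval lengths
  p0 <- removal_cell_probs(1e-9, c(0, 1, 3, 5))
  expect_equal(p0, c(1, 2, 2) / 5, tolerance = 1e-6)
  expect_equal(sum(removal_cell_probs(0.37, 0:5)), 1, tolerance = 1e-12)
  expect_error(removal_cell_probs(-1, 0:5), class = "densitycal_invalid_argument")
  expect_error(removal_cell_probs(1, c(0, 2, 1)), class = "densitycal_invalid_argument")
})

test_that("removal probabilities match truncated-exponential Monte Carlo", {
  p <- removal_cell_probs(0.5, 0:5)
  freqs <- mc_removal_freqs(0.5, 0:5, n_draws = 1e5, seed = 42)
  expect_lt(max(abs(p - freqs)), 0.01)
})

test_that("distance band probabilities match the half-normal quadrature", {
  p <- distance_cell_probs(100, EDGES)
  expect_lt(max(abs(p - quad_distance_probs(100, EDGES))), 1e-8)
  # probabilities always telescope to 1; oracle agreement across scales
  for (tau in withr::with_seed(1, runif(20, 15, 400))) {
    p <- distance_cell_probs(tau, EDGES)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_lt(max(abs(p - quad_distance_probs(tau, EDGES))), 1e-6)
  }
  # flat detection limit: everything lands in the unbounded band
  expect_gt(distance_cell_probs(1e6, EDGES)[5], 0.999)
  expect_error(distance_cell_probs(0, EDGES), class = "densitycal_invalid_argument")
})

test_that("AICc arithmetic and limits", {
  expect_equal(aicc(-50, 0, 100), 100)
  expect_equal(aicc(-100, 3, 50), 206 + 24 / 46)
  # converges to plain AIC as n grows
  expect_equal(aicc(-100, 3, 1e9), 206, tolerance = 1e-6)
  expect_error(aicc(-10, 3, 4), class = "densitycal_invalid_argument")
})

test_that("availability probability uses the actual duration", {
  am <- constant_availability_model(0.3)
  expect_equal(availability_prob(am, data.frame(jday = 150, tod = 60), 1e6), 1)
  expect_lt(availability_prob(constant_availability_model(1e-4),
                              data.frame(jday = 150, tod = 60), 5), 1e-3)
  # Monte-Carlo oracle: fraction of Exponential(0.3) draws below 5
  mc <- withr::with_seed(11, mean(rexp(1e5, 0.3) <= 5))
  expect_lt(abs(availability_prob(am, data.frame(jday = 150, tod = 60), 5) - mc),
            0.005)
  expect_error(availability_prob(am, data.frame(jday = 1, tod = 1), 0),
               class = "densitycal_invalid_argument")
})

test_that("removal model set recovers a constant rate and ranks by AICc", {
  rd <- sim_removal_data(2000, seed = 21, phi_fun = function(j, t) 0.4)
  fits <- fit_removal_set(rd, seed = 1)
  expect_true(all(diff(vapply(fits, `[[`, numeric(1), "aicc")) >= 0))
  null_fit <- fits[[which(vapply(fits, `[[`, character(1), "label") == "null")]]
  phi_hat <- exp(null_fit$coefs[["(Intercept)"]])
  expect_lt(abs(phi_hat - 0.4) / 0.4, 0.05)
  # a single individual cannot support any candidate: clean classed error
  expect_error(
    suppressWarnings(fit_removal_set(sim_removal_data(1, seed = 1))),
    class = "densitycal_estimation_error")
})

test_that("removal selection finds a real time-of-day effect", {
  wins <- vapply(1:3, function(rep) {
    rd <- sim_removal_data(4000, seed = 100 + rep,
                           phi_fun = function(j, t) exp(log(0.4) + 0.5 * (t - 210) / 210))
    top <- fit_removal_set(rd, seed = 1)[[1]]
    "tod" %in% top$terms
  }, logical(1))
  expect_true(all(wins))
})

test_that("distance model set recovers a constant scale", {
  dd <- sim_distance_data(2000, seed = 31)
  fits <- fit_distance_set(dd, seed = 1)
  top <- fits[[1]]
  tau_hat <- mean(predict_tau(top, dd))
  expect_lt(abs(tau_hat - 80) / 80, 0.05)
  # degenerate input: every detection in the first band still converges
  dd1 <- dd[1:60, ]; dd1$bin <- 1L
  t1 <- suppressWarnings(fit_distance_set(dd1, seed = 1))[[1]]
  tau1 <- mean(predict_tau(t1, dd1))
  expect_true(is.finite(tau1) && tau1 < 50)
})

test_that("distance selection finds a real canopy effect", {
  wins <- vapply(1:3, function(rep) {
    dd <- sim_distance_data(4000, seed = 200 + rep,
                            tau_fun = function(cov) exp(log(80) + 0.35 * cov$canopy_f75))
    top <- fit_distance_set(dd, seed = 1)[[1]]
    any(grepl("canopy", top$terms))
  }, logical(1))
  expect_true(all(wins))
})

test_that("EDR equals tau for the half-normal and satisfies the balance integral", {
  pm <- constant_perceptibility_model(80)
  expect_equal(edr(pm, data.frame(x = 1)), 80)
  for (tau in withr::with_seed(2, runif(20, 15, 400)))
    expect_lt(abs(edr_from_integral(tau) - tau) / tau, 1e-6)
  # doubling tau quadruples the effective area
  a1 <- pi * edr(constant_perceptibility_model(60), data.frame(x = 1))^2
  a2 <- pi * edr(constant_perceptibility_model(120), data.frame(x = 1))^2
  expect_equal(a2 / a1, 4)
})

test_that("offsets combine availability and effective area in hectares", {
  l <- generate_landscape(10, 10, 100, smoothness = 300, seed = 5)
  surveys <- data.frame(survey_id = c("s1", "s2"), x_m = c(500, 500),
                        y_m = c(300, 300), jday = 150, min_since_dawn = 100,
                        duration_min = c(3, 30))
  am <- constant_availability_model(50)   # p effectively 1
  pm <- constant_perceptibility_model(200)
  offs <- fixed_offsets(surveys, radius_m = 200)
  expect_equal(offs$C, rep(pi * 4, 2))    # pi 200^2 m^2 = 4 pi ha
  offs2 <- compute_offsets(surveys, am, pm, l)
  expect_equal(offs2$C, rep(pi * 4, 2), tolerance = 1e-6)
  expect_equal(offs2$q, c(1, 1))

  # identical surveys except duration: offset ratio is p(3)/p(30) < 1
  am2 <- constant_availability_model(0.3)
  offs3 <- compute_offsets(surveys, am2, pm, l)
  expect_equal(offs3$C[1] / offs3$C[2],
               (1 - exp(-0.3 * 3)) / (1 - exp(-0.3 * 30)))
  expect_lt(offs3$C[1] / offs3$C[2], 1)

  bad <- generate_landscape(10, 10, 100, n_covariates = 2, smoothness = 300,
                            seed = 5, covariate_names = c("a", "b"))
  expect_error(compute_offsets(surveys, am, pm, bad),
               class = "densitycal_invalid_argument")
})

test_that("fitted likelihoods agree with numerical oracles across parameter draws", {
  draws <- withr::with_seed(3, data.frame(phi = runif(20, 0.05, 2),
                                          tau = runif(20, 20, 300)))
  for (i in seq_len(nrow(draws))) {
    phi <- draws$phi[i]; tau <- draws$tau[i]
    e <- exp(-phi * 0:5)
    oracle_rem <- (e[-6] - e[-1]) / (1 - e[6])
    expect_equal(removal_cell_probs(phi, 0:5), oracle_rem, tolerance = 1e-10)
    expect_lt(max(abs(distance_cell_probs(tau, EDGES) -
                        quad_distance_probs(tau, EDGES))), 1e-6)
  }
})
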