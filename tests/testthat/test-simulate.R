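test_that("perfect-detection limit detects every bird in interval 1", {
  w <- make_constant_world(density = 1, n_x = 10, n_y = 10)
  tr <- species_truth(w$landscape, suit_coefs = list(intercept = 10),
                      dens_coefs = list(intercept = log(1)),
                      phi_coefs = list(intercept = log(1e6)),
                      tau_coefs = list(intercept = log(1e7)))
  birds <- generate_population(w$landscape, tr, seed = 4)
  out <- simulate_structured_survey(w$landscape, birds, tr, 500, 500,
                                    jday = 150, tod = 100, seed = 1)
  expect_equal(out$checklist$count, nrow(birds))
  expect_true(all(out$detections$removal_interval == 1L))
})

test_that("a bird at the observer's feet is always detected (g(0) = 1)", {
  w <- make_constant_world()
  tr <- species_truth(w$landscape, suit_coefs = list(intercept = 10),
                      dens_coefs = list(intercept = 0),
                      phi_coefs = list(intercept = log(50)),
                      tau_coefs = list(intercept = log(80)))
  bird <- data.frame(x_m = 500, y_m = 500, cell_id = 1L)
  for (s in 1:20) {
    out <- simulate_structured_survey(w$landscape, bird, tr, 500, 500,
                                      jday = 150, tod = 100, seed = s)
    expect_equal(out$checklist$count, 1L)
    expect_equal(out$detections$distance_bin, 1L)
  }
})

test_that("availability fraction matches the closed form 1 - exp(-phi T)", {
  # 10^4 birds stacked at the point with unlimited perceptibility: the
  # detected fraction estimates P(first cue <= 5) for phi = 0.5
  w <- make_constant_world()
  tr <- species_truth(w$landscape, suit_coefs = list(intercept = 10),
                      dens_coefs = list(intercept = 0),
                      phi_coefs = list(intercept = log(0.5)),
                      tau_coefs = list(intercept = log(1e7)))
  n <- 1e4
  birds <- data.frame(x_m = rep(500, n), y_m = rep(500, n), cell_id = 1L)
  out <- simulate_structured_survey(w$landscape, birds, tr, 500, 500,
                                    jday = 150, tod = 100, seed = 2)
  p_hat <- out$checklist$count / n
  p_true <- 1 - exp(-0.5 * 5)
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / n))
})

test_that("removal intervals follow the truncated-exponential cell probabilities", {
  w <- make_constant_world()
  tr <- species_truth(w$landscape, suit_coefs = list(intercept = 10),
                      dens_coefs = list(intercept = 0),
                      phi_coefs = list(intercept = log(0.5)),
                      tau_coefs = list(intercept = log(1e7)))
  n <- 2e4
  birds <- data.frame(x_m = rep(500, n), y_m = rep(500, n), cell_id = 1L)
  out <- simulate_structured_survey(w$landscape, birds, tr, 500, 500,
                                    jday = 150, tod = 100, seed = 3)
  obs <- tabulate(out$detections$removal_interval, nbins = 5)
  p <- removal_cell_probs(0.5, 0:5)
  expect_gt(suppressWarnings(chisq.test(obs, p = p)$p.value), 0.01)
})

test_that("distance bins follow the half-normal band probabilities", {
  # dense homogeneous population around one survey point
  w <- make_constant_world(density = 1500, tau = 80, n_x = 10, n_y = 10)
  tr <- species_truth(w$landscape, suit_coefs = list(intercept = 10),
                      dens_coefs = list(intercept = log(1500)),
                      phi_coefs = list(intercept = log(50)),
                      tau_coefs = list(intercept = log(80)))
  birds <- generate_population(w$landscape, tr, seed = 5)
  out <- simulate_structured_survey(w$landscape, birds, tr, 500, 500,
                                    jday = 150, tod = 100, seed = 6)
  expect_gt(nrow(out$detections), 2000)
  obs <- tabulate(out$detections$distance_bin, nbins = 5)
  p <- distance_cell_probs(80, c(0, 50, 100, 150, 200, Inf))
  expect_gt(suppressWarnings(chisq.test(obs, p = p)$p.value), 0.01)
})

test_that("halving the perceptibility scale quarters expected counts", {
  w <- make_constant_world(density = 3, n_x = 20, n_y = 20)
  birds <- generate_population(w$landscape, w$truth, seed = 7)
  mean_count <- function(kappa) {
    obs <- list(observer_profile("o1", kappa = kappa))
    cl <- simulate_community_checklists(
      w$landscape, birds, w$truth, obs, n_checklists = 1000,
      hotspot_fraction = 0, n_hotspots = 1, duration_range = c(20, 20),
      buffer_m = 400, seed = 8, p_stationary = 1, p_complete = 1)
    mean(cl$count)
  }
  m1 <- mean_count(1)
  m05 <- mean_count(0.5)
  # effective area scales as (kappa tau)^2
  expect_equal(m05 / m1, 0.25, tolerance = 0.12)
})

test_that("observer mechanisms: X substitution and identity behaviour", {
  w <- make_constant_world(density = 2, n_x = 12, n_y = 12)
  birds <- generate_population(w$landscape, w$truth, seed = 10)
  cl_x <- simulate_community_checklists(
    w$landscape, birds, w$truth, list(observer_profile("ox", x_prob = 1)),
    n_checklists = 150, hotspot_fraction = 0.2, n_hotspots = 2,
    buffer_m = 350, seed = 11)
  expect_true(all(is.na(cl_x$count) == cl_x$presence_x))
  expect_true(all(cl_x$count[!cl_x$presence_x] == 0))

  # identity observers on fixed-duration stationary checklists reproduce
  # the structured count distribution at equal duration
  cl_id <- simulate_community_checklists(
    w$landscape, birds, w$truth, list(observer_profile("o1")),
    n_checklists = 600, hotspot_fraction = 0, n_hotspots = 1,
    duration_range = c(5, 5), buffer_m = 350, seed = 12,
    p_stationary = 1, p_complete = 1)
  str_counts <- simulate_structured_surveys(w$landscape, birds, w$truth,
                                            n_surveys = 600, buffer_m = 350,
                                            seed = 13)$checklists$count
  expect_equal(mean(cl_id$count), mean(str_counts),
               tolerance = 4 * sd(str_counts) / sqrt(600) / mean(str_counts))
})

test_that("mean structured count matches the offset identity E[Y] = D A p q", {
  w <- make_constant_world(density = 2, tau = 80, n_x = 20, n_y = 20)
  birds <- generate_population(w$landscape, w$truth, seed = 20)
  sim <- simulate_structured_surveys(w$landscape, birds, w$truth,
                                     n_surveys = 1000, buffer_m = 350,
                                     seed = 21)
  counts <- sim$checklists$count
  d_realized <- nrow(birds) / (20 * 20 * w$landscape$cell_area_ha)
  expected <- d_realized * pi * 80^2 / 1e4 * (1 - exp(-(-log(0.2) / 5) * 5))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("simulation argument validation", {
  w <- make_constant_world(n_x = 10, n_y = 10)
  birds <- generate_population(w$landscape, w$truth, seed = 1)
  expect_error(simulate_structured_survey(w$landscape, birds, w$truth, 100, 100,
                                          150, 100, duration = 0),
               class = "densitycal_invalid_argument")
  expect_error(simulate_structured_survey(w$landscape, birds, w$truth, 100, 100,
                                          150, 100, bin_edges = c(0, 50, 100)),
               class = "densitycal_invalid_argument")
  expect_error(simulate_community_checklists(w$landscape, birds, w$truth,
                                             list(), 10),
               class = "densitycal_invalid_argument")
  expect_error(simulate_community_checklists(w$landscape, birds, w$truth,
                                             list(observer_profile("o")), 10,
                                             hotspot_fraction = 1.5),
               class = "densitycal_invalid_argument")
})
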