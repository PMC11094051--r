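brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

test_that("AUC equals the Mann-Whitney statistic with half ties", {
  expect_equal(auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)),
               brute_force_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)))
  expect_error(auc(1:4, c(1, 1, 1, 1)), class = "densitycal_invalid_argument")

  # property: exact agreement with pair enumeration on random instances,
  # including ties from score rounding
  withr::with_seed(99, {
    for (i in 1:100) {
      n <- sample(4:25, 1)
      labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
      scores <- round(runif(n), sample(1:3, 1))
      expect_identical(auc(scores, labels), brute_force_auc(scores, labels))
    }
  })
  # independent implementation cross-check
  if (requireNamespace("pROC", quietly = TRUE)) {
    withr::with_seed(7, {
      labels <- rbinom(50, 1, 0.4)
      labels[1:2] <- c(0, 1)
      scores <- rnorm(50)
      expect_equal(auc(scores, labels),
                   as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                                  direction = "<"))))
    })
  }
})

test_that("prevalence threshold uses the >= convention", {
  l <- generate_landscape(8, 8, 100, n_covariates = 1, seed = 1)
  fake_fit <- structure(list(threshold = 0.25, prevalence = 0.25,
                             cell_probs = c(0.30, 0.25, 0.2499,
                                            rep(0.1, 61))),
                        class = "occurrence_fit")
  mask <- threshold_by_prevalence(fake_fit, l)
  expect_equal(sum(mask$suitable), 2)   # 0.30 and the exact tie retained
  expect_equal(mask$area_ha, 2 * l$cell_area_ha)
  # constant predictor exactly at the prevalence: everything suitable
  fake_fit$cell_probs <- rep(0.25, 64)
  expect_true(all(threshold_by_prevalence(fake_fit, l)$suitable))
})

sim_occurrence_data <- function(landscape, n, seed, beta = 4, null = FALSE) {
  withr::with_seed(seed, {
    ext <- landscape$n_x * landscape$cell_m
    x <- runif(n, 0, ext - 0.01); y <- runif(n, 0, ext - 0.01)
    cc <- densitycal:::cell_covariates(landscape, x, y)
    p <- if (null) rep(0.4, n) else plogis(beta * cc$canopy_f315)
    data.frame(survey_id = sprintf("s%d", seq_len(n)), x_m = x, y_m = y,
               jday = 150, min_since_dawn = 60, duration_min = 5,
               protocol = "stationary", location_type = "personal",
               observer_id = "o", complete = TRUE,
               count = rbinom(n, 1, p), presence_x = FALSE)
  })
}

test_that("occurrence stage separates a strong logistic signal", {
  l <- generate_landscape(20, 20, 100, smoothness = 400, seed = 8)
  train <- sim_occurrence_data(l, 400, seed = 1)
  test <- sim_occurrence_data(l, 2000, seed = 2)
  fit <- fit_occurrence(train, test, l, seed = 1)
  expect_gt(fit$auc, 0.9)
  expect_equal(fit$threshold, mean(train$count > 0))
  # determinism under the fallback learner
  fit2 <- fit_occurrence(train, test, l, seed = 1)
  expect_identical(fit$auc, fit2$auc)
  expect_identical(fit$cell_probs, fit2$cell_probs)
})

test_that("occurrence AUC is near 0.5 when labels are independent of habitat", {
  l <- generate_landscape(20, 20, 100, smoothness = 400, seed = 9)
  train <- sim_occurrence_data(l, 400, seed = 3, null = TRUE)
  test <- sim_occurrence_data(l, 2000, seed = 4, null = TRUE)
  fit <- fit_occurrence(train, test, l, seed = 1)
  expect_gt(fit$auc, 0.45)
  expect_lt(fit$auc, 0.55)
})

test_that("single-class training data raises an estimation error", {
  l <- generate_landscape(10, 10, 100, seed = 1)
  train <- sim_occurrence_data(l, 50, seed = 5)
  train$count <- 0L
  expect_error(fit_occurrence(train, NULL, l, seed = 1),
               class = "densitycal_estimation_error")
})

make_count_data <- function(landscape, n, density, C, seed) {
  withr::with_seed(seed, {
    ext <- landscape$n_x * landscape$cell_m
    x <- runif(n, 0, ext - 0.01); y <- runif(n, 0, ext - 0.01)
    data.frame(survey_id = sprintf("c%d", seq_len(n)), x_m = x, y_m = y,
               jday = 150, min_since_dawn = 60, duration_min = 5,
               protocol = "stationary", location_type = "personal",
               observer_id = "o", complete = TRUE,
               count = rpois(n, density * C), presence_x = FALSE)
  })
}

full_mask <- function(landscape) {
  structure(list(suitable = rep(TRUE, landscape$n_x * landscape$n_y),
                 area_ha = landscape$n_x * landscape$n_y * landscape$cell_area_ha,
                 n_x = landscape$n_x, n_y = landscape$n_y,
                 cell_area_ha = landscape$cell_area_ha),
            class = "suitability_mask")
}

test_that("count stage recovers a homogeneous density through the offsets", {
  l <- generate_landscape(16, 16, 100, smoothness = 400, seed = 12)
  train <- make_count_data(l, 500, density = 2, C = 1.6, seed = 6)
  offs <- data.frame(survey_id = train$survey_id, C = 1.6)
  fit <- fit_density(train, offs, full_mask(l), l, seed = 1)
  expect_lt(abs(fit$mean_density - 2) / 2, 0.1)
  expect_equal(fit$population, sum(fit$cell_density) * l$cell_area_ha)
})

test_that("doubling offsets halves fitted density (exposure contract)", {
  l <- generate_landscape(16, 16, 100, smoothness = 400, seed = 13)
  tab <- covariate_table(l)
  train <- make_count_data(l, 600, density = 1.5, C = 2, seed = 7)
  # density varies with habitat so both learners fit real structure
  cid <- cell_at(l, train$x_m, train$y_m)
  train$count <- withr::with_seed(7,
    rpois(600, exp(log(1.5) + 0.4 * tab$canopy_f315[cid]) * 2))
  offs1 <- data.frame(survey_id = train$survey_id, C = 2)
  offs2 <- data.frame(survey_id = train$survey_id, C = 4)
  f1 <- fit_density(train, offs1, full_mask(l), l, seed = 1)
  f2 <- fit_density(train, offs2, full_mask(l), l, seed = 1)
  expect_equal(f2$mean_density / f1$mean_density, 0.5, tolerance = 0.02)

  if (requireNamespace("xgboost", quietly = TRUE)) {
    cfg <- learner_config(type = "xgboost", tree_range = c(100, 400))
    b1 <- suppressWarnings(fit_density(train, offs1, full_mask(l), l, cfg, seed = 1))
    b2 <- suppressWarnings(fit_density(train, offs2, full_mask(l), l, cfg, seed = 1))
    expect_equal(b2$mean_density / b1$mean_density, 0.5, tolerance = 0.1)
  }
})

test_that("count-stage boundary and validation behaviour", {
  l <- generate_landscape(10, 10, 100, seed = 14)
  train <- make_count_data(l, 60, density = 1, C = 1.5, seed = 8)
  train$count <- 0L
  offs <- data.frame(survey_id = train$survey_id, C = 1.5)
  fit <- fit_density(train, offs, full_mask(l), l, seed = 1)
  expect_equal(fit$population, 0)
  expect_equal(fit$mean_density, 0)

  offs_bad <- data.frame(survey_id = train$survey_id, C = -1)
  expect_error(fit_density(train, offs_bad, full_mask(l), l, seed = 1),
               class = "densitycal_invalid_argument")
  expect_error(fit_density(train[0, ], offs, full_mask(l), l, seed = 1),
               class = "densitycal_estimation_error")
})

test_that("intercept-only count model matches the closed-form ratio estimator", {
  l <- generate_landscape(10, 10, 100, seed = 15)
  train <- make_count_data(l, 300, density = 2.5, C = 1.2, seed = 9)
  offs <- data.frame(survey_id = train$survey_id, C = 1.2)
  fit <- fit_density(train, offs, full_mask(l), l, seed = 1,
                     covars = character(0))
  expect_equal(fit$mean_density, sum(train$count) / sum(offs$C),
               tolerance = 1e-8)
})

test_that("predictive correlation handles proportional and degenerate cases", {
  l <- generate_landscape(10, 10, 100, seed = 16)
  mask <- full_mask(l)
  fit <- structure(list(cell_density = rep(1, 100) * seq_len(100) / 50,
                        mask = mask), class = "density_fit")
  test <- make_count_data(l, 30, density = 1, C = 1.5, seed = 10)
  offs <- data.frame(survey_id = test$survey_id, C = 1.5)
  pred <- predict_density(fit, l, test) * offs$C
  test$count <- 3 * pred                      # proportional observations
  expect_equal(predictive_correlation(fit, test, offs, l), 1, tolerance = 1e-6)

  fit0 <- structure(list(cell_density = rep(2, 100), mask = mask),
                    class = "density_fit")
  expect_warning(r <- predictive_correlation(fit0, test, offs, l),
                 class = "densitycal_undefined_result")
  expect_true(is.na(r))
})

test_that("population estimate is exact arithmetic over the mask", {
  l <- generate_landscape(10, 10, 100, seed = 17)
  mask <- full_mask(l)
  fit <- structure(list(cell_density = rep(2, 100), mask = mask),
                   class = "density_fit")
  expect_equal(estimate_population(fit), 200)   # 2 birds/ha over 100 ha

  empty <- mask; empty$suitable <- rep(FALSE, 100)
  expect_equal(estimate_population(fit, empty), 0)

  # checker-board on a 4-cell fixture, hand-summed
  l2 <- generate_landscape(8, 8, 50, seed = 18)
  m2 <- structure(list(suitable = rep(c(TRUE, FALSE), 32),
                       area_ha = 32 * 0.25, n_x = 8, n_y = 8,
                       cell_area_ha = 0.25), class = "suitability_mask")
  d <- rep(c(3, 7), 32)
  f2 <- structure(list(cell_density = d, mask = m2), class = "density_fit")
  expect_equal(estimate_population(f2), 3 * 32 * 0.25)
  bad_mask <- m2; bad_mask$suitable <- rep(TRUE, 10)
  expect_error(estimate_population(f2, bad_mask),
               class = "densitycal_invalid_argument")
})
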