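# Zero-inflated density modeling: an occurrence stage thresholded at the
# sample prevalence defines suitable habitat; a Poisson count stage with
# per-survey log-offsets then converts counts to density within suitable
# habitat. Learners are pluggable: a boosted-tree ensemble (xgboost) with
# the standard hyperparameters (interaction depth 3, bag fraction 0.75,
# cross-validated tree count targeted to 1000-5000 trees) or a fast
# deterministic penalized log-linear fallback (glmnet ridge; the Poisson
# fallback carries an explicit offset so the exposure contract
# E[Y] = C x density is exact).

#' Learner configuration for the occurrence and count stages
#'
#' @param type `"glmnet"` (deterministic penalized GLM fallback, default) or
#'   `"xgboost"` (boosted trees).
#' @param depth tree interaction depth (boosted learner).
#' @param bag_fraction subsample fraction per boosting step.
#' @param tree_range target range for the cross-validated optimal number of
#'   trees; the learning rate is halved until the optimum falls inside it.
#' @param nfolds cross-validation folds (seeded, survey-level).
#' @param learning_rate initial boosted learning rate.
#' @param max_halvings cap on learning-rate halvings (warns if the tree
#'   target is unattainable).
#' @return a `learner_config` list.
#' @export
learner_config <- function(type = c("glmnet", "xgboost"), depth = 3,
                           bag_fraction = 0.75, tree_range = c(1000, 5000),
                           nfolds = 10, learning_rate = 0.1,
                           max_halvings = 8) {
  type <- match.arg(type)
  structure(list(type = type, depth = depth, bag_fraction = bag_fraction,
                 tree_range = tree_range, nfolds = nfolds,
                 learning_rate = learning_rate, max_halvings = max_halvings),
            class = "learner_config")
}

#' Area under the ROC curve
#'
#' Mann-Whitney rank form: the probability a random positive scores above a
#' random negative, counting ties as 1/2.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 (or logical) class labels; both classes required.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop_invalid("AUC requires both classes (got %d positive, %d negative)",
                 n_pos, n_neg)
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

## ---- learners --------------------------------------------------------------

seeded_foldid <- function(n, nfolds, seed) {
  withr::with_seed(as.integer(seed), sample(rep_len(seq_len(nfolds), n)))
}

fit_glmnet_learner <- function(x, y, family, offset, config, seed) {
  foldid <- seeded_foldid(nrow(x), min(config$nfolds, nrow(x)), seed)
  fit <- glmnet::cv.glmnet(x, y, family = family, alpha = 0,
                           offset = offset, foldid = foldid, nlambda = 40)
  list(kind = "glmnet", fit = fit, lambda = fit$lambda.min)
}

fit_xgboost_learner <- function(x, y, objective, base_margin, config, seed) {
  if (!requireNamespace("xgboost", quietly = TRUE))
    stop_estimation("the boosted learner requires the xgboost package")
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  if (!is.null(base_margin)) xgboost::setinfo(dtrain, "base_margin", base_margin)
  eta <- config$learning_rate
  best <- NULL
  for (h in 0:config$max_halvings) {
    params <- list(objective = objective, max_depth = config$depth,
                   subsample = config$bag_fraction, eta = eta, nthread = 1,
                   # neutral global bias: the base_margin offset must be the
                   # only exposure term on the link scale
                   base_score = if (objective == "count:poisson") 1 else 0.5)
    cv <- withr::with_seed(as.integer(seed), xgboost::xgb.cv(
      params = params, data = dtrain, nrounds = config$tree_range[2],
      nfold = config$nfolds, early_stopping_rounds = 50, verbose = 0))
    best <- cv$best_iteration %||% cv$early_stop$best_iteration
    if (best >= config$tree_range[1] || eta <= 1e-4) break
    eta <- eta / 2
  }
  if (best < config$tree_range[1])
    warning(sprintf(
      "optimal tree count %d below target [%d, %d] after %d halvings",
      best, config$tree_range[1], config$tree_range[2], config$max_halvings))
  fit <- withr::with_seed(as.integer(seed), xgboost::xgb.train(
    params = params, data = dtrain, nrounds = best, verbose = 0))
  list(kind = "xgboost", fit = fit, nrounds = best, eta = eta)
}

predict_learner <- function(learner, newx) {
  if (learner$kind == "glmnet") {
    has_offset <- !is.null(learner$fit$glmnet.fit$offset) &&
      learner$fit$glmnet.fit$offset
    drop(predict(learner$fit, newx = newx, s = "lambda.min",
                 type = "response",
                 newoffset = if (has_offset) rep(0, nrow(newx))))
  } else if (learner$kind == "xgboost") {
    d <- xgboost::xgb.DMatrix(newx)
    xgboost::setinfo(d, "base_margin", rep(0, nrow(newx)))
    drop(predict(learner$fit, d))
  } else stop_invalid("unknown learner kind")
}

## ---- occurrence stage ------------------------------------------------------

checklist_positive <- function(checklists) {
  (!is.na(checklists$count) & checklists$count > 0) | checklists$presence_x
}

checklist_feature_matrix <- function(checklists, landscape, covars,
                                     table = covariate_table(landscape)) {
  cc <- cell_covariates(landscape, checklists$x_m, checklists$y_m, table)
  as.matrix(cc[, covars, drop = FALSE])
}

#' Fit the occurrence stage of a zero-inflated density model
#'
#' Trains a probability-of-occurrence learner on presence/absence derived
#' from checklist counts using all focal covariates at all radii, evaluates
#' AUC on the independent test set, and stores the training prevalence as
#' the suitability threshold.
#'
#' @param train training checklists (counts or presence).
#' @param test independent test checklists for AUC.
#' @param landscape the `landscape`.
#' @param config a [learner_config()].
#' @param seed integer seed (cross-validation folds, boosting).
#' @param covars covariate column names; default all focal columns.
#' @return an `occurrence_fit`: learner, prevalence/threshold, AUC, and
#'   per-cell predicted probabilities.
#' @export
fit_occurrence <- function(train, test, landscape, config = learner_config(),
                           seed = 1, covars = focal_column_names(landscape)) {
  y <- checklist_positive(train)
  if (sum(y) == 0 || sum(!y) == 0)
    stop_estimation("occurrence stage needs both presences and absences in training data")
  table <- covariate_table(landscape)
  x <- checklist_feature_matrix(train, landscape, covars, table)
  learner <- if (config$type == "glmnet") {
    fit_glmnet_learner(x, as.numeric(y), "binomial", NULL, config, seed)
  } else {
    fit_xgboost_learner(x, as.numeric(y), "binary:logistic", NULL, config, seed)
  }
  cell_probs <- predict_learner(learner, as.matrix(table[, covars, drop = FALSE]))
  test_auc <- NA_real_
  if (!is.null(test) && nrow(test)) {
    xt <- checklist_feature_matrix(test, landscape, covars, table)
    scores <- predict_learner(learner, xt)
    yt <- checklist_positive(test)
    test_auc <- if (sum(yt) == 0 || sum(!yt) == 0)
      signal_undefined("test set has a single class; AUC undefined")
    else auc(scores, yt)
  }
  structure(list(learner = learner, covars = covars,
                 prevalence = mean(y), threshold = mean(y),
                 auc = test_auc, cell_probs = cell_probs, config = config),
            class = "occurrence_fit")
}

#' Threshold predicted occurrence at the sample prevalence
#'
#' A cell is suitable iff its predicted probability of occurrence is greater
#' than or equal to the training-set prevalence (ties suitable).
#'
#' @param fit an `occurrence_fit`.
#' @param landscape the `landscape` the fit predicts over.
#' @return a `suitability_mask`: per-cell logical vector and suitable area
#'   (exactly the number of suitable cells times the cell area).
#' @export
threshold_by_prevalence <- function(fit, landscape) {
  stopifnot(inherits(fit, "occurrence_fit"))
  suitable <- fit$cell_probs >= fit$threshold
  structure(list(suitable = suitable,
                 area_ha = sum(suitable) * landscape$cell_area_ha,
                 n_x = landscape$n_x, n_y = landscape$n_y,
                 cell_area_ha = landscape$cell_area_ha),
            class = "suitability_mask")
}

#' Which checklists fall in suitable habitat
#' @param checklists checklist data.frame.
#' @param mask a `suitability_mask`.
#' @param landscape the `landscape`.
#' @return logical vector per checklist.
#' @export
in_suitable <- function(checklists, mask, landscape) {
  mask$suitable[cell_at(landscape, checklists$x_m, checklists$y_m)]
}

## ---- count stage -----------------------------------------------------------

#' Fit the offset-adjusted Poisson count stage
#'
#' Fits a count learner with per-observation exposure `C` (`log C` as a
#' Poisson offset) to checklists in suitable habitat, so that the predicted
#' mean count at a survey is `C` times the predicted density (birds/ha).
#' Density is predicted for every suitable cell; unsuitable cells have
#' density 0.
#'
#' @param train training checklists already restricted to suitable habitat,
#'   with numeric counts.
#' @param offsets offsets data.frame from [compute_offsets()] or
#'   [fixed_offsets()] covering all training surveys with `C > 0`.
#' @param mask a `suitability_mask`.
#' @param landscape the `landscape`.
#' @param config a [learner_config()].
#' @param seed integer seed.
#' @param covars covariate columns; default all focal columns. An empty
#'   vector fits an intercept-only log-linear model.
#' @return a `density_fit`: learner, per-cell density surface, mean density
#'   over suitable cells, and population estimate.
#' @export
fit_density <- function(train, offsets, mask, landscape,
                        config = learner_config(), seed = 1,
                        covars = focal_column_names(landscape)) {
  if (!nrow(train)) stop_estimation("no training surveys in suitable habitat")
  idx <- match(train$survey_id, offsets$survey_id)
  if (anyNA(idx)) stop_invalid("every training survey needs an offset")
  C <- offsets$C[idx]
  if (any(!is.finite(C) | C <= 0)) stop_invalid("offsets C must be positive")
  y <- train$count
  if (anyNA(y)) stop_invalid("count stage requires numeric counts (no 'X')")

  table <- covariate_table(landscape)
  cell_density <- numeric(nrow(table))

  if (all(y == 0)) {
    # Degenerate boundary: no individuals observed; the MLE density is 0.
    learner <- list(kind = "zero")
  } else if (!length(covars)) {
    dat <- data.frame(y = y, logC = log(C))
    fit <- glm(y ~ 1, family = poisson(), offset = logC, data = dat)
    learner <- list(kind = "glm", fit = fit)
    cell_density[mask$suitable] <- exp(coef(fit)[1])
  } else {
    x <- checklist_feature_matrix(train, landscape, covars, table)
    learner <- if (config$type == "glmnet") {
      fit_glmnet_learner(x, y, "poisson", log(C), config, seed)
    } else {
      fit_xgboost_learner(x, y, "count:poisson", log(C), config, seed)
    }
    newx <- as.matrix(table[mask$suitable, covars, drop = FALSE])
    cell_density[mask$suitable] <- predict_learner(learner, newx)
  }

  structure(list(
    learner = learner, covars = covars, config = config,
    cell_density = cell_density, mask = mask,
    mean_density = if (any(mask$suitable)) mean(cell_density[mask$suitable]) else 0,
    population = sum(cell_density) * landscape$cell_area_ha
  ), class = "density_fit")
}

#' Predicted density at survey locations
#' @param fit a `density_fit`.
#' @param landscape the `landscape`.
#' @param checklists checklists to predict for.
#' @return density (birds/ha) at each checklist's containing cell (0 in
#'   unsuitable habitat).
#' @export
predict_density <- function(fit, landscape, checklists) {
  stopifnot(inherits(fit, "density_fit"))
  fit$cell_density[cell_at(landscape, checklists$x_m, checklists$y_m)]
}

#' Predictive correlation on an independent test set
#'
#' Pearson correlation between predicted counts (density at the survey's
#' cell times the survey's offset `C`, zero outside suitable habitat) and
#' observed counts.
#'
#' @param fit a `density_fit`.
#' @param test test checklists with numeric counts.
#' @param test_offsets offsets for the test surveys.
#' @param landscape the `landscape`.
#' @return Pearson r, or `NA` with an undefined-result warning when either
#'   vector has zero variance or fewer than 3 surveys are available.
#' @export
predictive_correlation <- function(fit, test, test_offsets, landscape) {
  idx <- match(test$survey_id, test_offsets$survey_id)
  if (anyNA(idx)) stop_invalid("every test survey needs an offset")
  pred <- predict_density(fit, landscape, test) * test_offsets$C[idx]
  obs <- test$count
  ok <- !is.na(obs)
  if (sum(ok) < 3)
    return(signal_undefined("fewer than 3 test surveys with counts"))
  if (var(pred[ok]) == 0 || var(obs[ok]) == 0)
    return(signal_undefined("zero variance in predictive-correlation inputs"))
  cor(pred[ok], obs[ok])
}

#' Population estimate from a density surface
#'
#' Exact arithmetic: the sum over suitable cells of density times cell area.
#'
#' @param fit a `density_fit`.
#' @param mask a `suitability_mask` aligned with the fit's landscape.
#' @return estimated number of birds.
#' @export
estimate_population <- function(fit, mask = fit$mask) {
  stopifnot(inherits(fit, "density_fit"))
  if (length(mask$suitable) != length(fit$cell_density))
    stop_invalid("mask and density surface are misaligned")
  sum(fit$cell_density[mask$suitable]) * mask$cell_area_ha
}
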