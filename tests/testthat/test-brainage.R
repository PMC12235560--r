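test_that("unregularized fit recovers an exact linear age signal", {
  S <- withr::with_seed(1, matrix(rnorm(200), 50, 4))
  ages <- 2 * S[, 1] + 30
  m <- train_age_model(S, ages, k = 1)
  expect_equal(m$weights, 2, tolerance = 1e-8)
  expect_equal(m$intercept, 30, tolerance = 1e-8)
  expect_equal(predict_age(m, S), ages, tolerance = 1e-8)
})

test_that("singular unregularized designs fail with a pointer to regularization", {
  S <- withr::with_seed(2, matrix(rnorm(20), 4, 5))
  ages <- rnorm(4)
  expect_error(train_age_model(S, ages, k = 5), "regulariz")
  S2 <- cbind(1:6, 1:6) # collinear columns
  expect_error(train_age_model(S2, rnorm(6), k = 2), "regulariz")
})

test_that("ridge shrinks to the mean-age model as lambda grows", {
  S <- withr::with_seed(3, matrix(rnorm(120), 30, 4))
  ages <- withr::with_seed(4, runif(30, 20, 60))
  m <- train_age_model(S, ages, k = 4, regularization = "l2", lambda = 1e12)
  expect_true(all(abs(m$weights) < 1e-8))
  expect_equal(m$intercept, mean(ages), tolerance = 1e-6)
  # lambda -> 0 approaches the OLS fit
  m0 <- train_age_model(S, ages, k = 4, regularization = "l2", lambda = 1e-10)
  ols <- train_age_model(S, ages, k = 4)
  expect_equal(m0$weights, ols$weights, tolerance = 1e-6)
})

test_that("ridge matches an independent augmented-least-squares solution", {
  # oracle: ridge as OLS on the design augmented with sqrt(lambda) * I rows
  for (seed in 1:5) {
    S <- withr::with_seed(seed, matrix(rnorm(35 * 6), 35, 6))
    ages <- withr::with_seed(seed + 100, runif(35, 18, 80))
    lambda <- withr::with_seed(seed + 200, 10^runif(1, -2, 2))
    Sc <- scale(S, center = TRUE, scale = FALSE)
    yc <- ages - mean(ages)
    aug <- stats::lm.fit(rbind(Sc, sqrt(lambda) * diag(6)), c(yc, rep(0, 6)))
    m <- train_age_model(S, ages, k = 6, regularization = "l2", lambda = lambda)
    expect_equal(m$weights, unname(aug$coefficients), tolerance = 1e-8)
    expect_equal(m$intercept,
                 mean(ages) - sum(colMeans(S) * aug$coefficients),
                 tolerance = 1e-8)
  }
})

test_that("lasso with a large penalty zeroes the slopes", {
  S <- withr::with_seed(5, matrix(rnorm(120), 30, 4))
  ages <- withr::with_seed(6, runif(30, 20, 60))
  m <- train_age_model(S, ages, k = 4, regularization = "l1", lambda = 1e6)
  expect_true(all(m$weights == 0))
  expect_equal(m$intercept, mean(ages), tolerance = 1e-6)
  # mild penalty keeps a fit close to OLS on a strong signal
  ages2 <- 3 * S[, 2] + 40
  m2 <- train_age_model(S, ages2, k = 4, regularization = "l1", lambda = 1e-6)
  expect_equal(m2$weights[2], 3, tolerance = 1e-3)
})

test_that("predict_age is affine in the scores", {
  S <- withr::with_seed(7, matrix(rnorm(60), 15, 4))
  ages <- withr::with_seed(8, runif(15, 20, 60))
  m <- train_age_model(S, ages, k = 3)
  expect_equal(predict_age(m, matrix(0, 2, 3)), rep(m$intercept, 2))
  a <- 2.5
  expect_equal(predict_age(m, a * S[, 1:3]) - m$intercept,
               a * (predict_age(m, S[, 1:3]) - m$intercept), tolerance = 1e-10)
  expect_error(predict_age(m, S[, 1:2, drop = FALSE]), "columns")
})

test_that("BAG is elementwise predicted minus chronological age", {
  expect_equal(compute_bag(40, 35), 5)
  expect_equal(compute_bag(c(30, 40), c(30, 40)), c(0, 0))
  p <- withr::with_seed(9, runif(50, 20, 80))
  y <- withr::with_seed(10, runif(50, 20, 80))
  expect_equal(mean(compute_bag(p, y)), mean(p) - mean(y))
  expect_error(compute_bag(1:3, 1:2), "length")
})

test_that("age-bias adjustment is the OLS residual of BAG on age", {
  ages <- withr::with_seed(11, runif(100, 18, 50))
  delta1 <- 0.5 * ages - 10
  b <- fit_bag_adjustment(delta1, ages)
  expect_equal(unname(b["slope"]), 0.5, tolerance = 1e-10)
  expect_equal(unname(b["intercept"]), -10, tolerance = 1e-8)
  bc <- fit_bag_adjustment(rep(3.2, 100), ages)
  expect_equal(unname(bc["slope"]), 0, tolerance = 1e-10)
  expect_equal(unname(bc["intercept"]), 3.2, tolerance = 1e-10)
  expect_error(fit_bag_adjustment(delta1, rep(30, 100)), "constant")
  # identity adjustment
  expect_equal(adjust_bag(delta1, ages, c(slope = 0, intercept = 0)), delta1)
  # residual oracle: delta2 equals lm() residuals
  noisy <- delta1 + withr::with_seed(12, rnorm(100))
  b2 <- fit_bag_adjustment(noisy, ages)
  d2 <- adjust_bag(noisy, ages, b2)
  expect_equal(d2, unname(stats::resid(stats::lm(noisy ~ ages))),
               tolerance = 1e-10)
  expect_lt(abs(mean(d2)), 1e-8)
  expect_lt(abs(cor(d2, ages)), 1e-8)
})

test_that("bag adjustment slope is null when BAG is independent of age", {
  slopes <- ses <- numeric(20)
  for (r in 1:20) {
    withr::with_seed(300 + r, {
      ages <- runif(500, 18, 50)
      delta1 <- rnorm(500, sd = 3)
    })
    fit <- stats::lm(delta1 ~ ages)
    slopes[r] <- fit_bag_adjustment(delta1, ages)["slope"]
    ses[r] <- summary(fit)$coefficients[2, 2]
  }
  expect_true(mean(abs(slopes) < 3 * ses) >= 0.9)
})

test_that("cv curve identifies a noiseless single-component signal", {
  S <- withr::with_seed(13, matrix(rnorm(600), 60, 10))
  ages <- 1.5 * S[, 1] + 35
  curve <- cv_select_components(S, ages, k_range = 1:10, folds = 10, seed = 1)
  expect_equal(curve$k_star, 1)
  expect_lt(curve$mean_rmse[1], 1e-6)
  # singleton range is honoured regardless of fit quality
  c5 <- cv_select_components(S, ages, k_range = 5, folds = 10, seed = 1)
  expect_equal(c5$k_star, 5)
  expect_error(cv_select_components(S[1:4, ], ages[1:4], 1:2, folds = 10),
               "folds")
})

test_that("fold splits are seeded, near-equal and shared across k", {
  S <- withr::with_seed(14, matrix(rnorm(303 * 5), 303, 5))
  ages <- withr::with_seed(15, runif(303, 18, 50))
  c1 <- cv_select_components(S, ages, k_range = 1:3, folds = 10, seed = 9)
  c2 <- cv_select_components(S, ages, k_range = 1:3, folds = 10, seed = 9)
  expect_identical(c1$fold_id, c2$fold_id)
  expect_identical(c1$mean_rmse, c2$mean_rmse)
  expect_true(all(abs(table(c1$fold_id) - 303 / 10) <= 1))
})

test_that("out-of-fold predictions never come from a model that saw the scan", {
  S <- withr::with_seed(16, matrix(rnorm(40 * 3), 40, 3))
  ages <- withr::with_seed(17, runif(40, 18, 50))
  cvp <- cv_predictions(S, ages, k = 2, folds = 5, seed = 3)
  for (i in seq_len(40)) {
    expect_false(i %in% cvp$trained_on[[i]])
    expect_true(all(cvp$fold_id[cvp$trained_on[[i]]] != cvp$fold_id[i]))
  }
})

test_that("within-session protocol gives CV predictions only to the training session", {
  cfg <- sim_config(n_train = 10, n_test_subjects = 40, n_features = 20,
                    n_latent = 0, noise_sd = 0, subject_sd = 0,
                    motion_bias = 0, seed = 21)
  coh <- generate_motion_cohort(cfg)
  res <- train_within_session(coh$features, coh$records, "STAND",
                              k_range = 1, folds = 5, seed = 1)
  expect_true(all(res$predictions$from_cv == (res$predictions$session == "STAND")))
  # noiseless age signal: CV predictions reproduce the ages
  tr <- res$predictions[res$predictions$from_cv, ]
  expect_lt(sqrt(mean((tr$predicted_age - tr$age)^2)), 1e-6)
  # no training scan predicted by a model trained on it
  for (i in seq_along(res$fold_info$scan_id)) {
    expect_false(i %in% res$fold_info$trained_on[[i]])
  }
  # symmetry: training on HM2 moves the CV flag, nothing else about the design
  res2 <- train_within_session(coh$features, coh$records, "HM2",
                               k_range = 1, folds = 5, seed = 1)
  expect_true(all(res2$predictions$from_cv == (res2$predictions$session == "HM2")))
  expect_identical(res$predictions$scan_id, res2$predictions$scan_id)
  # duplicate subject within the training session is rejected
  rec_bad <- coh$records
  rec_bad$subject_id[rec_bad$session == "STAND"][2] <-
    rec_bad$subject_id[rec_bad$session == "STAND"][1]
  expect_error(train_within_session(coh$features, rec_bad, "STAND",
                                    k_range = 1, folds = 5),
               "duplicate subject")
})
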