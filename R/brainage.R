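#' Train a (regularized) linear brain age model on PC scores
#'
#' Least-squares regression of chronological age on the first `k` principal
#' component scores, optionally with L2 (ridge) or L1 (lasso) penalties on
#' the slopes. The intercept is never penalized. The ridge solution is the
#' exact closed form `(Sc' Sc + lambda I)^-1 Sc' yc` on centred data; the
#' lasso is solved by coordinate descent (glmnet) with the penalty expressed
#' on the same `sum |beta|` scale (total, not per-observation).
#'
#' @param scores Numeric score matrix, scans x components.
#' @param ages Chronological ages in years.
#' @param k Number of leading score columns to use.
#' @param regularization One of `"none"`, `"l2"`, `"l1"`.
#' @param lambda Penalty strength (`>= 0`); ignored for `"none"`. If `NULL`
#'   for a penalized fit, chosen by 5-fold cross-validation over a 20-point
#'   log-spaced grid (see [select_lambda()]).
#' @param lambda_seed Seed for the internal lambda cross-validation fold
#'   split (only used when `lambda` is `NULL`).
#' @return An object of class `age_model`: `k`, `regularization`, `lambda`,
#'   `weights` (length-`k` slopes, years per score-unit), `intercept`
#'   (years).
#' @export
train_age_model <- function(scores, ages, k, regularization = c("none", "l2", "l1"),
                            lambda = NULL, lambda_seed = 1L) {
  regularization <- match.arg(regularization)
  scores <- as.matrix(scores)
  if (k > ncol(scores)) stop("k exceeds the number of score columns", call. = FALSE)
  if (length(ages) != nrow(scores)) stop("scores and ages differ in length", call. = FALSE)
  S <- scores[, seq_len(k), drop = FALSE]
  n <- nrow(S)
  if (regularization == "none") {
    if (n <= k) {
      stop("more components than scans: unregularized fit is singular; ",
           "use L1 or L2 regularization", call. = FALSE)
    }
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, S), ages)
    if (any(is.na(fit$coefficients))) {
      stop("singular design in unregularized fit; use L1 or L2 regularization",
           call. = FALSE)
    }
    weights <- fit$coefficients[-1]
    intercept <- fit$coefficients[1]
    lambda <- 0
  } else {
    if (is.null(lambda)) {
      lambda <- select_lambda(S, ages, regularization, seed = lambda_seed)
    }
    if (lambda < 0) stop("lambda must be non-negative", call. = FALSE)
    if (regularization == "l2") {
      sol <- ridge_closed_form(S, ages, lambda)
      weights <- sol$weights; intercept <- sol$intercept
    } else {
      # glmnet objective is RSS/(2n) + lambda_g * |beta|_1
      fit <- glmnet::glmnet(S, ages, alpha = 1, lambda = lambda / n,
                            standardize = FALSE, intercept = TRUE,
                            thresh = 1e-12)
      weights <- as.numeric(fit$beta)
      intercept <- as.numeric(fit$a0)
    }
  }
  names(weights) <- colnames(S)
  out <- list(k = k, regularization = regularization, lambda = lambda,
              weights = unname(weights), weight_names = colnames(S),
              intercept = unname(intercept))
  class(out) <- "age_model"
  out
}

# Exact ridge: centre scores and ages, solve the penalized normal equations,
# reconstruct the unpenalized intercept.
ridge_closed_form <- function(S, y, lambda) {
  n <- nrow(S); k <- ncol(S)
  smean <- colMeans(S); ymean <- mean(y)
  Sc <- sweep(S, 2, smean, "-")
  yc <- y - ymean
  A <- crossprod(Sc) + diag(lambda, k)
  beta <- solve(A, crossprod(Sc, yc))
  list(weights = drop(beta), intercept = ymean - sum(smean * beta))
}

#' Choose a penalty strength by inner cross-validation
#'
#' 5-fold cross-validation over a 20-point log-spaced lambda grid, selecting
#' the lambda with minimum mean out-of-fold RMSE (smallest lambda on ties).
#' The grid runs from `1e-4 * lambda_max` to `lambda_max`, where
#' `lambda_max` is the classical smallest-all-zero lasso penalty
#' `max |Sc' yc|` (also used as a reasonable upper anchor for ridge).
#'
#' @inheritParams train_age_model
#' @param folds Number of inner folds.
#' @param seed Seed for the fold split.
#' @return The selected lambda (scalar).
#' @export
select_lambda <- function(scores, ages, regularization = c("l2", "l1"),
                          folds = 5, seed = 1L) {
  regularization <- match.arg(regularization)
  S <- as.matrix(scores)
  n <- nrow(S)
  Sc <- sweep(S, 2, colMeans(S), "-")
  lam_max <- max(abs(crossprod(Sc, ages - mean(ages))))
  if (lam_max <= 0) lam_max <- 1
  grid <- exp(seq(log(1e-4 * lam_max), log(lam_max), length.out = 20))
  fold_id <- make_folds(n, folds, seed)
  rmse <- sapply(grid, function(lam) {
    errs <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      m <- train_age_model(S[tr, , drop = FALSE], ages[tr], k = ncol(S),
                           regularization = regularization, lambda = lam)
      pred <- predict_age(m, S[!tr, , drop = FALSE])
      sqrt(mean((pred - ages[!tr])^2))
    }, numeric(1))
    mean(errs)
  })
  grid[which.min(rmse)]
}

# Seeded permutation into `folds` near-equal folds.
make_folds <- function(n, folds, seed) {
  if (folds < 2) stop("need at least 2 folds", call. = FALSE)
  if (n < folds) stop("fewer rows (", n, ") than folds (", folds, ")", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    sample(rep_len(seq_len(folds), n))
  })
}

#' Cross-validated selection of the number of principal components
#'
#' For each candidate `k`, fits the (optionally regularized) linear age
#' model on the first `k` score columns within each training fold and
#' accumulates out-of-fold root-mean-squared error; the fold split is a
#' seeded random partition shared across all `k`, so the curves are
#' comparable. The selected `k*` is the smallest `k` attaining the minimum
#' mean CV-RMSE (parsimony tie-break).
#'
#' @inheritParams train_age_model
#' @param k_range Integer vector of candidate component counts.
#' @param folds Number of CV folds (default 10).
#' @param seed Seed for the fold split.
#' @param lambda Fixed penalty for penalized fits; `NULL` selects it by
#'   inner CV within each outer training fold (slower).
#' @return An object of class `cv_curve`: `k_values`, `mean_rmse` (years),
#'   `k_star`, `fold_id` (the fold assignment used), `folds`, `seed`,
#'   `regularization`, `lambda`.
#' @export
cv_select_components <- function(scores, ages, k_range, folds = 10,
                                 regularization = c("none", "l2", "l1"),
                                 lambda = NULL, seed = 1L) {
  regularization <- match.arg(regularization)
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (length(ages) != n) stop("scores and ages differ in length", call. = FALSE)
  k_range <- sort(unique(as.integer(k_range)))
  if (max(k_range) > ncol(scores)) {
    stop("k_range exceeds the available components", call. = FALSE)
  }
  fold_id <- make_folds(n, folds, seed)
  sqerr <- matrix(NA_real_, nrow = folds, ncol = length(k_range))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    for (j in seq_along(k_range)) {
      k <- k_range[j]
      m <- train_age_model(scores[tr, , drop = FALSE], ages[tr], k = k,
                           regularization = regularization, lambda = lambda,
                           lambda_seed = stage_seed(seed, 1000L + f))
      pred <- predict_age(m, scores[!tr, , drop = FALSE])
      sqerr[f, j] <- sqrt(mean((pred - ages[!tr])^2))
    }
  }
  mean_rmse <- colMeans(sqerr)
  # parsimony tie-break: smallest k attaining the minimum, with a relative
  # tolerance so exact fits are not separated by floating-point fuzz
  tol <- max(1e-12, 1e-8 * min(mean_rmse))
  k_star <- k_range[which(mean_rmse <= min(mean_rmse) + tol)[1]]
  out <- list(k_values = k_range, mean_rmse = mean_rmse, k_star = k_star,
              fold_id = fold_id, folds = folds, seed = as.integer(seed),
              regularization = regularization, lambda = lambda)
  class(out) <- "cv_curve"
  out
}

#' @export
print.cv_curve <- function(x, ...) {
  cat(sprintf("CV curve over k = %d..%d (%d folds, %s regularization)\n",
              min(x$k_values), max(x$k_values), x$folds, x$regularization))
  cat(sprintf("  k* = %d with mean CV-RMSE %.3f years\n", x$k_star,
              min(x$mean_rmse)))
  invisible(x)
}

#' Out-of-fold age predictions for a fixed component count
#'
#' Refits the age model on each training fold and predicts the held-out
#' fold, so every scan's prediction comes from a model that never saw it.
#' Used both to anchor the age-bias adjustment on training-cohort
#' cross-validated predictions and for the within-session protocol.
#'
#' @inheritParams cv_select_components
#' @param k Component count to use.
#' @param fold_id Optional precomputed fold assignment (from
#'   [cv_select_components()]); if `NULL`, a fresh seeded split is made.
#' @return A list: `predictions` (one per scan, out-of-fold), `fold_id`,
#'   and `trained_on` — for each scan, the sorted indices of the scans its
#'   predicting model was trained on (bookkeeping that lets callers verify
#'   the no-self-prediction protocol).
#' @export
cv_predictions <- function(scores, ages, k, folds = 10,
                           regularization = c("none", "l2", "l1"),
                           lambda = NULL, seed = 1L, fold_id = NULL) {
  regularization <- match.arg(regularization)
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (is.null(fold_id)) fold_id <- make_folds(n, folds, seed)
  preds <- numeric(n)
  trained_on <- vector("list", n)
  for (f in sort(unique(fold_id))) {
    te <- which(fold_id == f)
    tr <- which(fold_id != f)
    m <- train_age_model(scores[tr, , drop = FALSE], ages[tr], k = k,
                         regularization = regularization, lambda = lambda,
                         lambda_seed = stage_seed(seed, 2000L + f))
    preds[te] <- predict_age(m, scores[te, , drop = FALSE])
    trained_on[te] <- list(tr)
  }
  list(predictions = preds, fold_id = fold_id, trained_on = trained_on)
}

#' Predict brain age from PC scores
#'
#' @param model An [train_age_model()] result.
#' @param scores Score matrix with at least `model$k` columns.
#' @return Predicted ages in years (`scores[, 1:k] %*% weights + intercept`).
#' @export
predict_age <- function(model, scores) {
  stopifnot(inherits(model, "age_model"))
  scores <- as.matrix(scores)
  if (ncol(scores) < model$k) {
    stop("score matrix has ", ncol(scores), " columns but the model needs ",
         model$k, call. = FALSE)
  }
  drop(scores[, seq_len(model$k), drop = FALSE] %*% model$weights) + model$intercept
}

#' Brain age gap (BAG)
#'
#' The raw brain age gap: predicted minus chronological age, per scan.
#'
#' @param predicted Predicted ages (years).
#' @param chronological Chronological ages (years).
#' @return `predicted - chronological`, in years.
#' @export
#' @examples
#' compute_bag(40, 35)
compute_bag <- function(predicted, chronological) {
  if (length(predicted) != length(chronological)) {
    stop("predicted and chronological ages differ in length", call. = FALSE)
  }
  predicted - chronological
}

#' Fit the age-bias adjustment of the brain age gap
#'
#' Raw BAG is mechanically correlated with chronological age (regression to
#' the mean of the predictor). This fits the ordinary least squares of BAG
#' on age, whose coefficients are then used by [adjust_bag()] to residualize
#' BAG on age.
#'
#' @param delta1 Raw BAG values (years).
#' @param ages Chronological ages (years).
#' @return Named numeric `c(slope, intercept)` of the BAG-on-age line.
#' @export
fit_bag_adjustment <- function(delta1, ages) {
  if (length(delta1) != length(ages)) {
    stop("delta1 and ages differ in length", call. = FALSE)
  }
  if (length(ages) < 3) stop("need at least 3 scans to fit the adjustment", call. = FALSE)
  if (stats::var(ages) == 0) stop("ages are constant: adjustment slope is undefined", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, ages), delta1)
  c(slope = unname(fit$coefficients[2]), intercept = unname(fit$coefficients[1]))
}

#' Age-bias-adjusted brain age gap
#'
#' Subtracts the fitted linear age trend from the raw BAG:
#' `delta2 = delta1 - (slope * age + intercept)`. When `beta2` was fitted on
#' the same sample, the adjusted BAG has exactly zero mean and zero
#' correlation with age (OLS orthogonality); fitted on a reference sample
#' (e.g. training-cohort cross-validated BAG) it removes the training-
#' anchored age bias from test scans without leaking test structure.
#'
#' @param delta1 Raw BAG values (years).
#' @param ages Chronological ages (years).
#' @param beta2 `c(slope, intercept)` from [fit_bag_adjustment()].
#' @return Adjusted BAG values (years).
#' @export
adjust_bag <- function(delta1, ages, beta2) {
  if (length(delta1) != length(ages)) {
    stop("delta1 and ages differ in length", call. = FALSE)
  }
  if (length(beta2) != 2) stop("beta2 must be c(slope, intercept)", call. = FALSE)
  delta1 - (beta2[["slope"]] * ages + beta2[["intercept"]])
}

#' Within-session training protocol
#'
#' Trains the brain age model on the scans of a single session of a
#' repeated-session cohort: scaler and PCA are fitted on that session,
#' `k` is selected by cross-validation, the training-session scans receive
#' out-of-fold predictions (no scan is predicted by a model trained on it),
#' and the remaining sessions are predicted by a final model refitted on all
#' training-session scans. The age-bias adjustment is fitted on the training
#' session's cross-validated (BAG, age) pairs and applied to every scan, so
#' all sessions feed the same adjustment chain.
#'
#' @param features Feature matrix for the whole cohort (all sessions).
#' @param records Matching scan metadata (needs `scan_id`, `subject_id`,
#'   `age`, `session`).
#' @param train_session Session label to train on (e.g. `"STAND"`).
#' @param k_range Candidate component counts for CV selection.
#' @param folds CV folds.
#' @param regularization,lambda Passed to the age model.
#' @param seed Seed for all fold splits.
#' @return A list: `predictions` data frame (`scan_id`, `subject_id`, `age`,
#'   `session`, `predicted_age`, `delta1`, `delta2`, `from_cv`), `model`
#'   (the full-session refit), `scaler`, `pca`, `cv_curve`, `beta2`, and
#'   `fold_info` (`fold_id` and `trained_on` bookkeeping for the training
#'   session, in training-session scan order).
#' @export
train_within_session <- function(features, records, train_session = "STAND",
                                 k_range = 1:20, folds = 10,
                                 regularization = "none", lambda = NULL,
                                 seed = 1L) {
  features <- as_feature_matrix(features)
  stopifnot(nrow(features) == nrow(records))
  in_train <- records$session == train_session
  if (!any(in_train)) stop("no scans in session '", train_session, "'", call. = FALSE)
  if (anyDuplicated(records$subject_id[in_train])) {
    stop("duplicate subject within session '", train_session,
         "': one scan per subject required", call. = FALSE)
  }
  Xtr <- features[in_train, , drop = FALSE]
  ages_tr <- records$age[in_train]
  scaler <- fit_feature_scaler(Xtr)
  pca <- fit_pca(apply_scaler(Xtr, scaler))
  k_range <- k_range[k_range <= ncol(pca$loadings) & k_range < sum(in_train)]
  scores_tr <- project_scores(Xtr, scaler, pca, k = max(k_range))
  curve <- cv_select_components(scores_tr, ages_tr, k_range, folds = folds,
                                regularization = regularization,
                                lambda = lambda, seed = seed)
  cvp <- cv_predictions(scores_tr, ages_tr, k = curve$k_star, folds = folds,
                        regularization = regularization, lambda = lambda,
                        seed = seed, fold_id = curve$fold_id)
  model <- train_age_model(scores_tr, ages_tr, k = curve$k_star,
                           regularization = regularization, lambda = lambda,
                           lambda_seed = stage_seed(seed, 3000L))
  pred <- numeric(nrow(features))
  pred[in_train] <- cvp$predictions
  if (any(!in_train)) {
    scores_oos <- project_scores(features[!in_train, , drop = FALSE],
                                 scaler, pca, k = curve$k_star)
    pred[!in_train] <- predict_age(model, scores_oos)
  }
  delta1 <- compute_bag(pred, records$age)
  beta2 <- fit_bag_adjustment(delta1[in_train], ages_tr)
  delta2 <- adjust_bag(delta1, records$age, beta2)
  predictions <- data.frame(
    scan_id = records$scan_id, subject_id = records$subject_id,
    age = records$age, session = records$session,
    predicted_age = pred, delta1 = delta1, delta2 = delta2,
    from_cv = in_train, stringsAsFactors = FALSE
  )
  list(predictions = predictions, model = model, scaler = scaler, pca = pca,
       cv_curve = curve, beta2 = beta2,
       fold_info = list(fold_id = cvp$fold_id, trained_on = cvp$trained_on,
                        scan_id = records$scan_id[in_train]))
}
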