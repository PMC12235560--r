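#' Load and validate a feature table plus scan metadata
#'
#' Reads a TSV feature table (`scan_id` first column, one column per
#' feature) and a CSV metadata table (`scan_id`, `subject_id`, `age`, and
#' optionally `sex`, `session`, `rating`, `euler_raw`), checks that the scan
#' IDs match one-to-one, and returns the typed merge in feature-table row
#' order.
#'
#' @param features_path Path to the TSV feature table.
#' @param meta_path Path to the CSV metadata table.
#' @return A list: `features` (numeric matrix, rownames = scan IDs) and
#'   `records` (data frame).
#' @export
load_scan_table <- function(features_path, meta_path) {
  for (p in c(features_path, meta_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  feat <- utils::read.delim(features_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (names(feat)[1] != "scan_id") {
    stop("feature table must have 'scan_id' as its first column", call. = FALSE)
  }
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  for (col in c("scan_id", "subject_id", "age")) {
    if (!col %in% names(meta)) {
      stop("metadata is missing required column '", col, "'", call. = FALSE)
    }
  }
  if (anyDuplicated(feat$scan_id)) {
    stop("duplicate scan_id in feature table: ",
         paste(unique(feat$scan_id[duplicated(feat$scan_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(meta$scan_id)) {
    stop("duplicate scan_id in metadata: ",
         paste(unique(meta$scan_id[duplicated(meta$scan_id)]), collapse = ", "),
         call. = FALSE)
  }
  only_feat <- setdiff(feat$scan_id, meta$scan_id)
  only_meta <- setdiff(meta$scan_id, feat$scan_id)
  if (length(only_feat) || length(only_meta)) {
    stop("scan_id mismatch between features and metadata; ",
         if (length(only_feat)) paste0("missing from metadata: ",
                                       paste(only_feat, collapse = ", "), "; ") else "",
         if (length(only_meta)) paste0("missing from features: ",
                                       paste(only_meta, collapse = ", ")) else "",
         call. = FALSE)
  }
  X <- as.matrix(feat[, -1, drop = FALSE])
  if (!is.numeric(X)) stop("feature columns must be numeric", call. = FALSE)
  rownames(X) <- feat$scan_id
  records <- meta[match(feat$scan_id, meta$scan_id), , drop = FALSE]
  rownames(records) <- NULL
  if (any(!is.finite(records$age)) || any(records$age <= 0)) {
    stop("ages must be positive and finite; offending scan(s): ",
         paste(records$scan_id[!is.finite(records$age) | records$age <= 0],
               collapse = ", "), call. = FALSE)
  }
  if ("session" %in% names(records)) {
    bad <- !records$session %in% c("STAND", "HM1", "HM2") & !is.na(records$session)
    if (any(bad)) {
      stop("invalid session label(s) for scan(s): ",
           paste(records$scan_id[bad], collapse = ", "),
           " (expected STAND/HM1/HM2)", call. = FALSE)
    }
  }
  if ("rating" %in% names(records)) {
    bad <- !is.na(records$rating) & !records$rating %in% 0:5
    if (any(bad)) {
      stop("rating out of range 0..5 for scan(s): ",
           paste(records$scan_id[bad], collapse = ", "), call. = FALSE)
    }
  }
  list(features = X, records = records)
}

#' Run the full synthetic motion experiment in memory
#'
#' One-call composition of the whole analysis: simulate training and
#' repeated-session motion cohorts, fit the training-anchored scaler and
#' PCA, select the component count by 10-fold cross-validated RMSE, train
#' the age model, anchor the age-bias adjustment on training-cohort
#' cross-validated BAG, project and predict the motion cohort, and fit the
#' requested mixed models and per-component screens.
#'
#' @param config A [sim_config()]; its `seed` drives every stage.
#' @param k_range Candidate component counts.
#' @param folds CV folds.
#' @param regularization,lambda Age-model penalty settings.
#' @param q FDR level for the per-component screens.
#' @param lmm_models Character subset of `c("session", "rating", "euler")`:
#'   which adjusted-BAG mixed models to fit (Euler-on-session/rating models
#'   are always fitted when `"euler"` is included).
#' @param pc_tests Logical: run the per-component screens (session and
#'   rating) on the projected scores.
#' @param beta2_sample `"train"` (default) fits the age-bias adjustment on
#'   training-cohort cross-validated BAG; `"test"` refits it on the test
#'   sample (sensitivity option).
#' @return A list bundling every stage: `config`, `train`, `test`, `scaler`,
#'   `pca`, `cv_curve`, `model`, `beta2`, `train_metrics` (CV r and RMSE on
#'   the training cohort), `predictions` (per-scan data frame with
#'   `predicted_age`, `delta1`, `delta2`, `euler_norm`), `lmm` (list of
#'   `lmm_result` by name), `fdr` (list of `fdr_report`), `agreement`
#'   (intra-rater statistics from a seeded second rating pass).
#' @export
run_experiment <- function(config = sim_config(),
                           k_range = 1:20, folds = 10,
                           regularization = "none", lambda = NULL,
                           q = 0.05,
                           lmm_models = c("session", "rating", "euler"),
                           pc_tests = TRUE,
                           beta2_sample = c("train", "test")) {
  beta2_sample <- match.arg(beta2_sample)
  train <- generate_training_cohort(config)
  test <- generate_motion_cohort(config)

  scaler <- fit_feature_scaler(train$features)
  pca <- fit_pca(apply_scaler(train$features, scaler))
  k_range <- k_range[k_range <= ncol(pca$loadings)]
  scores_tr <- project_scores(train$features, scaler, pca, k = max(k_range))
  ages_tr <- train$records$age
  cv_seed <- stage_seed(config$seed, 53L)
  curve <- cv_select_components(scores_tr, ages_tr, k_range, folds = folds,
                                regularization = regularization,
                                lambda = lambda, seed = cv_seed)
  model <- train_age_model(scores_tr, ages_tr, k = curve$k_star,
                           regularization = regularization, lambda = lambda,
                           lambda_seed = stage_seed(config$seed, 59L))
  cvp <- cv_predictions(scores_tr, ages_tr, k = curve$k_star, folds = folds,
                        regularization = regularization, lambda = lambda,
                        seed = cv_seed, fold_id = curve$fold_id)
  delta1_tr <- compute_bag(cvp$predictions, ages_tr)
  train_metrics <- list(
    cv_r = stats::cor(cvp$predictions, ages_tr),
    cv_rmse = sqrt(mean((cvp$predictions - ages_tr)^2)),
    k_star = curve$k_star
  )

  scores_te <- project_scores(test$features, scaler, pca, k = curve$k_star)
  pred_te <- predict_age(model, scores_te)
  delta1_te <- compute_bag(pred_te, test$records$age)
  beta2 <- if (beta2_sample == "train") {
    fit_bag_adjustment(delta1_tr, ages_tr)
  } else {
    fit_bag_adjustment(delta1_te, test$records$age)
  }
  delta2_te <- adjust_bag(delta1_te, test$records$age, beta2)

  predictions <- test$records
  predictions$predicted_age <- pred_te
  predictions$delta1 <- delta1_te
  predictions$delta2 <- delta2_te
  predictions$euler_norm <- normalize_euler(predictions$euler_raw)

  lmm <- list()
  for (m in intersect(lmm_models, c("session", "rating", "euler"))) {
    lmm[[paste0("bag_", m)]] <- fit_lmm(predictions, outcome = "delta2",
                                        predictor = m)
  }
  if ("euler" %in% lmm_models) {
    lmm$euler_session <- fit_lmm(predictions, outcome = "euler_norm",
                                 predictor = "session")
    lmm$euler_rating <- fit_lmm(predictions, outcome = "euler_norm",
                                predictor = "rating")
  }

  fdr <- list()
  if (isTRUE(pc_tests)) {
    fdr$session <- pc_motion_tests(scores_te, predictions, "session", q = q,
                                   explained_variance = pca$explained_variance)
    fdr$rating <- pc_motion_tests(scores_te, predictions, "rating", q = q,
                                  explained_variance = pca$explained_variance)
  }

  # seeded second rating pass over the same severities emulates the
  # blind intra-rater repeat
  rating2 <- assign_visual_ratings(test$truth$severities,
                                   config$rating_noise_sd,
                                   seed = stage_seed(config$seed, 61L))
  agreement <- rater_agreement(predictions$rating, rating2)

  list(config = config, train = train, test = test, scaler = scaler,
       pca = pca, cv_curve = curve, model = model, beta2 = beta2,
       train_metrics = train_metrics, predictions = predictions,
       scores_test = scores_te, lmm = lmm, fdr = fdr, agreement = agreement)
}

#' Run the synthetic experiment and write a report bundle
#'
#' Wraps [run_experiment()] and writes every artifact to `out_dir`:
#' the model directory (`model/` with scaler, PCA, age model, adjustment
#' and CV curve as JSON), `predictions.csv`, one `lmm_<name>.json` per
#' fitted mixed model, `fdr_<predictor>.csv` per screen, `agreement.json`,
#' and a human-readable `report.md` summarizing session contrasts, rating
#' and Euler slopes, the CV curve and agreement. Every output is stamped
#' with the configuration hash and seed; rerunning with an identical
#' configuration reproduces the bundle.
#'
#' @inheritParams run_experiment
#' @param out_dir Output directory (created if absent).
#' @param ... Passed on to [run_experiment()].
#' @return Invisibly, the [run_experiment()] bundle with `paths` attached.
#' @export
run_pipeline <- function(config = sim_config(), out_dir, ...) {
  res <- run_experiment(config, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- config_hash(config)
  stamp <- list(config_hash = cfg_hash, seed = config$seed)

  model_dir <- file.path(out_dir, "model")
  save_model_dir(list(scaler = res$scaler, pca = res$pca, model = res$model,
                      beta2 = res$beta2, cv_curve = res$cv_curve,
                      stamp = stamp), model_dir)

  pred_path <- file.path(out_dir, "predictions.csv")
  utils::write.csv(res$predictions, pred_path, row.names = FALSE, quote = FALSE)

  lmm_paths <- character(0)
  for (nm in names(res$lmm)) {
    p <- file.path(out_dir, paste0("lmm_", nm, ".json"))
    write_json_file(c(lmm_as_list(res$lmm[[nm]]), stamp), p)
    lmm_paths[nm] <- p
  }
  fdr_paths <- character(0)
  for (nm in names(res$fdr)) {
    p <- file.path(out_dir, paste0("fdr_", nm, ".csv"))
    utils::write.csv(res$fdr[[nm]]$table, p, row.names = FALSE, quote = FALSE)
    fdr_paths[nm] <- p
  }
  agree_path <- file.path(out_dir, "agreement.json")
  write_json_file(c(res$agreement, stamp), agree_path)

  report_path <- file.path(out_dir, "report.md")
  writeLines(render_report(res, stamp), report_path)

  res$paths <- c(list(model = model_dir, predictions = pred_path,
                      agreement = agree_path, report = report_path),
                 lmm = list(lmm_paths), fdr = list(fdr_paths))
  invisible(res)
}

lmm_as_list <- function(x) {
  list(outcome = x$outcome, predictor = x$predictor,
       fixed = x$fixed, var_subject = x$var_subject, var_resid = x$var_resid,
       r2_conditional_adj = x$r2_conditional_adj,
       r2_marginal_adj = x$r2_marginal_adj,
       n_obs = x$n_obs, n_subjects = x$n_subjects)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
}

# Deterministic hash of the configuration: md5 of its canonical JSON.
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

render_report <- function(res, stamp) {
  fx <- function(name, term) {
    tab <- res$lmm[[name]]$fixed
    tab[tab$term == term, , drop = FALSE]
  }
  lines <- c(
    "# Synthetic motion / brain-age experiment report",
    "",
    sprintf("- config hash: `%s`", stamp$config_hash),
    sprintf("- seed: %d", stamp$seed),
    sprintf("- training cohort: %d scans; test cohort: %d subjects x 3 sessions",
            res$config$n_train, res$config$n_test_subjects),
    "",
    "## Brain age model",
    sprintf("- selected components k* = %d (10-fold CV-RMSE %.3f years)",
            res$train_metrics$k_star, res$train_metrics$cv_rmse),
    sprintf("- training CV correlation r = %.3f", res$train_metrics$cv_r),
    sprintf("- age-bias adjustment: slope %.4f, intercept %.3f",
            res$beta2[["slope"]], res$beta2[["intercept"]]),
    ""
  )
  if (!is.null(res$lmm$bag_session)) {
    for (term in c("sessionHM1", "sessionHM2")) {
      row <- fx("bag_session", term)
      lines <- c(lines, sprintf(
        "- adjusted BAG, %s vs STAND: %.3f years (t = %.2f, p = %.3g)%s",
        sub("session", "", term), row$estimate, row$t, row$p,
        if (row$p < 0.05) "" else " — not significant"))
    }
  }
  if (!is.null(res$lmm$bag_rating)) {
    row <- fx("bag_rating", "rating")
    lines <- c(lines, sprintf(
      "- adjusted BAG per rating level: %.3f years (t = %.2f, p = %.3g)%s",
      row$estimate, row$t, row$p,
      if (row$p < 0.05) "" else " — not significant"))
  }
  if (!is.null(res$lmm$bag_euler)) {
    row <- fx("bag_euler", "euler")
    lines <- c(lines, sprintf(
      "- adjusted BAG per unit normalized Euler: %.3f years (t = %.2f, p = %.3g)",
      row$estimate, row$t, row$p))
  }
  if (!is.null(res$lmm$euler_session)) {
    for (term in c("sessionHM1", "sessionHM2")) {
      tab <- res$lmm$euler_session$fixed
      row <- tab[tab$term == term, , drop = FALSE]
      lines <- c(lines, sprintf(
        "- normalized Euler, %s vs STAND: %.3f (t = %.2f, p = %.3g)",
        sub("session", "", term), row$estimate, row$t, row$p))
    }
  }
  if (length(res$fdr)) {
    lines <- c(lines, "", "## Per-component motion screen")
    for (nm in names(res$fdr)) {
      rep <- res$fdr[[nm]]
      for (tm in names(rep$n_rejected)) {
        ev <- rep$explained_variance_rejected[[tm]]
        lines <- c(lines, sprintf(
          "- %s / %s: %d of %d components significant (q = %g)%s",
          nm, tm, rep$n_rejected[[tm]], length(unique(rep$table$component)),
          rep$q,
          if (is.na(ev)) "" else sprintf(", %.1f%% of training variance", 100 * ev)))
      }
    }
  }
  lines <- c(lines, "", "## Intra-rater agreement",
             sprintf("- exact agreement: %.1f%%; linearly weighted kappa: %s",
                     res$agreement$agreement_pct,
                     if (res$agreement$kappa_defined)
                       sprintf("%.3f", res$agreement$kappa) else "undefined"))
  lines
}

#' Save / load a fitted model directory
#'
#' Serializes the scaler, PCA, age model, age-bias adjustment and CV curve
#' to JSON files (full-precision numbers) in `dir`; [load_model_dir()]
#' restores them with classes intact. The round trip preserves all numeric
#' values exactly.
#'
#' @param bundle Named list with elements `scaler`, `pca`, `model`, `beta2`,
#'   `cv_curve` and optionally `stamp`.
#' @param dir Target directory.
#' @return `save_model_dir`: invisibly, `dir`. `load_model_dir`: the
#'   restored bundle.
#' @export
save_model_dir <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sc <- bundle$scaler
  write_json_file(list(mean = sc$mean, sd = sc$sd, features = sc$features,
                       dropped = sc$dropped), file.path(dir, "scaler.json"))
  pc <- bundle$pca
  write_json_file(list(loadings = pc$loadings,
                       feature_names = rownames(pc$loadings),
                       singular_values = pc$singular_values,
                       explained_variance = pc$explained_variance,
                       n_fitted = pc$n_fitted), file.path(dir, "pca.json"))
  m <- bundle$model
  write_json_file(list(k = m$k, regularization = m$regularization,
                       lambda = m$lambda, weights = m$weights,
                       weight_names = m$weight_names,
                       intercept = m$intercept),
                  file.path(dir, "age_model.json"))
  write_json_file(as.list(bundle$beta2), file.path(dir, "beta2.json"))
  cv <- bundle$cv_curve
  write_json_file(list(k_values = cv$k_values, mean_rmse = cv$mean_rmse,
                       k_star = cv$k_star, fold_id = cv$fold_id,
                       folds = cv$folds, seed = cv$seed,
                       regularization = cv$regularization,
                       lambda = cv$lambda),
                  file.path(dir, "cv_curve.json"))
  if (!is.null(bundle$stamp)) {
    write_json_file(bundle$stamp, file.path(dir, "stamp.json"))
  }
  invisible(dir)
}

#' @rdname save_model_dir
#' @export
load_model_dir <- function(dir) {
  rd <- function(f) jsonlite::read_json(file.path(dir, f), simplifyVector = TRUE)
  sc <- rd("scaler.json")
  scaler <- list(mean = stats::setNames(as.numeric(sc$mean), sc$features),
                 sd = stats::setNames(as.numeric(sc$sd), sc$features),
                 features = sc$features,
                 dropped = if (length(sc$dropped)) sc$dropped else character(0))
  class(scaler) <- "scaler_model"
  pc <- rd("pca.json")
  L <- as.matrix(pc$loadings)
  rownames(L) <- pc$feature_names
  colnames(L) <- sprintf("PC%d", seq_len(ncol(L)))
  pca <- list(loadings = L, singular_values = as.numeric(pc$singular_values),
              explained_variance = as.numeric(pc$explained_variance),
              n_fitted = pc$n_fitted)
  class(pca) <- "pca_model"
  m <- rd("age_model.json")
  model <- list(k = m$k, regularization = m$regularization, lambda = m$lambda,
                weights = as.numeric(m$weights), weight_names = m$weight_names,
                intercept = as.numeric(m$intercept))
  class(model) <- "age_model"
  b2 <- rd("beta2.json")
  beta2 <- c(slope = as.numeric(b2$slope), intercept = as.numeric(b2$intercept))
  cv <- rd("cv_curve.json")
  cv_curve <- list(k_values = as.integer(cv$k_values),
                   mean_rmse = as.numeric(cv$mean_rmse),
                   k_star = as.integer(cv$k_star),
                   fold_id = as.integer(cv$fold_id), folds = cv$folds,
                   seed = cv$seed, regularization = cv$regularization,
                   lambda = cv$lambda)
  class(cv_curve) <- "cv_curve"
  stamp_path <- file.path(dir, "stamp.json")
  stamp <- if (file.exists(stamp_path)) rd("stamp.json") else NULL
  list(scaler = scaler, pca = pca, model = model, beta2 = beta2,
       cv_curve = cv_curve, stamp = stamp)
}
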