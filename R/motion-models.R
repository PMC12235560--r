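#' Fit a random-intercept mixed model for a motion predictor
#'
#' Fits `outcome ~ predictor + (1 | subject_id)` by REML and reports Wald
#' t-tests for the fixed effects. The three model families mirror the
#' analysis design of a repeated-session motion study:
#' \describe{
#'   \item{`session`}{categorical motion session with `STAND` (no induced
#'     motion) as the reference level, yielding `HM1` and `HM2` contrasts;}
#'   \item{`rating`}{the 0--5 visual motion rating treated as a continuous
#'     covariate (one slope, outcome-units per rating level);}
#'   \item{`euler`}{the continuous normalized Euler number.}
#' }
#' Degrees of freedom for the Wald t are the residual df
#' `n_obs - n_fixed`. Both a conditional adjusted R-squared (observed vs
#' fitted values including predicted random intercepts) and a marginal one
#' (fixed effects only) are reported, since either convention is common.
#'
#' @param data Data frame with columns `subject_id`, the outcome and the
#'   predictor.
#' @param outcome Name of the outcome column (e.g. `"delta2"`,
#'   `"euler_norm"`, or a PC score column).
#' @param predictor One of `"session"`, `"rating"`, `"euler"`, or the name
#'   of any numeric column to use as a continuous fixed effect.
#' @param session_levels Factor levels for the session predictor; the first
#'   is the reference.
#' @return An object of class `lmm_result`: `fixed` (data frame with
#'   `term`, `estimate`, `se`, `t`, `df`, `p`), `var_subject`, `var_resid`,
#'   `r2_conditional_adj`, `r2_marginal_adj`, `n_obs`, `n_subjects`,
#'   `outcome`, `predictor`, and the fitted `lme4` object in `fit`.
#' @export
fit_lmm <- function(data, outcome, predictor = c("session", "rating", "euler"),
                    session_levels = c("STAND", "HM1", "HM2")) {
  predictor <- if (length(predictor) == 1) predictor else match.arg(predictor)
  pred_col <- switch(predictor,
                     session = "session",
                     rating = "rating",
                     euler = "euler_norm",
                     predictor)
  for (col in c("subject_id", outcome, pred_col)) {
    if (!col %in% names(data)) {
      stop("column '", col, "' missing from data", call. = FALSE)
    }
  }
  df <- data.frame(
    .y = data[[outcome]],
    subject_id = as.character(data$subject_id),
    stringsAsFactors = FALSE
  )
  if (identical(predictor, "session")) {
    lev <- intersect(session_levels, unique(data[[pred_col]]))
    if (length(lev) < 2) {
      stop("session predictor requires at least 2 distinct sessions", call. = FALSE)
    }
    df$.x <- factor(data[[pred_col]], levels = lev)
  } else {
    df$.x <- as.numeric(data[[pred_col]])
  }
  if (anyNA(df$.y) || anyNA(df$.x)) {
    stop("outcome and predictor must be finite and non-missing", call. = FALSE)
  }
  if (length(unique(df$subject_id)) < 2) {
    stop("grouping is singular: need at least 2 subjects for a random intercept",
         call. = FALSE)
  }
  fit <- withCallingHandlers(
    lme4::lmer(.y ~ .x + (1 | subject_id), data = df, REML = TRUE),
    message = function(m) invokeRestart("muffleMessage"),
    warning = function(w) {
      # boundary (singular) fits are legitimate here (e.g. zero RE variance)
      if (grepl("boundary|singular|converge", conditionMessage(w), ignore.case = TRUE))
        invokeRestart("muffleWarning")
    }
  )
  cc <- tryCatch(fit@optinfo$conv$lme4, error = function(e) NULL)
  if (!is.null(cc$code) && cc$code < 0) {
    stop("mixed model did not converge: ", paste(cc$messages, collapse = "; "),
         call. = FALSE)
  }
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  n_obs <- nrow(df)
  n_fixed <- length(est)
  dof <- n_obs - n_fixed
  tval <- est / se
  pval <- 2 * stats::pt(abs(tval), df = dof, lower.tail = FALSE)
  terms <- names(est)
  terms <- sub("^\\.x", if (identical(predictor, "session")) "session" else predictor,
               terms)
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_subject <- vc$vcov[vc$grp == "subject_id"]
  var_resid <- vc$vcov[vc$grp == "Residual"]
  y <- df$.y
  fitted_cond <- stats::fitted(fit)
  fitted_marg <- drop(stats::model.matrix(fit) %*% est)
  adj <- function(r2, p) 1 - (1 - r2) * (n_obs - 1) / (n_obs - p - 1)
  r2c <- if (stats::var(y) > 0) stats::cor(y, fitted_cond)^2 else NA_real_
  r2m <- if (stats::var(y) > 0 && stats::var(fitted_marg) > 0) {
    stats::cor(y, fitted_marg)^2
  } else 0
  out <- list(
    fixed = data.frame(term = terms, estimate = unname(est), se = unname(se),
                       t = unname(tval), df = dof, p = unname(pval),
                       stringsAsFactors = FALSE),
    var_subject = var_subject, var_resid = var_resid,
    r2_conditional_adj = if (is.na(r2c)) NA_real_ else adj(r2c, n_fixed - 1),
    r2_marginal_adj = adj(r2m, n_fixed - 1),
    n_obs = n_obs, n_subjects = length(unique(df$subject_id)),
    outcome = outcome, predictor = predictor, fit = fit
  )
  class(out) <- "lmm_result"
  out
}

#' @export
print.lmm_result <- function(x, ...) {
  cat(sprintf("Random-intercept LMM: %s ~ %s + (1 | subject)\n",
              x$outcome, x$predictor))
  cat(sprintf("  %d scans from %d subjects\n", x$n_obs, x$n_subjects))
  fx <- x$fixed
  for (i in seq_len(nrow(fx))) {
    cat(sprintf("  %-16s beta = %8.3f  (SE %.3f, t = %6.2f, p = %.3g)\n",
                fx$term[i], fx$estimate[i], fx$se[i], fx$t[i], fx$p[i]))
  }
  cat(sprintf("  variance: subject %.4f, residual %.4f\n",
              x$var_subject, x$var_resid))
  cat(sprintf("  adjusted R-squared: conditional %.3f, marginal %.3f\n",
              x$r2_conditional_adj, x$r2_marginal_adj))
  invisible(x)
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Classic step-up procedure: with sorted p-values `p(1) <= ... <= p(m)`,
#' reject hypotheses `1..k*` where `k* = max { k : p(k) <= k q / m }`.
#' Adjusted p-values are the usual monotone BH values
#' (`min over j >= k of m p(j) / j`, capped at 1, computed via
#' [stats::p.adjust()]), and a hypothesis is rejected exactly when its
#' adjusted p is `<= q`.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @param q Target false discovery rate in `(0, 1]`.
#' @return A list: `adjusted` (BH-adjusted p-values, original order) and
#'   `rejected` (logical flags).
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.5), q = 0.05)
bh_fdr <- function(pvalues, q) {
  if (!is.numeric(pvalues) || anyNA(pvalues) ||
      any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must be numeric in [0, 1]", call. = FALSE)
  }
  if (length(q) != 1 || is.na(q) || q <= 0 || q > 1) {
    stop("q must be a single value in (0, 1]", call. = FALSE)
  }
  adjusted <- stats::p.adjust(pvalues, method = "BH")
  list(adjusted = adjusted, rejected = adjusted <= q)
}

#' Per-component motion-effect screen with FDR correction
#'
#' Fits one random-intercept mixed model per principal-component score
#' (`score_i ~ session + (1|subject)` or `score_i ~ rating + (1|subject)`)
#' and applies Benjamini-Hochberg correction across components. For the
#' session predictor, screening is per contrast: BH is applied separately to
#' the pooled HM1-vs-STAND p-values and to the pooled HM2-vs-STAND p-values,
#' so each contrast has its own rejected set. When the training PCA's
#' explained-variance fractions are supplied, the cumulative explained
#' variance of each rejected set is reported.
#'
#' @param scores Score matrix, scans x components (columns `PC1..PCk`).
#' @param data Scan metadata aligned with `scores` rows (needs
#'   `subject_id` plus the predictor column).
#' @param predictor `"session"` or `"rating"`.
#' @param q FDR level in `(0, 1]`.
#' @param explained_variance Optional per-component explained-variance
#'   fractions from the training PCA.
#' @return An object of class `fdr_report`: `table` (one row per component
#'   and contrast: `component`, `term`, `estimate`, `t`, `p`, `p_adjusted`,
#'   `rejected`), `q`, `n_rejected` and `explained_variance_rejected` (named
#'   by contrast).
#' @export
pc_motion_tests <- function(scores, data, predictor = c("session", "rating"),
                            q = 0.05, explained_variance = NULL) {
  predictor <- match.arg(predictor)
  scores <- as.matrix(scores)
  k <- ncol(scores)
  if (k < 1) stop("need at least one component", call. = FALSE)
  if (nrow(scores) != nrow(data)) {
    stop("scores and metadata differ in row count", call. = FALSE)
  }
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    df <- data
    df$.score <- scores[, i]
    res <- tryCatch(
      fit_lmm(df, outcome = ".score", predictor = predictor),
      error = function(e) {
        stop("component ", i, ": ", conditionMessage(e), call. = FALSE)
      }
    )
    fx <- res$fixed[-1, , drop = FALSE] # drop intercept
    fx$component <- i
    rows[[i]] <- fx
  }
  tab <- do.call(rbind, rows)
  tab$p_adjusted <- NA_real_
  tab$rejected <- NA
  ev_rej <- c()
  for (tm in unique(tab$term)) {
    idx <- tab$term == tm
    res <- bh_fdr(tab$p[idx], q)
    tab$p_adjusted[idx] <- res$adjusted
    tab$rejected[idx] <- res$rejected
    comp_rej <- tab$component[idx][res$rejected]
    ev_rej[tm] <- if (!is.null(explained_variance)) {
      sum(explained_variance[comp_rej])
    } else NA_real_
  }
  tab <- tab[, c("component", "term", "estimate", "se", "t", "df", "p",
                 "p_adjusted", "rejected")]
  rownames(tab) <- NULL
  out <- list(table = tab, q = q,
              n_rejected = tapply(tab$rejected, tab$term, sum),
              explained_variance_rejected = ev_rej)
  class(out) <- "fdr_report"
  out
}

#' @export
print.fdr_report <- function(x, ...) {
  cat(sprintf("Per-component motion screen (BH FDR, q = %g)\n", x$q))
  for (tm in names(x$n_rejected)) {
    ev <- x$explained_variance_rejected[[tm]]
    cat(sprintf("  %-16s %d component(s) significant%s\n", tm,
                x$n_rejected[[tm]],
                if (is.na(ev)) "" else
                  sprintf(" (%.1f%% of training variance)", 100 * ev)))
  }
  invisible(x)
}

#' Intra-rater agreement for 0--5 motion ratings
#'
#' Percent exact agreement and linearly weighted Cohen's kappa on the 6x6
#' contingency table of two rating passes over the same scans. Linear
#' weights `1 - |i - j| / 5` credit near-misses on the ordinal scale. When
#' both passes are constant and identical, chance agreement equals observed
#' agreement and kappa is undefined; the result is flagged and agreement is
#' still reported.
#'
#' @param ratings_a,ratings_b Integer vectors in `0:5`, same length.
#' @return A list: `agreement_pct`, `kappa` (NA when undefined),
#'   `kappa_defined`, `n`.
#' @export
rater_agreement <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b) || length(ratings_a) < 2) {
    stop("ratings must be two equal-length vectors with n >= 2", call. = FALSE)
  }
  ok <- function(r) all(r %in% 0:5)
  if (!ok(ratings_a) || !ok(ratings_b)) {
    stop("ratings must be integers in 0..5", call. = FALSE)
  }
  n <- length(ratings_a)
  lev <- 0:5
  tab <- table(factor(ratings_a, levels = lev), factor(ratings_b, levels = lev))
  P <- tab / n
  w <- 1 - abs(outer(lev, lev, "-")) / (length(lev) - 1)
  po <- sum(w * P)
  pe <- sum(w * outer(rowSums(P), colSums(P)))
  kappa_defined <- abs(1 - pe) > .Machine$double.eps^0.5
  kappa <- if (kappa_defined) (po - pe) / (1 - pe) else NA_real_
  list(agreement_pct = 100 * mean(ratings_a == ratings_b),
       kappa = kappa, kappa_defined = kappa_defined, n = n)
}
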