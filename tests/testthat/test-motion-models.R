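test_that("noiseless session effects are recovered exactly", {
  n_sub <- 12
  session <- rep(c("STAND", "HM1", "HM2"), times = n_sub)
  means <- c(STAND = 1.0, HM1 = 2.0, HM2 = 3.5)
  df <- data.frame(subject_id = rep(sprintf("s%02d", 1:n_sub), each = 3),
                   session = session, y = unname(means[session]),
                   stringsAsFactors = FALSE)
  # zero residual variance makes the mixed model numerically degenerate;
  # lme4's scaling diagnostic is expected here
  res <- suppressWarnings(fit_lmm(df, outcome = "y", predictor = "session"))
  fx <- res$fixed
  expect_equal(fx$estimate[fx$term == "sessionHM1"], 1.0, tolerance = 1e-8)
  expect_equal(fx$estimate[fx$term == "sessionHM2"], 2.5, tolerance = 1e-8)
  expect_lt(res$var_resid, 1e-10)
  expect_equal(fx$df[1], 3 * n_sub - 3)
})

test_that("with no subject variance the LMM collapses to OLS", {
  withr::with_seed(31, {
    df <- simulate_ri_data(60, beta = c(2, 1, 2.5), sd_u = 0, sd_e = 1)
  })
  res <- fit_lmm(df, outcome = "y", predictor = "session")
  ols <- stats::lm(y ~ factor(session, levels = c("STAND", "HM1", "HM2")),
                   data = df)
  expect_equal(unname(res$fixed$estimate), unname(stats::coef(ols)),
               tolerance = 1e-6)
})

test_that("LMM results are invariant to row permutation and ID relabeling", {
  withr::with_seed(32, {
    df <- simulate_ri_data(30, beta = c(1, 0.5, 1.5), sd_u = 1, sd_e = 0.7)
    perm <- sample(nrow(df))
  })
  res1 <- fit_lmm(df, outcome = "y", predictor = "session")
  df2 <- df[perm, ]
  res2 <- fit_lmm(df2, outcome = "y", predictor = "session")
  expect_equal(res1$fixed$estimate, res2$fixed$estimate, tolerance = 1e-6)
  expect_equal(res1$var_subject, res2$var_subject, tolerance = 1e-6)
  df3 <- df
  df3$subject_id <- paste0("relabel_", rev(as.integer(factor(df$subject_id))))
  res3 <- fit_lmm(df3, outcome = "y", predictor = "session")
  expect_equal(res1$fixed$estimate, res3$fixed$estimate, tolerance = 1e-6)
})

test_that("rating slope recovers the generator-implied dose response", {
  # linear severity bias of known slope, rating used as its proxy
  cfg <- sim_config(n_test_subjects = 300, n_train = 10, n_features = 40,
                    rating_noise_sd = 0.05, seed = 41)
  coh <- generate_motion_cohort(cfg)
  # outcome: severity-linear bias (slope c) plus subject intercept and noise
  c_true <- 1.2
  withr::with_seed(42, {
    u <- rnorm(cfg$n_test_subjects, sd = 1)
    y <- c_true * coh$truth$severities +
      u[as.integer(factor(coh$records$subject_id))] + rnorm(nrow(coh$records), sd = 0.3)
  })
  df <- coh$records
  df$y <- y
  res <- fit_lmm(df, outcome = "y", predictor = "rating")
  sl <- res$fixed[res$fixed$term == "rating", ]
  # rating approximates severity * 5/3 up to rounding, so the implied slope
  # per rating level is c * 3/5
  expect_gt(sl$estimate, 0)
  expect_lt(abs(sl$estimate - c_true * 3 / 5), 3 * sl$se + 0.1 * c_true)
})

test_that("singular grouping and missing columns are rejected", {
  df <- data.frame(subject_id = "s1", session = c("STAND", "HM1", "HM2"),
                   y = c(1, 2, 3), stringsAsFactors = FALSE)
  expect_error(fit_lmm(df, "y", "session"), "2 subjects")
  df2 <- data.frame(subject_id = c("a", "b"), y = c(1, 2))
  expect_error(fit_lmm(df2, "y", "session"), "session")
  df3 <- data.frame(subject_id = rep(c("a", "b"), each = 2),
                    session = rep("STAND", 4), y = rnorm(4))
  expect_error(fit_lmm(df3, "y", "session"), "2 distinct sessions")
})

test_that("BH step-up matches the hand-enumerated oracle", {
  res <- bh_fdr(c(0.01, 0.02, 0.03, 0.5), q = 0.05)
  expect_identical(res$rejected, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(res$adjusted, c(0.04, 0.04, 0.04, 0.5))
  res1 <- bh_fdr(rep(1, 5), q = 0.05)
  expect_true(all(!res1$rejected))
  expect_true(all(res1$adjusted == 1))
  res2 <- bh_fdr(0.04, q = 0.05)
  expect_true(res2$rejected)
  expect_equal(res2$adjusted, 0.04)
  expect_error(bh_fdr(c(0.5, 1.2), 0.05), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.5), 0), "q must")
})

test_that("BH agrees with a brute-force step-up on random p-vectors", {
  withr::with_seed(51, {
    for (rep in 1:200) {
      m <- sample(1:50, 1)
      p <- runif(m)^sample(1:3, 1) # mix of null and signal-like vectors
      q <- runif(1, 0.01, 0.2)
      mine <- bh_fdr(p, q)
      ref <- bh_brute_force(p, q)
      expect_identical(mine$rejected, ref$rejected)
      expect_equal(mine$adjusted, ref$adjusted, tolerance = 1e-12)
    }
  })
})

test_that("per-component screen respects its limiting FDR levels", {
  withr::with_seed(61, {
    n_sub <- 30
    scores <- matrix(rnorm(3 * n_sub * 4), ncol = 4,
                     dimnames = list(NULL, paste0("PC", 1:4)))
    df <- data.frame(subject_id = rep(sprintf("s%02d", 1:n_sub), each = 3),
                     session = rep(c("STAND", "HM1", "HM2"), times = n_sub),
                     rating = sample(0:5, 3 * n_sub, replace = TRUE),
                     stringsAsFactors = FALSE)
  })
  rep_all <- pc_motion_tests(scores, df, "session", q = 1)
  expect_true(all(rep_all$table$rejected))
  rep_none <- pc_motion_tests(scores, df, "session", q = 1e-12)
  expect_true(all(!rep_none$table$rejected))
  # k = 1 reduces BH to the single raw p-value against q
  rep1 <- pc_motion_tests(scores[, 1, drop = FALSE], df, "rating", q = 0.05)
  expect_equal(rep1$table$p_adjusted, rep1$table$p)
  expect_identical(rep1$table$rejected, rep1$table$p <= 0.05)
})

test_that("screen finds an injected single-component bias and reports its variance", {
  withr::with_seed(62, {
    n_sub <- 60
    session <- rep(c("STAND", "HM1", "HM2"), times = n_sub)
    sub <- rep(seq_len(n_sub), each = 3)
    scores <- matrix(rnorm(3 * n_sub * 5, sd = 0.3), ncol = 5,
                     dimnames = list(NULL, paste0("PC", 1:5)))
    scores <- scores + rnorm(n_sub, sd = 0.3)[sub] # shared subject intercept
    scores[, 1] <- scores[, 1] + 1.5 * (session == "HM2") + 0.8 * (session == "HM1")
  })
  df <- data.frame(subject_id = sprintf("s%02d", sub), session = session,
                   stringsAsFactors = FALSE)
  ev <- c(0.4, 0.2, 0.2, 0.1, 0.1)
  rep <- pc_motion_tests(scores, df, "session", q = 0.05,
                         explained_variance = ev)
  hm2 <- rep$table[rep$table$term == "sessionHM2", ]
  expect_true(hm2$rejected[hm2$component == 1])
  expect_equal(rep$explained_variance_rejected[["sessionHM2"]],
               sum(ev[hm2$component[hm2$rejected]]))
})

test_that("rater agreement statistics behave on identical, reversed and null ratings", {
  a <- c(0L, 1L, 2L, 3L, 4L, 5L, 2L, 3L)
  res <- rater_agreement(a, a)
  expect_equal(res$agreement_pct, 100)
  expect_equal(res$kappa, 1)
  # frozen oracle: linearly weighted kappa of a systematic reversal,
  # computed by direct double loop over the 6x6 table
  b <- 5L - a
  kappa_brute <- local({
    n <- length(a)
    w <- function(i, j) 1 - abs(i - j) / 5
    po <- mean(mapply(w, a, b))
    pe <- 0
    for (i in 0:5) for (j in 0:5) {
      pe <- pe + w(i, j) * mean(a == i) * mean(b == j)
    }
    (po - pe) / (1 - pe)
  })
  res_rev <- rater_agreement(a, b)
  expect_lt(res_rev$kappa, 0)
  expect_equal(res_rev$kappa, kappa_brute, tolerance = 1e-12)
  # independent uniform ratings: kappa near zero
  withr::with_seed(71, {
    ra <- sample(0:5, 2000, replace = TRUE)
    rb <- sample(0:5, 2000, replace = TRUE)
  })
  res_null <- rater_agreement(ra, rb)
  expect_lt(abs(res_null$kappa), 0.05)
  # degenerate: both raters constant and equal
  res_const <- rater_agreement(rep(0L, 10), rep(0L, 10))
  expect_equal(res_const$agreement_pct, 100)
  expect_false(res_const$kappa_defined)
  expect_true(is.na(res_const$kappa))
  expect_error(rater_agreement(c(0, 7), c(0, 1)), "0..5")
})

test_that("euler model on the default motion cohort shows a negative HM2 contrast", {
  coh <- generate_motion_cohort(sim_config(seed = 8))
  df <- coh$records
  df$euler_norm <- normalize_euler(df$euler_raw)
  res <- fit_lmm(df, outcome = "euler_norm", predictor = "session")
  fx <- res$fixed
  expect_lt(fx$estimate[fx$term == "sessionHM2"], 0)
  expect_lt(fx$estimate[fx$term == "sessionHM1"], 0)
})
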