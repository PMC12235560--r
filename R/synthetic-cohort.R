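#' @importFrom stats rnorm runif rbinom sd qnorm
NULL

# Shared latent structure for one configuration: feature baselines, the unit
# aging direction, the unit motion direction (cosine motion_overlap with the
# aging direction), and the low-rank factor loadings. Drawn once per (config,
# seed) so that training and motion cohorts live in the same feature space.
sim_structure <- function(cfg) {
  withr::with_seed(stage_seed(cfg$seed, 11L), {
    p <- cfg$n_features
    mu <- rnorm(p, mean = 0, sd = 1)
    if (cfg$n_latent > 0) {
      W <- matrix(rnorm(cfg$n_latent * p, sd = 1 / sqrt(p)),
                  nrow = cfg$n_latent)
      # unit rows so each factor contributes subject_sd feature-units overall
      W <- W / sqrt(rowSums(W^2))
      span_vec <- function() drop(crossprod(W, rnorm(cfg$n_latent)))
    } else {
      W <- matrix(numeric(0), nrow = 0, ncol = p)
      span_vec <- function() rnorm(p)
    }
    d_age <- span_vec()
    d_age <- d_age / sqrt(sum(d_age^2))
    d_raw <- span_vec()
    d_perp <- d_raw - sum(d_raw * d_age) * d_age
    nrm <- sqrt(sum(d_perp^2))
    if (nrm < 1e-12) { # degenerate span: fall back to any orthogonal direction
      d_raw <- rnorm(p)
      d_perp <- d_raw - sum(d_raw * d_age) * d_age
      nrm <- sqrt(sum(d_perp^2))
    }
    d_perp <- d_perp / nrm
    ov <- cfg$motion_overlap
    d_motion <- ov * d_age + sqrt(max(0, 1 - ov^2)) * d_perp
    list(mu = mu, W = W, d_age = d_age, d_motion = d_motion,
         age_loadings = cfg$age_effect_scale * d_age,
         motion_loadings = d_motion)
  })
}

feature_names <- function(p) sprintf("f%03d", seq_len(p))

# Assemble the feature matrix for a set of scans given per-scan ages,
# subject-factor scores and severities. Age is centred at the midpoint of the
# configured age range so training and test cohorts share one reference.
build_features <- function(cfg, str, ages, factors, severities, noise) {
  n <- length(ages)
  age_c <- ages - mean(cfg$age_range)
  X <- matrix(rep(str$mu, each = n), nrow = n)
  X <- X + outer(age_c, str$age_loadings)
  if (cfg$n_latent > 0) X <- X + factors %*% str$W
  X <- X + cfg$motion_bias * outer(severities, str$motion_loadings)
  X <- X + noise
  colnames(X) <- feature_names(cfg$n_features)
  X
}

#' Generate a synthetic training cohort
#'
#' One motion-free scan per subject, ages uniform on `age_range`, with the
#' feature model `x_ij = mu_j + a_j (Y_i - Ybar) + sum_l u_il w_lj + eps_ij`:
#' a per-feature baseline, a linear age effect along a fixed aging direction,
#' low-rank subject structure and i.i.d. Gaussian noise. Severities are all
#' zero, emulating a quality-controlled healthy training sample.
#'
#' @param config A [sim_config()].
#' @return A list with components:
#' \describe{
#'   \item{features}{numeric matrix, scans x features, rownames = scan IDs.}
#'   \item{records}{data frame of scan metadata: `scan_id`, `subject_id`,
#'     `age` (years), `sex`, `session`, `rating`, `euler_raw`.}
#'   \item{truth}{ground-truth list: `age_loadings`, `motion_loadings`,
#'     `subject_effects` (matrix of latent factor scores), `severities`.}
#' }
#' Identical `(config, seed)` give bit-identical output.
#' @export
#' @examples
#' coh <- generate_training_cohort(sim_config(n_train = 20, seed = 1))
#' dim(coh$features)
generate_training_cohort <- function(config) {
  validate_sim_config(config)
  str <- sim_structure(config)
  n <- config$n_train
  withr::with_seed(stage_seed(config$seed, 23L), {
    ages <- runif(n, config$age_range[1], config$age_range[2])
    sex <- ifelse(rbinom(n, 1, 0.5) == 1, "F", "M")
    factors <- if (config$n_latent > 0) {
      matrix(rnorm(n * config$n_latent, sd = config$subject_sd), nrow = n)
    } else matrix(numeric(0), nrow = n, ncol = 0)
    noise <- matrix(rnorm(n * config$n_features, sd = config$noise_sd), nrow = n)
  })
  severities <- rep(0, n)
  X <- build_features(config, str, ages, factors, severities, noise)
  scan_id <- sprintf("train%04d", seq_len(n))
  rownames(X) <- scan_id
  records <- data.frame(
    scan_id = scan_id,
    subject_id = sprintf("trainsub%04d", seq_len(n)),
    age = ages, sex = sex, session = "STAND",
    rating = 0L, euler_raw = NA_real_,
    stringsAsFactors = FALSE
  )
  truth <- list(age_loadings = str$age_loadings,
                motion_loadings = str$motion_loadings,
                subject_effects = factors, severities = severities)
  list(features = X, records = records, truth = truth)
}

#' Generate a synthetic repeated-session motion cohort
#'
#' Emulates an induced-motion repeated-measures design: every subject is
#' scanned in three sessions (`STAND`, `HM1`, `HM2`), sharing subject ID,
#' age, sex and latent subject effects across sessions. Each scan draws a
#' latent motion severity from a normal distribution truncated at zero with
#' session-specific mean, and the features receive an additional shift
#' `motion_bias * b_j * m` along the motion direction. Records carry a 0--5
#' visual motion rating (via [assign_visual_ratings()]) and a raw average
#' Euler number (via [synthesize_euler()]).
#'
#' @inheritParams generate_training_cohort
#' @return Same structure as [generate_training_cohort()]; `features` has
#'   `3 * n_test_subjects` rows ordered subject-major (STAND, HM1, HM2).
#' @export
generate_motion_cohort <- function(config) {
  validate_sim_config(config)
  str <- sim_structure(config)
  ns <- config$n_test_subjects
  n <- 3L * ns
  sessions <- rep(c("STAND", "HM1", "HM2"), times = ns)
  sess_idx <- rep(1:3, times = ns)
  withr::with_seed(stage_seed(config$seed, 37L), {
    ages_sub <- runif(ns, config$age_range[1], config$age_range[2])
    sex_sub <- ifelse(rbinom(ns, 1, 0.5) == 1, "F", "M")
    factors_sub <- if (config$n_latent > 0) {
      matrix(rnorm(ns * config$n_latent, sd = config$subject_sd), nrow = ns)
    } else matrix(numeric(0), nrow = ns, ncol = 0)
    sess_mean <- config$severity_means[sess_idx]
    severities <- rtruncnorm0(n, mean = sess_mean, sd = config$severity_sd)
    # a session with zero mean severity is a no-induced-motion protocol:
    # its scans carry exactly zero latent severity
    severities[sess_mean == 0] <- 0
    noise <- matrix(rnorm(n * config$n_features, sd = config$noise_sd), nrow = n)
  })
  sub_of_scan <- rep(seq_len(ns), each = 3L)
  ages <- ages_sub[sub_of_scan]
  factors <- if (config$n_latent > 0) factors_sub[sub_of_scan, , drop = FALSE] else
    matrix(numeric(0), nrow = n, ncol = 0)
  X <- build_features(config, str, ages, factors, severities, noise)
  subject_id <- sprintf("sub%04d", sub_of_scan)
  scan_id <- paste0(subject_id, "_", sessions)
  rownames(X) <- scan_id
  ratings <- assign_visual_ratings(severities, config$rating_noise_sd,
                                   seed = stage_seed(config$seed, 41L))
  euler_raw <- synthesize_euler(severities, config$euler_intercept,
                                config$euler_slope, config$euler_noise_sd,
                                seed = stage_seed(config$seed, 43L))
  records <- data.frame(
    scan_id = scan_id, subject_id = subject_id,
    age = ages, sex = sex_sub[sub_of_scan],
    session = sessions, rating = ratings, euler_raw = euler_raw,
    stringsAsFactors = FALSE
  )
  truth <- list(age_loadings = str$age_loadings,
                motion_loadings = str$motion_loadings,
                subject_effects = factors_sub, severities = severities)
  list(features = X, records = records, truth = truth)
}

# Normal draws truncated at zero by inverse-CDF sampling (exact, vectorised).
rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(pmax(rep_len(mean, n), 0))
  lo <- stats::pnorm(0, mean = mean, sd = sd)
  u <- runif(n, min = lo, max = 1)
  pmax(stats::qnorm(u, mean = mean, sd = sd), 0)
}

# Severity value that maps to the top of the 0-5 rating scale.
RATING_SEVERITY_CAP <- 3

#' Map latent motion severities to 0--5 visual ratings
#'
#' A piecewise-linear monotone map sends severity 0 to rating 0 and severity
#' `3` (the cap) and above to rating 5; Gaussian rater noise is added before
#' rounding and clamping to the 6-point ordinal scale, so the rating is
#' correlated with, but not a deterministic function of, the latent severity.
#'
#' @param severities Non-negative numeric vector of latent severities.
#' @param rating_noise_sd Standard deviation of the pre-rounding rater noise.
#' @param seed Integer seed.
#' @return Integer vector of ratings in `0:5`.
#' @export
#' @examples
#' assign_visual_ratings(c(0, 1, 2, 3), rating_noise_sd = 0, seed = 1)
assign_visual_ratings <- function(severities, rating_noise_sd, seed) {
  if (anyNA(severities) || !is.numeric(severities)) {
    stop("severities must be finite numeric values", call. = FALSE)
  }
  if (any(severities < 0)) stop("severities must be non-negative", call. = FALSE)
  continuous <- 5 * pmin(severities, RATING_SEVERITY_CAP) / RATING_SEVERITY_CAP
  noise <- if (rating_noise_sd > 0) {
    withr::with_seed(as.integer(seed), rnorm(length(severities), sd = rating_noise_sd))
  } else rep(0, length(severities))
  as.integer(pmin(pmax(round(continuous + noise), 0), 5))
}

#' Synthesize raw average Euler numbers from latent motion severities
#'
#' Draws a latent scan quality on the normalized-Euler scale,
#' `e = euler_intercept - euler_slope * m + noise`, and returns the raw
#' average Euler number `raw = 1 - exp(-e)` — the exact inverse of
#' [normalize_euler()]. Because the latent is Gaussian, the raw values are
#' left-skewed with a heavy negative tail, as observed for real surface
#' reconstructions, and more motion gives stochastically more negative raw
#' Euler numbers.
#'
#' @inheritParams assign_visual_ratings
#' @param euler_intercept Latent normalized Euler at severity 0.
#' @param euler_slope Latent quality loss per unit severity.
#' @param noise_sd Standard deviation of the latent quality noise.
#' @return Numeric vector of raw average Euler numbers (all `< 1`).
#' @export
#' @examples
#' raw <- synthesize_euler(c(0, 1, 2), -4, 0.7, noise_sd = 0, seed = 1)
#' normalize_euler(raw)  # recovers the latent values exactly
synthesize_euler <- function(severities, euler_intercept, euler_slope,
                             noise_sd, seed) {
  if (anyNA(severities) || !is.numeric(severities)) {
    stop("severities must be finite numeric values", call. = FALSE)
  }
  if (any(severities < 0)) stop("severities must be non-negative", call. = FALSE)
  noise <- if (noise_sd > 0) {
    withr::with_seed(as.integer(seed), rnorm(length(severities), sd = noise_sd))
  } else rep(0, length(severities))
  latent <- euler_intercept - euler_slope * severities + noise
  1 - exp(-latent)
}

#' Write a generated cohort to plain-text files
#'
#' Features go to `features.tsv` (scan_id + one column per feature), scan
#' metadata to `records.csv`, and the generator's ground truth (intended for
#' tests, not analysis) to `truth.csv`.
#'
#' @param cohort A list as returned by the cohort generators.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fpath <- file.path(dir, "features.tsv")
  rpath <- file.path(dir, "records.csv")
  tpath <- file.path(dir, "truth.csv")
  feat <- data.frame(scan_id = rownames(cohort$features),
                     cohort$features, check.names = FALSE,
                     stringsAsFactors = FALSE)
  utils::write.table(feat, fpath, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(cohort$records, rpath, row.names = FALSE, quote = FALSE)
  tr <- data.frame(scan_id = rownames(cohort$features),
                   severity = cohort$truth$severities,
                   stringsAsFactors = FALSE)
  utils::write.csv(tr, tpath, row.names = FALSE, quote = FALSE)
  invisible(c(features = fpath, records = rpath, truth = tpath))
}
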