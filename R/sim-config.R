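#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions emulated by [generate_training_cohort()] and
#' [generate_motion_cohort()]: a healthy-adult training cohort with linear age
#' effects on morphometric features, and a repeated-session test cohort in
#' which every subject is scanned three times (sessions `STAND`, `HM1`, `HM2`
#' = no / low / high induced head motion). Motion attenuates grey-matter-like
#' features along a direction that, at `motion_overlap = 1`, coincides with
#' the aging direction — the confound scenario in which motion masquerades as
#' accelerated aging.
#'
#' @param n_train Number of training subjects (one scan each).
#' @param n_test_subjects Number of test subjects (three scans each).
#' @param n_features Number of morphometric features per scan.
#' @param n_latent Number of latent factors generating low-rank
#'   between-subject structure; `0` disables subject-level structure.
#' @param age_range Length-2 numeric, minimum and maximum age in years; ages
#'   are drawn uniformly on this interval.
#' @param age_effect_scale Overall magnitude (root-sum-square across
#'   features) of the linear age effect, in feature-units per year. Negative
#'   by default: grey-matter density declines with age.
#' @param subject_sd Standard deviation of the latent subject factors, in
#'   feature-units; induces within-subject correlation across sessions.
#' @param noise_sd Standard deviation of i.i.d. per-scan measurement noise,
#'   in feature-units.
#' @param motion_bias Overall magnitude of the motion effect on features, in
#'   feature-units per unit latent severity. Negative by default, emulating
#'   motion-induced underestimation of grey matter.
#' @param motion_overlap Cosine between the motion direction and the aging
#'   direction in feature space: `1` makes motion mimic aging exactly, `0`
#'   makes it orthogonal to aging.
#' @param severity_means Length-3 non-decreasing numeric, mean latent motion
#'   severity for sessions (`STAND`, `HM1`, `HM2`); per-scan severities are
#'   drawn normal with these means and truncated at 0. A session with mean 0
#'   is treated as a no-induced-motion protocol and draws exactly zero
#'   severity.
#' @param severity_sd Standard deviation of latent severity before
#'   truncation.
#' @param rating_noise_sd Standard deviation of the noise added before the
#'   severity-to-rating map is rounded onto the 0--5 visual-rating scale.
#' @param euler_intercept Latent normalized Euler number of a motion-free
#'   scan (typical good-quality surfaces sit near -4, i.e. a raw average
#'   Euler number near -53).
#' @param euler_slope Decrease in latent normalized Euler number per unit
#'   severity (positive value = quality degrades with motion).
#' @param euler_noise_sd Standard deviation of scan-to-scan noise on the
#'   latent normalized Euler number.
#' @param seed Integer root seed; all generator randomness derives from it.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [generate_training_cohort()], [generate_motion_cohort()]
#' @export
#' @examples
#' cfg <- sim_config(n_train = 50, n_test_subjects = 20, seed = 1)
#' cfg$age_range
sim_config <- function(n_train = 281,
                       n_test_subjects = 121,
                       n_features = 100,
                       n_latent = 10,
                       age_range = c(18, 50),
                       age_effect_scale = -0.03,
                       subject_sd = 0.1,
                       noise_sd = 0.05,
                       motion_bias = -0.03,
                       motion_overlap = 1,
                       severity_means = c(0, 1, 2),
                       severity_sd = 0.3,
                       rating_noise_sd = 0.5,
                       euler_intercept = -4,
                       euler_slope = 0.75,
                       euler_noise_sd = 0.3,
                       seed = 1L) {
  cfg <- list(
    n_train = n_train, n_test_subjects = n_test_subjects,
    n_features = n_features, n_latent = n_latent,
    age_range = as.numeric(age_range),
    age_effect_scale = age_effect_scale,
    subject_sd = subject_sd, noise_sd = noise_sd,
    motion_bias = motion_bias, motion_overlap = motion_overlap,
    severity_means = as.numeric(severity_means),
    severity_sd = severity_sd, rating_noise_sd = rating_noise_sd,
    euler_intercept = euler_intercept, euler_slope = euler_slope,
    euler_noise_sd = euler_noise_sd, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  chk_count <- function(field, allow_zero = FALSE) {
    x <- cfg[[field]]
    lo <- if (allow_zero) 0 else 1
    if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < lo ||
        x != round(x)) {
      stop("invalid sim_config: '", field, "' must be a ",
           if (allow_zero) "non-negative" else "positive",
           " integer count", call. = FALSE)
    }
  }
  chk_pos <- function(field, strict = TRUE) {
    x <- cfg[[field]]
    if (length(x) != 1 || !is.numeric(x) || is.na(x) ||
        (strict && x <= 0) || (!strict && x < 0)) {
      stop("invalid sim_config: '", field, "' must be ",
           if (strict) "positive" else "non-negative", call. = FALSE)
    }
  }
  chk_count("n_train"); chk_count("n_test_subjects")
  chk_count("n_features"); chk_count("n_latent", allow_zero = TRUE)
  if (length(cfg$age_range) != 2 || anyNA(cfg$age_range) ||
      cfg$age_range[1] >= cfg$age_range[2]) {
    stop("invalid sim_config: 'age_range' must satisfy age_range[1] < age_range[2]",
         call. = FALSE)
  }
  chk_pos("noise_sd", strict = FALSE)
  chk_pos("subject_sd", strict = FALSE)
  chk_pos("severity_sd")
  chk_pos("rating_noise_sd", strict = FALSE)
  chk_pos("euler_noise_sd", strict = FALSE)
  if (length(cfg$severity_means) != 3 || anyNA(cfg$severity_means) ||
      is.unsorted(cfg$severity_means)) {
    stop("invalid sim_config: 'severity_means' must be non-decreasing across (STAND, HM1, HM2)",
         call. = FALSE)
  }
  if (any(cfg$severity_means < 0)) {
    stop("invalid sim_config: 'severity_means' must be non-negative", call. = FALSE)
  }
  if (length(cfg$motion_overlap) != 1 || is.na(cfg$motion_overlap) ||
      cfg$motion_overlap < -1 || cfg$motion_overlap > 1) {
    stop("invalid sim_config: 'motion_overlap' must lie in [-1, 1]", call. = FALSE)
  }
  if (length(cfg$seed) != 1 || is.na(cfg$seed)) {
    stop("invalid sim_config: 'seed' must be a single integer", call. = FALSE)
  }
  invisible(cfg)
}

#' Read a simulation configuration from a YAML file
#'
#' The file holds any subset of [sim_config()]'s arguments; unspecified
#' fields take the defaults. Validation is identical to calling
#' [sim_config()] directly.
#'
#' @param path Path to a YAML file.
#' @return A validated `sim_config`.
#' @export
sim_config_from_yaml <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(sim_config, vals)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  training subjects : %d (1 scan each)\n", x$n_train))
  cat(sprintf("  test subjects     : %d (3 sessions each: STAND/HM1/HM2)\n",
              x$n_test_subjects))
  cat(sprintf("  features          : %d (latent rank %d)\n",
              x$n_features, x$n_latent))
  cat(sprintf("  age range         : [%g, %g] years\n",
              x$age_range[1], x$age_range[2]))
  cat(sprintf("  age effect        : %g feature-units/year; motion bias %g/severity (overlap %g)\n",
              x$age_effect_scale, x$motion_bias, x$motion_overlap))
  cat(sprintf("  severity means    : %s (sd %g, truncated at 0)\n",
              paste(x$severity_means, collapse = "/"), x$severity_sd))
  cat(sprintf("  seed              : %d\n", x$seed))
  invisible(x)
}

# Deterministic per-stage seed derived from the root seed; kept inside the
# 32-bit integer range R requires of set.seed().
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}
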