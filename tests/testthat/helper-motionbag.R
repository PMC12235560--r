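# Small, fast configurations reused across tests.

tiny_config <- function(...) {
  sim_config(n_train = 60, n_test_subjects = 25, n_features = 30,
             n_latent = 4, seed = 11, ...)
}

# Independent brute-force BH step-up: sort, find the largest k with
# p(k) <= k q / m, reject 1..k; adjusted p by the monotone min construction.
bh_brute_force <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ok <- which(ps <= seq_len(m) * q / m)
  kstar <- if (length(ok)) max(ok) else 0L
  rejected <- logical(m)
  if (kstar > 0) rejected[o[seq_len(kstar)]] <- TRUE
  adj_sorted <- pmin(rev(cummin(rev(m * ps / seq_len(m)))), 1)
  adjusted <- numeric(m)
  adjusted[o] <- adj_sorted
  list(adjusted = adjusted, rejected = rejected)
}

# Simulate a balanced random-intercept dataset with known parameters:
# y = b0 + b1*HM1 + b2*HM2 + u_subject + e.
simulate_ri_data <- function(n_subjects, beta, sd_u, sd_e) {
  session <- rep(c("STAND", "HM1", "HM2"), times = n_subjects)
  subject <- rep(seq_len(n_subjects), each = 3)
  X <- cbind(1, session == "HM1", session == "HM2")
  y <- drop(X %*% beta) + rnorm(n_subjects)[subject] * sd_u +
    rnorm(3 * n_subjects) * sd_e
  data.frame(subject_id = sprintf("s%03d", subject), session = session,
             y = y, stringsAsFactors = FALSE)
}
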