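# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: plain loops and closed forms only.

# O(n^2) pairwise concordance enumerator (Harrell's convention:
# comparable when t_i < t_j and event_i == 1; score ties count 1/2).
brute_force_cindex <- function(time, event, scores) {
  conc <- 0
  comp <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (time[i] < time[j] && event[i] == 1) {
        comp <- comp + 1
        if (scores[i] < scores[j]) conc <- conc + 1
        else if (scores[i] == scores[j]) conc <- conc + 0.5
      }
    }
  }
  if (comp == 0) stop("no comparable pairs")
  conc / comp
}

# Small random censored survival instance for property tests.
random_survival_instance <- function(n, tie_prob = 0.3) {
  time <- if (stats::runif(1) < tie_prob) {
    sample(1:5, n, replace = TRUE)            # force time ties
  } else {
    round(stats::rexp(n, 0.5), 3)
  }
  event <- stats::rbinom(n, 1, 0.7)
  if (all(event == 0)) event[sample(n, 1)] <- 1
  scores <- if (stats::runif(1) < tie_prob) {
    sample(1:4, n, replace = TRUE)            # force score ties
  } else {
    stats::rnorm(n)
  }
  list(time = time, event = event, scores = scores)
}

# Cohort with a purely linear log-scale signal, for recovery tests.
linear_signal_cohort <- function(n, beta = c(0.5, -0.5), shape = 1.5,
                                 intercept = 1, censor_rate = 0.15,
                                 seed = 1) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n * length(beta)), n,
              dimnames = list(NULL, paste0("x", seq_along(beta))))
  log_scale <- intercept + drop(x %*% beta)
  latent <- stats::rweibull(n, shape, exp(log_scale))
  cens <- stats::rexp(n, censor_rate)
  cohort(x, pmin(latent, cens), as.integer(latent <= cens))
}

# Study-shaped cohort with one dominant effect (APOE-E4-like) at least
# five times every other configured effect.
dominant_signal_config <- function(seed, n_subjects = 956) {
  sim_config(
    n_subjects = n_subjects,
    snp_panel = default_snp_panel(8),
    apoe_effects = c(E2 = 0.2, E3 = 0, E4 = -1.0),
    mmse_effect = 0.1, sex_effect = 0.05,
    seed = seed)
}
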