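# Shared fixtures: all data built in code at test time.

# Expand a 2x2 exposure-by-outcome table into record-level data.
expand_2x2 <- function(a, b, c_, d) {
  data.frame(
    outcome = rep(c(1L, 1L, 0L, 0L), c(a, b, c_, d)),
    exposure = rep(c(1L, 0L, 1L, 0L), c(a, b, c_, d))
  )
}

# Small, fast cohort for plumbing tests.
small_cohort <- function(n_cases = 120, n_controls = 80, seed = 11,
                         true_log_or = log(1.3)) {
  cfg <- charge_like_config(seed = seed, true_log_or = true_log_or)
  cfg$n_cases <- as.integer(n_cases)
  cfg$n_controls <- as.integer(n_controls)
  generate_cohort(cfg)
}

# Scaled-down MCMC settings for unit tests.
quick_mcmc <- function(seed = 101, chains = 2, iters = 1200, burnin = 400) {
  mcmc_config(n_chains = chains, n_iterations = iters, n_burnin = burnin,
              seed = seed)
}

# Cohort with a three-level reported-use pattern and known stratum odds
# ratios, for the consistency-stratified models (no generator involved).
make_strata_cohort <- function(n, or_occasional, or_consistent,
                               p_occ = 0.06, p_con = 0.06) {
  stratum <- sample(c("unexposed", "occasional", "consistent"), n,
                    replace = TRUE, prob = c(1 - p_occ - p_con, p_occ, p_con))
  sex <- stats::rbinom(n, 1, 0.2)
  eta <- -0.4 + log(or_occasional) * (stratum == "occasional") +
    log(or_consistent) * (stratum == "consistent") + 0.2 * sex
  data.frame(
    outcome = stats::rbinom(n, 1, stats::plogis(eta)),
    reported_prenatal = as.integer(stratum != "unexposed"),
    consistency = factor(stratum,
                         levels = c("unexposed", "occasional", "consistent")),
    sex = sex
  )
}
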