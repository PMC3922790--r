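# Independent oracles for the joint misclassification posterior on a tiny
# cohort with one binary covariate: explicit enumeration over all 2^n latent
# exposure configurations, the analytically marginalized likelihood, and
# grid quadrature over the five regression coefficients. None of these share
# code with the sampler.

toy_cohort <- function() {
  data.frame(
    outcome = c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
    z       = c(0, 0, 1, 1, 0, 1, 0, 0, 1, 1, 1, 0),
    xs      = c(1, 0, 1, 0, 0, 1, 0, 1, 0, 0, 1, 0)
  )
}

toy_scenario <- function() misclass_scenario(0.8, 0.8, 0.1, 0.1)

# Per-record likelihood factors for latent exposure 1 and 0 at fixed
# coefficients a = (a0, a_z), b = (b0, b_x, b_z).
toy_factors <- function(dat, a, b, sc) {
  la <- stats::plogis(a[1] + a[2] * dat$z)
  p1 <- stats::plogis(b[1] + b[2] + b[3] * dat$z)
  p0 <- stats::plogis(b[1] + b[3] * dat$z)
  se <- ifelse(dat$outcome == 1, sc$se_case, sc$se_control)
  fpp <- ifelse(dat$outcome == 1, sc$fpp_case, sc$fpp_control)
  list(
    f1 = ifelse(dat$xs == 1, se, 1 - se) *
      ifelse(dat$outcome == 1, p1, 1 - p1) * la,
    f0 = ifelse(dat$xs == 1, fpp, 1 - fpp) *
      ifelse(dat$outcome == 1, p0, 1 - p0) * (1 - la)
  )
}

# Brute force: sum the joint density over every latent configuration.
enum_loglik <- function(dat, a, b, sc) {
  n <- nrow(dat)
  stopifnot(n <= 14)
  f <- toy_factors(dat, a, b, sc)
  M <- as.matrix(expand.grid(rep(list(0:1), n)))
  log(sum(exp(M %*% log(f$f1) + (1 - M) %*% log(f$f0))))
}

# Closed form: latent exposures are independent given coefficients, so the
# enumeration collapses to a product of per-record sums.
marg_loglik <- function(dat, a, b, sc) {
  f <- toy_factors(dat, a, b, sc)
  sum(log(f$f1 + f$f0))
}

# Grid quadrature for the marginal posterior of the exposure log odds ratio
# under independent N(0,1) priors on all five coefficients. Nuisance
# coefficients are integrated on a coarser grid; the exposure axis is finer
# and quantiles are interpolated from the midpoint CDF.
grid_posterior_exposure <- function(dat, sc,
                                    b1_grid = seq(-3.5, 3.5, length.out = 57),
                                    nuis_grid = seq(-3, 3, length.out = 13)) {
  G <- expand.grid(a0 = nuis_grid, a1 = nuis_grid,
                   b0 = nuis_grid, b2 = nuis_grid)
  lp_nuis <- stats::dnorm(G$a0, log = TRUE) + stats::dnorm(G$a1, log = TRUE) +
    stats::dnorm(G$b0, log = TRUE) + stats::dnorm(G$b2, log = TRUE)
  dens <- numeric(length(b1_grid))
  for (k in seq_along(b1_grid)) {
    b1 <- b1_grid[k]
    ll <- 0
    for (i in seq_len(nrow(dat))) {
      la <- stats::plogis(G$a0 + G$a1 * dat$z[i])
      p1 <- stats::plogis(G$b0 + b1 + G$b2 * dat$z[i])
      p0 <- stats::plogis(G$b0 + G$b2 * dat$z[i])
      se <- if (dat$outcome[i] == 1) sc$se_case else sc$se_control
      fpp <- if (dat$outcome[i] == 1) sc$fpp_case else sc$fpp_control
      m1 <- if (dat$xs[i] == 1) se else 1 - se
      m0 <- if (dat$xs[i] == 1) fpp else 1 - fpp
      py1 <- if (dat$outcome[i] == 1) p1 else 1 - p1
      py0 <- if (dat$outcome[i] == 1) p0 else 1 - p0
      ll <- ll + log(m1 * py1 * la + m0 * py0 * (1 - la))
    }
    w <- ll + lp_nuis
    mx <- max(w)
    dens[k] <- exp(mx) * sum(exp(w - mx)) * stats::dnorm(b1)
  }
  dens <- dens / sum(dens)
  cdf <- cumsum(dens) - dens / 2
  qfun <- function(p) stats::approx(cdf, b1_grid, xout = p, rule = 2)$y
  c(q2.5 = qfun(0.025), median = qfun(0.5), q97.5 = qfun(0.975))
}

# Model spec for the toy cohort with tight priors everywhere, matching the
# quadrature oracle's priors.
toy_spec <- function(sc = toy_scenario()) {
  joint_model_spec(
    sc, exposure = "xs", covariates = "z",
    outcome_priors = prior_set(c("intercept", "xs", "z"), 0, 1),
    exposure_priors = prior_set(c("intercept", "z"), 0, 1)
  )
}
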