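test_that("latent-exposure conditional honors boundary scenarios", {
  toy <- toy_cohort()
  Xb <- cbind(intercept = 1, xs = toy$xs, z = toy$z)
  Xa <- Xb[, c("intercept", "z")]
  # perfect report: conditional equals the report with certainty
  p <- latent_exposure_conditional(toy$xs, toy$outcome, Xa, Xb, 2,
                                   alpha = c(0.2, -0.1),
                                   beta = c(0.1, 0.5, -0.3),
                                   perfect_scenario())
  expect_identical(p, as.numeric(toy$xs))

  # uninformative everything: report carries nothing, outcome model flat,
  # exposure model at 0.5 -> conditional is exactly 0.5
  flat_sc <- suppressWarnings(
    misclass_scenario(0.5, 0.5, 0.5, 0.5, allow_nonidentifiable = TRUE))
  expect_warning(
    p2 <- latent_exposure_conditional(toy$xs, toy$outcome, Xa, Xb, 2,
                                      alpha = c(0, 0), beta = c(0.4, 0, 0.2),
                                      flat_sc),
    "no information"
  )
  expect_equal(p2, rep(0.5, nrow(toy)))
})

test_that("latent-exposure conditional matches brute-force Bayes' rule", {
  # fixed numeric case, evaluated against an independently coded two-branch
  # enumeration of Bayes' rule
  sc <- misclass_scenario(0.85, 0.85, 0.05, 0.05)
  z <- 1; y <- 1L; xs <- 1L
  alpha <- c(0.3, 0.3); beta <- c(0.3, 0.3, 0.3)
  Xa <- cbind(1, z); Xb <- cbind(1, xs, z)
  got <- latent_exposure_conditional(xs, y, Xa, Xb, 2, alpha, beta, sc)

  pX <- 1 / (1 + exp(-(0.3 + 0.3 * z)))
  pY1 <- 1 / (1 + exp(-(0.3 + 0.3 + 0.3 * z)))
  pY0 <- 1 / (1 + exp(-(0.3 + 0.3 * z)))
  num <- 0.85 * pY1 * pX
  den <- num + 0.05 * pY0 * (1 - pX)
  expect_equal(got, num / den, tolerance = 1e-12)
})

test_that("identical records get identical update probabilities", {
  sc <- misclass_scenario(0.8, 0.9, 0.1, 0.05)
  n <- 6
  Xa <- cbind(rep(1, n), rep(0.7, n))
  Xb <- cbind(rep(1, n), rep(1, n), rep(0.7, n))
  p <- latent_exposure_conditional(rep(1L, n), rep(1L, n), Xa, Xb, 2,
                                   c(-1, 0.4), c(-0.5, 0.6, 0.1), sc)
  expect_true(all(p == p[1]))
})

test_that("Gibbs sweep frequencies match the conditional at frozen coefficients", {
  sc <- misclass_scenario(0.8, 0.9, 0.1, 0.05)
  toy <- toy_cohort()
  Xb <- cbind(intercept = 1, xs = toy$xs, z = toy$z)
  Xa <- Xb[, c("intercept", "z")]
  alpha <- c(-1, 0.5); beta <- c(-0.4, 0.7, 0.2)

  # perfect scenario: one sweep returns the report exactly
  lat <- gibbs_update_latent(toy$xs, toy$outcome, Xa, Xb, 2, alpha, beta,
                             perfect_scenario(), seed = 81)
  expect_identical(lat, as.integer(toy$xs))

  p_target <- latent_exposure_conditional(toy$xs, toy$outcome, Xa, Xb, 2,
                                          alpha, beta, sc)
  n_sweep <- 10000
  set.seed(82)
  counts <- numeric(nrow(toy))
  for (s in seq_len(n_sweep)) {
    counts <- counts + gibbs_update_latent(toy$xs, toy$outcome, Xa, Xb, 2,
                                           alpha, beta, sc)
  }
  freq <- counts / n_sweep
  mc_se <- sqrt(p_target * (1 - p_target) / n_sweep)
  expect_true(all(abs(freq - p_target) <= 3 * mc_se + 1e-9))
})

test_that("full run is reproducible bit-exactly and rejects equal chain seeds", {
  coh <- small_cohort(seed = 83)
  cfg <- quick_mcmc(84, iters = 600, burnin = 200)
  spec <- joint_model_spec(misclass_scenario(0.85, 0.85, 0.05, 0.05))
  r1 <- run_mcmc(coh, spec, cfg, on_nonconvergence = "none")
  r2 <- run_mcmc(coh, spec, cfg, on_nonconvergence = "none")
  expect_identical(r1$beta_draws, r2$beta_draws)
  expect_identical(r1$alpha_draws, r2$alpha_draws)
  expect_error(mcmc_config(n_chains = 2, chain_seeds = c(5, 5)),
               "identical chain seeds")
})

test_that("record order does not change posterior summaries beyond MC noise", {
  coh <- small_cohort(n_cases = 150, n_controls = 100, seed = 85)
  cfg <- quick_mcmc(86, chains = 2, iters = 9000, burnin = 1500)
  spec <- joint_model_spec(misclass_scenario(0.85, 0.85, 0.05, 0.05))
  r1 <- run_mcmc(coh, spec, cfg, on_nonconvergence = "none")
  set.seed(87)
  perm <- sample(nrow(coh))
  r2 <- run_mcmc(coh[perm, ], spec, cfg, on_nonconvergence = "none")
  expect_lt(abs(log(r1$estimate$or_point) - log(r2$estimate$or_point)), 0.1)
})

test_that("split R-hat behaves on constructed chains", {
  set.seed(88)
  one <- rnorm(2000)
  copies <- cbind(one, one, one)
  gr <- gelman_rubin(copies)
  expect_lt(abs(gr$rhat - 1), 0.05)

  separated <- cbind(rnorm(2000, 0), rnorm(2000, 10))
  gr2 <- gelman_rubin(separated)
  # closed form: B/n ~ n * 50 / n, W ~ 1 -> rhat ~ sqrt(1 + 50)
  expect_gt(gr2$rhat, 5)

  white <- matrix(rnorm(5000 * 4), 5000, 4)
  gr3 <- gelman_rubin(white)
  expect_lt(gr3$rhat, 1.01)
  expect_gt(gr3$ess, 5000)

  stuck <- cbind(rep(1, 100), rep(2, 100))
  gr4 <- gelman_rubin(stuck)
  expect_identical(gr4$rhat, Inf)
  expect_match(gr4$note, "zero within-chain variance")
})

test_that("non-convergence raises an error carrying the diagnostic report", {
  coh <- small_cohort(seed = 89)
  cfg <- mcmc_config(n_chains = 2, n_iterations = 300, n_burnin = 100,
                     seed = 90, rhat_threshold = 1 + 1e-9)
  spec <- joint_model_spec(misclass_scenario(0.85, 0.85, 0.05, 0.05))
  err <- tryCatch(run_mcmc(coh, spec, cfg), error = identity)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "R-hat")
  expect_s3_class(err$convergence, "data.frame")
})
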