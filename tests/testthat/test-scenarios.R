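test_that("grid construction implements the four differential-recall groups", {
  g2 <- build_grid(se_steps = 0.85, fpp_steps = 0.05, groups = 2)[[1]]
  expect_equal(g2$se_case, 0.85)
  expect_equal(g2$se_control, 0.85)
  expect_equal(g2$fpp_case, 0.05)
  expect_equal(g2$fpp_control, 0.05)

  g4 <- build_grid(se_steps = 0.8, fpp_steps = 0.05,
                   differential_offset = 0.1, groups = 4)[[1]]
  expect_equal(g4$se_control, 0.8)
  expect_equal(g4$se_case, 0.9)
  expect_equal(g4$fpp_case, g4$fpp_control)

  g1 <- build_grid(se_steps = 0.8, fpp_steps = 0.05, groups = 1)[[1]]
  expect_gt(g1$se_control, g1$se_case)
  expect_gt(g1$fpp_control, g1$fpp_case)
})

test_that("inadmissible scenarios are dropped and counted by enumeration", {
  se <- c(0.70, 0.80, 0.90, 1.00)
  fpp <- c(0.00, 0.05, 0.10)
  off <- 0.10
  # independent enumeration of admissibility
  n_admissible <- 0L
  for (g in 1:4) for (s in se) for (f in fpp) {
    par <- switch(g,
                  c(s, s + off, f, f + off),
                  c(s, s, f, f),
                  c(s + off, s, f + off, f),
                  c(s + off, s, f, f))
    in_range <- all(par >= 0 & par <= 1)
    identifiable <- par[1] > par[3] && par[2] > par[4]
    if (in_range && identifiable) n_admissible <- n_admissible + 1L
  }
  grid <- suppressMessages(build_grid(se, fpp, off))
  expect_identical(length(grid), n_admissible)
  expect_gt(length(attr(grid, "dropped")), 0)
})

test_that("grids round-trip through JSON scenario files", {
  grid <- suppressMessages(build_grid(c(0.8, 0.9), c(0.05), 0.1))
  path <- withr::local_tempfile(fileext = ".json")
  write_scenarios(grid, path)
  back <- read_scenarios(path)
  expect_equal(as.data.frame(grid), as.data.frame(back))
})

test_that("a perfect-classification grid point reduces to the naive posterior", {
  coh <- small_cohort(n_cases = 200, n_controls = 150, seed = 91)
  cfg <- quick_mcmc(92, chains = 2, iters = 2500, burnin = 800)
  grid <- list(perfect_scenario())
  res <- run_grid(coh, grid, config = cfg)
  naive <- fit_bayes_logistic(build_design(coh), config = cfg,
                              on_nonconvergence = "none")
  expect_lt(abs(log(res$or_point) - log(naive$estimate$or_point)), 0.05)

  # determinism: identical grid result on re-run
  res2 <- run_grid(coh, grid, config = cfg)
  expect_identical(res, res2)
})

test_that("per-scenario failures are isolated, not fatal", {
  coh <- small_cohort(seed = 93)
  grid <- list(misclass_scenario(0.85, 0.85, 0.05, 0.05))
  strict <- mcmc_config(n_chains = 2, n_iterations = 300, n_burnin = 100,
                        seed = 94, rhat_threshold = 1 + 1e-9)
  res <- run_grid(coh, grid, config = strict)
  expect_identical(nrow(res), 1L)
  expect_false(res$converged)
  expect_match(res$note, "R-hat")
})

test_that("priors wash out at large n but shrink a tiny cohort toward the null", {
  cfg_gen <- charge_like_config(seed = 95, true_log_or = 0.4)
  cfg_gen$n_cases <- 3000L; cfg_gen$n_controls <- 3000L
  big <- generate_cohort(cfg_gen)
  sc <- misclass_scenario(0.85, 0.85, 0.05, 0.05)
  mc <- quick_mcmc(96, chains = 2, iters = 2500, burnin = 800)
  res_big <- prior_sensitivity(big, sc, presets = c("vague", "tight"),
                               config = mc, on_nonconvergence = "none")
  lo <- log(res_big$table$or_point)
  expect_lt(abs(lo[1] - lo[2]), log(1.05))

  tiny <- small_cohort(n_cases = 36, n_controls = 24, seed = 97,
                       true_log_or = log(3))
  res_tiny <- prior_sensitivity(tiny, sc,
                                presets = c("vague", "tight"),
                                config = quick_mcmc(98, chains = 2,
                                                    iters = 3000,
                                                    burnin = 1000),
                                covariates = c("sex", "pet_ownership"),
                                on_nonconvergence = "none")
  lo_t <- log(res_tiny$table$or_point)
  expect_lt(abs(lo_t[res_tiny$table$preset == "tight"]),
            abs(lo_t[res_tiny$table$preset == "vague"]))

  # missing informative table: remaining presets still run, with a warning
  expect_warning(
    res3 <- prior_sensitivity(tiny, sc,
                              presets = c("tight", "informative"),
                              informative_path = "does-not-exist.json",
                              config = quick_mcmc(99, chains = 2, iters = 800,
                                                  burnin = 300),
                              covariates = c("sex", "pet_ownership"),
                              on_nonconvergence = "none"),
    "informative"
  )
  expect_identical(res3$table$preset, "tight")
})
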