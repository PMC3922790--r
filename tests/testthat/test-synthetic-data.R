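test_that("misclassification operator honors the boundary scenarios exactly", {
  n <- 500
  outcome <- rep(c(0L, 1L), length.out = n)
  perfect <- perfect_scenario()
  truth <- rbinom(n, 1, 0.3)
  expect_identical(apply_misclassification(truth, outcome, perfect, seed = 1),
                   truth)
  all_se1 <- misclass_scenario(1, 1, 0.3, 0.2)
  expect_true(all(apply_misclassification(rep(1L, n), outcome, all_se1,
                                          seed = 1) == 1))
  no_fpp <- misclass_scenario(0.7, 0.9, 0, 0)
  expect_true(all(apply_misclassification(rep(0L, n), outcome, no_fpp,
                                          seed = 1) == 0))
})

test_that("report rates match the binomial law at large n", {
  n <- 10000
  sc <- misclass_scenario(0.8, 0.8, 0.05, 0.05)
  rep_exposed <- apply_misclassification(rep(1L, n), rep(0L, n), sc, seed = 2)
  expect_lt(abs(mean(rep_exposed) - 0.8), 3 * sqrt(0.8 * 0.2 / n))

  # marginal report rate = prevalence * Se + (1 - prevalence) * FPP
  prev <- 0.11
  set.seed(3)
  truth <- rbinom(n, 1, prev)
  reported <- apply_misclassification(truth, rep(1L, n), sc, seed = 4)
  expected <- prev * 0.8 + (1 - prev) * 0.05
  # truth is random too, so the marginal report is Bernoulli(expected)
  expect_lt(abs(mean(reported) - expected),
            3 * sqrt(expected * (1 - expected) / n))
})

test_that("window flags collapse to the two agreement extremes", {
  rep_pre <- c(rep(1L, 200), rep(0L, 100))
  all_win <- generate_windows(rep_pre, window_agreement = 1, seed = 5)
  exposed <- rep_pre == 1
  expect_true(all(rowSums(all_win$windows[exposed, ]) == 7))
  expect_true(all(all_win$consistency[exposed] == "consistent"))
  expect_true(all(rowSums(all_win$windows[!exposed, ]) == 0))
  expect_true(all(all_win$consistency[!exposed] == "unexposed"))

  one_win <- generate_windows(rep_pre, window_agreement = 0, seed = 6)
  expect_true(all(rowSums(one_win$windows[exposed, ]) == 1))
  expect_true(all(one_win$consistency[exposed] == "occasional"))
  # anchor is always prenatal
  expect_true(all(rowSums(one_win$windows[exposed, 1:4]) == 1))
})

test_that("between-window correlation rises monotonically with agreement", {
  n <- 20000
  phi <- function(w) {
    tri <- w$windows[, c("win_trimester1", "win_trimester2")]
    stats::cor(tri[, 1], tri[, 2])
  }
  rep_pre <- rep(1L, n)
  phis <- vapply(c(0.2, 0.5, 0.8), function(p) {
    phi(generate_windows(rep_pre, p, seed = 7))
  }, numeric(1))
  expect_true(all(diff(phis) > 0))
})

test_that("cohort generation is deterministic and honors requested counts", {
  coh1 <- small_cohort(seed = 21)
  coh2 <- small_cohort(seed = 21)
  expect_identical(coh1, coh2)
  expect_identical(sum(coh1$outcome == 1), 120L)
  expect_identical(sum(coh1$outcome == 0), 80L)
  coh3 <- small_cohort(seed = 22)
  expect_false(identical(coh1, coh3))
})

test_that("null outcome model gives equal exposure prevalence in both arms", {
  labels <- c("intercept", "educationhigh_school", "educationsome_college",
              "race_ethother", "parity", "pet_ownership", "sex",
              "age_centered", paste0("regionregion", 2:5))
  alpha <- setNames(rep(0, length(labels)), labels)
  alpha["intercept"] <- qlogis(0.11)
  beta <- setNames(rep(0, length(labels) + 1),
                   c(labels[1], "true_prenatal", labels[-1]))
  beta["intercept"] <- -1
  cfg <- generative_config(700, 700, alpha, beta, perfect_scenario(),
                           seed = 31)
  coh <- generate_cohort(cfg)
  for (arm in c(0, 1)) {
    p <- mean(coh$reported_prenatal[coh$outcome == arm])
    expect_lt(abs(p - 0.11), 3 * sqrt(0.11 * 0.89 / 700))
  }
  # perfect classification: report identical to truth
  expect_identical(coh$reported_prenatal, coh$true_prenatal)
})

test_that("default configuration reproduces the published cohort margins", {
  coh <- generate_cohort(charge_like_config())
  expect_identical(sum(coh$outcome == 1), 587L)
  expect_identical(sum(coh$outcome == 0), 356L)
  p_case <- mean(coh$reported_prenatal[coh$outcome == 1])
  p_ctrl <- mean(coh$reported_prenatal[coh$outcome == 0])
  expect_lt(abs(p_case - 0.12), 3 * sqrt(0.12 * 0.88 / 587))
  expect_lt(abs(p_ctrl - 0.11), 3 * sqrt(0.11 * 0.89 / 356))
  expect_true(validate_cohort(coh) |> is.data.frame())
})

test_that("an undersized source population fails loudly with the shortfall", {
  cfg <- charge_like_config()
  cfg$outcome_model_coeffs["intercept"] <- -9 # cases nearly impossible
  expect_error(generate_cohort(cfg), "shortfall")
})

test_that("MCAR injection feeds complete-case filtering with a logged count", {
  coh <- small_cohort(seed = 41)
  holey <- inject_missing(coh, c("pet_ownership", "education"), rate = 0.1,
                          seed = 42)
  expect_gt(sum(is.na(holey$pet_ownership)), 0)
  dsn <- build_design(holey)
  expect_identical(dsn$n_dropped + length(dsn$rows_kept), nrow(holey))
  expect_gt(dsn$n_dropped, 0)
})

test_that("schema validation itemizes violations", {
  coh <- small_cohort(seed = 51)
  bad <- coh
  bad$outcome[3] <- 2
  levels(bad$education) <- c(levels(bad$education), "phd")
  bad$education[1] <- "phd"
  err <- tryCatch(validate_cohort(bad), error = identity)
  expect_match(conditionMessage(err), "outcome")
  expect_match(conditionMessage(err), "phd")
  expect_error(validate_cohort(coh[, setdiff(names(coh), "parity")]),
               "missing column")
})
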