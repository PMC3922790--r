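test_that("logistic MLE on count-expanded data collapses to the 2x2 OR", {
  dat <- expand_2x2(70, 491, 40, 300)
  dsn <- build_design(dat, exposure = "exposure", covariates = character(0))
  fit <- fit_logistic_mle(dsn, model_label = "crude")
  ref <- crude_or_2x2(70, 491, 40, 300)
  expect_equal(fit$estimate$or_point, ref$or_point, tolerance = 1e-8)
  expect_equal(fit$estimate$ci_lower, ref$ci_lower, tolerance = 1e-6)
  expect_equal(fit$estimate$ci_upper, ref$ci_upper, tolerance = 1e-6)
})

test_that("null simulation keeps the exposure coefficient near zero", {
  set.seed(61)
  n <- 5000
  dat <- data.frame(outcome = rbinom(n, 1, 0.4),
                    exposure = rbinom(n, 1, 0.25))
  fit <- fit_logistic_mle(build_design(dat, "exposure", character(0)))
  se <- sqrt(fit$vcov["exposure", "exposure"])
  expect_lt(abs(log(fit$estimate$or_point)), 3 * se)
})

test_that("a constant covariate column is a named rank-deficiency error", {
  coh <- small_cohort(seed = 62)
  males <- coh[coh$sex == 0, ]
  expect_error(build_design(males, covariates = charge_covariates()), "sex")
  # dropping the constant column fits cleanly
  fit <- fit_logistic_mle(build_design(
    males, covariates = setdiff(charge_covariates(), "sex")))
  expect_true(fit$estimate$estimable)
})

test_that("profile intervals are available and bracket the point estimate", {
  skip_if_not_installed("MASS")
  dat <- expand_2x2(30, 170, 20, 180)
  fit <- fit_logistic_mle(build_design(dat, "exposure", character(0)),
                          ci_method = "profile")
  expect_lt(fit$estimate$ci_lower, fit$estimate$or_point)
  expect_gt(fit$estimate$ci_upper, fit$estimate$or_point)
})

test_that("naive battery orders crude / matching-only / fully adjusted rows", {
  coh <- small_cohort(n_cases = 250, n_controls = 180, seed = 63)
  tab <- fit_naive_models(coh)
  expect_identical(tab$model_label,
                   c("crude", "matching factors only", "fully adjusted"))
  expect_true(all(tab$estimable))
  expect_true(all(tab$limit_ratio >= 1))
})

test_that("covariates independent of exposure and outcome leave the three naive estimates together", {
  set.seed(64)
  n <- 4000
  dat <- data.frame(
    outcome = rbinom(n, 1, 0.35),
    reported_prenatal = rbinom(n, 1, 0.2),
    education = factor(sample(c("college_degree", "high_school",
                                "some_college"), n, TRUE),
                       levels = c("college_degree", "high_school",
                                  "some_college")),
    race_eth = factor(sample(c("white_non_hispanic", "other"), n, TRUE),
                      levels = c("white_non_hispanic", "other")),
    parity = sample(1:4, n, TRUE), pet_ownership = rbinom(n, 1, 0.5),
    sex = rbinom(n, 1, 0.2), age_centered = rnorm(n),
    region = factor(sample(paste0("region", 1:5), n, TRUE),
                    levels = paste0("region", 1:5))
  )
  tab <- fit_naive_models(dat)
  lo <- log(tab$or_point)
  expect_lt(max(lo) - min(lo), 0.1)
})

test_that("window models cover every window and flag unestimable ones", {
  coh <- small_cohort(n_cases = 250, n_controls = 200, seed = 65)
  # make every window identical to the overall exposure: all ORs must agree
  for (w in grep("^win_", names(coh), value = TRUE)) {
    coh[[w]] <- coh$reported_prenatal
  }
  coh$consistency <- factor(
    ifelse(coh$reported_prenatal == 1, "consistent", "unexposed"),
    levels = c("unexposed", "occasional", "consistent"))
  tab <- fit_window_models(coh)
  expect_identical(nrow(tab), 7L)
  overall <- fit_logistic_mle(build_design(coh))$estimate$or_point
  expect_true(all(abs(tab$or_point - overall) < 1e-8))

  # empty window stratum: flagged, not dropped
  coh$win_year3 <- 0L
  tab2 <- fit_window_models(coh)
  expect_identical(nrow(tab2), 7L)
  y3 <- tab2[tab2$window == "year3", ]
  expect_false(y3$estimable)
  expect_match(y3$note, "win_year3")
})

test_that("consistency strata recover a dose-response ordering", {
  set.seed(66)
  n_rep <- 200
  ordered_ok <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    coh <- make_strata_cohort(943, or_occasional = 1.2, or_consistent = 3)
    tab <- fit_consistency_strata(coh, covariates = "sex")
    ordered_ok[r] <- tab$or_point[tab$model_label == "consistent vs unexposed"] >
      tab$or_point[tab$model_label == "occasional vs unexposed"]
  }
  expect_gte(mean(ordered_ok), 0.9)
})

test_that("an empty consistency stratum is flagged without harming the other", {
  coh <- small_cohort(n_cases = 200, n_controls = 150, seed = 67)
  coh$consistency[coh$consistency == "occasional"] <- "unexposed"
  coh$reported_prenatal <- as.integer(coh$consistency != "unexposed")
  for (w in grep("^win_", names(coh), value = TRUE)) {
    coh[[w]] <- ifelse(coh$consistency == "consistent", coh[[w]], 0L)
  }
  tab <- fit_consistency_strata(coh)
  occ <- tab[tab$model_label == "occasional vs unexposed", ]
  con <- tab[tab$model_label == "consistent vs unexposed", ]
  expect_false(occ$estimable)
  expect_match(occ$note, "occasional")
  expect_true(con$estimable)
})

test_that("joint three-level fit agrees with separate stratified fits at large n", {
  set.seed(68)
  coh <- make_strata_cohort(20000, or_occasional = 1.3, or_consistent = 2.2)
  sep <- fit_consistency_strata(coh, covariates = "sex")
  jnt <- fit_consistency_strata(coh, covariates = "sex", joint = TRUE)
  expect_equal(log(sep$or_point), log(jnt$or_point), tolerance = 0.05)
})
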