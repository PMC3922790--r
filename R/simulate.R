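#' Apply reporting error to a true exposure vector
#'
#' Each truly exposed record reports exposure with the scenario's
#' group-specific sensitivity, and each truly unexposed record reports
#' exposure with the group-specific false-positive probability, the group
#' being the record's case/control status. Draws are independent across
#' records.
#'
#' @param truth Binary vector of true exposure.
#' @param outcome Binary vector of case status (same length).
#' @param scenario A [misclass_scenario()].
#' @param seed Optional integer; when supplied the RNG is seeded locally so
#'   the call is reproducible without disturbing the caller's RNG stream.
#' @return Binary vector of reported exposure.
#' @export
apply_misclassification <- function(truth, outcome, scenario, seed = NULL) {
  stopifnot(length(truth) == length(outcome),
            all(truth %in% c(0, 1)), all(outcome %in% c(0, 1)))
  rates <- scenario_rates(scenario, outcome)
  p_report <- ifelse(truth == 1, rates$se, rates$fpp)
  with_seed(seed, stats::rbinom(length(truth), 1L, p_report))
}

#' Generate correlated exposure-window flags and consistency labels
#'
#' Exposure timing is recorded over seven ordered windows: the three months
#' before conception, the three trimesters of pregnancy, and each of the
#' first three years of the child's life. For each record reporting prenatal
#' exposure, one of the four prenatal windows is flagged as the anchor and
#' the flag propagates outward to adjacent windows, each further step
#' succeeding with probability `window_agreement` (a one-parameter Markov
#' run), so pairwise correlation between windows rises with the agreement
#' parameter. Use is labelled *consistent* when all three trimester flags are
#' set (application at least monthly throughout pregnancy) and *occasional*
#' otherwise; records without reported prenatal exposure get all-zero flags
#' and the label *unexposed*.
#'
#' @param reported_prenatal Binary vector.
#' @param window_agreement Probability in `[0, 1]` that a flag propagates one
#'   further adjacent window.
#' @param seed Optional integer seed (local, see [apply_misclassification()]).
#' @return A list with `windows` (0/1 matrix, columns `win_preconception`,
#'   ..., `win_year3`) and `consistency` (factor).
#' @export
generate_windows <- function(reported_prenatal, window_agreement, seed = NULL) {
  stopifnot(all(reported_prenatal %in% c(0, 1)),
            is.numeric(window_agreement), length(window_agreement) == 1,
            window_agreement >= 0, window_agreement <= 1)
  n <- length(reported_prenatal)
  W <- matrix(0L, n, length(WINDOW_COLS), dimnames = list(NULL, WINDOW_COLS))
  exposed <- which(reported_prenatal == 1)
  with_seed(seed, {
    if (length(exposed)) {
      m <- length(exposed)
      anchor <- sample.int(4L, m, replace = TRUE) # one of the prenatal windows
      run_len <- function(k) {
        if (window_agreement >= 1) rep.int(length(WINDOW_COLS), k)
        else if (window_agreement <= 0) rep.int(0L, k)
        else stats::rgeom(k, prob = 1 - window_agreement)
      }
      left <- pmin(run_len(m), anchor - 1L)
      right <- pmin(run_len(m), length(WINDOW_COLS) - anchor)
      for (j in seq_len(m)) {
        W[exposed[j], (anchor[j] - left[j]):(anchor[j] + right[j])] <- 1L
      }
    }
  })
  tri <- W[, c("win_trimester1", "win_trimester2", "win_trimester3"),
           drop = FALSE]
  consistency <- rep("unexposed", n)
  consistency[exposed] <- ifelse(rowSums(tri[exposed, , drop = FALSE]) == 3L,
                                 "consistent", "occasional")
  list(windows = W,
       consistency = factor(consistency, levels = CONSISTENCY_LEVELS))
}

#' Generative configuration for a synthetic case-control cohort
#'
#' Bundles the two logistic models of the generator (true-exposure model
#' given covariates; outcome model given true exposure and covariates), the
#' measurement scenario converting true to reported exposure, the
#' window-agreement parameter, the requested case/control counts and the
#' size of the simulated source population.
#'
#' @param n_cases,n_controls Requested counts (positive integers).
#' @param exposure_model_coeffs Named vector over the covariate-only design
#'   columns (see [build_design()] with `exposure = NULL`), log-odds scale.
#' @param outcome_model_coeffs Named vector over the covariate design plus a
#'   `true_prenatal` term, log-odds scale.
#' @param scenario A [misclass_scenario()] for the reporting error.
#' @param window_agreement Propagation probability for [generate_windows()].
#' @param source_multiplier Source population size as a multiple of
#'   `n_cases + n_controls` (default 50).
#' @param seed Integer seed governing the whole generation.
#' @return A list of class `generative_config`.
#' @export
generative_config <- function(n_cases, n_controls, exposure_model_coeffs,
                              outcome_model_coeffs, scenario,
                              window_agreement = 0.9,
                              source_multiplier = 50, seed = 20140123) {
  stopifnot(n_cases > 0, n_controls > 0, source_multiplier >= 2,
            inherits(scenario, "misclass_scenario"),
            window_agreement >= 0, window_agreement <= 1,
            !is.null(names(exposure_model_coeffs)),
            !is.null(names(outcome_model_coeffs)),
            "true_prenatal" %in% names(outcome_model_coeffs))
  structure(
    list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         exposure_model_coeffs = exposure_model_coeffs,
         outcome_model_coeffs = outcome_model_coeffs,
         scenario = scenario, window_agreement = window_agreement,
         source_multiplier = source_multiplier, seed = as.integer(seed)),
    class = "generative_config"
  )
}

#' Default configuration emulating the published cohort margins
#'
#' Returns a [generative_config()] whose marginal frequencies approximate the
#' published participant table: 587 cases and 356 controls; reported prenatal
#' exposure near 12% in cases and 11% in controls; maternal education split
#' near 41/15/44% (college degree / high school / some college) in cases;
#' ~84% male children; mean interview age near 3.7 years. True exposure
#' prevalence is set near 7-9% so that, under the default non-differential
#' reporting scenario (sensitivity 0.85, false-positive probability 0.05,
#' mid-range plausible values), the *reported* prevalence lands near the
#' published 11-12%. The true exposure log odds ratio defaults to
#' `log(1.3)`, the adjusted naive estimate scale.
#'
#' @param seed Seed stored in the configuration.
#' @param true_log_or True exposure log odds ratio in the outcome model.
#' @param scenario Reporting scenario (default non-differential
#'   Se 0.85 / FPP 0.05).
#' @return A `generative_config`.
#' @export
charge_like_config <- function(seed = 20140123, true_log_or = log(1.3),
                               scenario = misclass_scenario(
                                 0.85, 0.85, 0.05, 0.05,
                                 label = "non-differential Se 0.85 FPP 0.05",
                                 group = 2L)) {
  # Covariate-design column order: intercept, education (2), race, parity,
  # pet, sex, age, region (4).
  alpha <- c(
    intercept = -3.25,
    educationhigh_school = 0.10, educationsome_college = 0.05,
    race_ethother = -0.25, parity = 0.05, pet_ownership = 0.90,
    sex = 0.00, age_centered = 0.00,
    regionregion2 = 0, regionregion3 = 0, regionregion4 = 0,
    regionregion5 = 0
  )
  beta <- c(
    intercept = -2.20, true_prenatal = true_log_or,
    educationhigh_school = -0.15, educationsome_college = -0.30,
    race_ethother = -0.20, parity = 0.00, pet_ownership = -0.35,
    sex = 0.00, age_centered = 0.35,
    regionregion2 = 0, regionregion3 = 0, regionregion4 = 0,
    regionregion5 = 0
  )
  generative_config(
    n_cases = 587L, n_controls = 356L,
    exposure_model_coeffs = alpha, outcome_model_coeffs = beta,
    scenario = scenario, window_agreement = 0.9,
    source_multiplier = 50, seed = seed
  )
}

# Population covariate distributions (complete data): education and parity
# marginals sit between the published case and control columns; age is
# normal truncated to the 2-5y recruitment window.
generate_covariates <- function(n) {
  education <- sample(EDUCATION_LEVELS, n, replace = TRUE,
                      prob = c(0.37, 0.15, 0.48))
  race_eth <- sample(RACE_LEVELS, n, replace = TRUE, prob = c(0.58, 0.42))
  parity <- pmin(stats::rgeom(n, prob = 0.32) + 1L, 6L)
  pet_ownership <- stats::rbinom(n, 1L, 0.63)
  sex <- stats::rbinom(n, 1L, 0.16) # female = 1
  age <- stats::qnorm(stats::runif(n, stats::pnorm(2, 3.7, 0.8),
                                   stats::pnorm(5, 3.7, 0.8)), 3.7, 0.8)
  region <- sample(REGION_LEVELS, n, replace = TRUE,
                   prob = c(0.30, 0.25, 0.20, 0.15, 0.10))
  data.frame(
    education = factor(education, levels = EDUCATION_LEVELS),
    race_eth = factor(race_eth, levels = RACE_LEVELS),
    parity = parity, pet_ownership = pet_ownership, sex = sex,
    age = age, region = factor(region, levels = REGION_LEVELS),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic case-control cohort
#'
#' Simulates a source population of `source_multiplier * (n_cases +
#' n_controls)` children, draws each child's true exposure from the logistic
#' exposure model given covariates and the outcome from the logistic outcome
#' model given true exposure and covariates, then samples the requested
#' numbers of cases and controls. Controls are frequency-matched: they are
#' drawn within sex-by-region strata in proportion to the realized case
#' distribution, mirroring matched recruitment from birth records. Reported
#' exposure is then derived from true exposure by
#' [apply_misclassification()] under the configuration's scenario, and the
#' exposure-window flags and consistency labels by [generate_windows()].
#' Age is centered at the realized cohort mean. The whole procedure is
#' deterministic given `config$seed`.
#'
#' @param config A [generative_config()].
#' @return A cohort `data.frame`, one row per child: `id`, `outcome`,
#'   `true_prenatal`, `reported_prenatal`, the seven `win_*` flags,
#'   `consistency`, and the covariates of [charge_covariates()].
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generative_config"))
  set.seed(config$seed)
  n_target <- config$n_cases + config$n_controls
  N <- ceiling(config$source_multiplier * n_target)
  cov <- generate_covariates(N)
  cov$age_centered <- cov$age - mean(cov$age) # provisional; recentered below
  pop <- cbind(outcome = 0L, cov)

  dsn_a <- build_design(pop, exposure = NULL)
  alpha <- align_named_coeffs(config$exposure_model_coeffs, dsn_a$labels)
  p_true <- stats::plogis(drop(dsn_a$X %*% alpha))
  true_prenatal <- stats::rbinom(N, 1L, p_true)

  beta <- config$outcome_model_coeffs
  beta_x <- beta[["true_prenatal"]]
  beta_cov <- align_named_coeffs(beta[names(beta) != "true_prenatal"],
                                 dsn_a$labels)
  p_case <- stats::plogis(drop(dsn_a$X %*% beta_cov) + beta_x * true_prenatal)
  outcome <- stats::rbinom(N, 1L, p_case)

  idx_cases_pool <- which(outcome == 1L)
  if (length(idx_cases_pool) < config$n_cases) {
    stop("source population supplied only ", length(idx_cases_pool),
         " cases for the ", config$n_cases, " requested (shortfall ",
         config$n_cases - length(idx_cases_pool),
         "); increase source_multiplier or the outcome model intercept")
  }
  idx_cases <- sample(idx_cases_pool, config$n_cases)
  idx_controls <- sample_matched_controls(
    outcome = outcome, stratum = interaction(pop$sex, pop$region, drop = FALSE),
    idx_cases = idx_cases, n_controls = config$n_controls
  )

  idx <- c(idx_cases, idx_controls)
  out <- pop[idx, , drop = FALSE]
  out$outcome <- as.integer(outcome[idx])
  out$true_prenatal <- as.integer(true_prenatal[idx])
  out$age_centered <- out$age - mean(out$age)
  out$age <- NULL

  out$reported_prenatal <- apply_misclassification(
    out$true_prenatal, out$outcome, config$scenario)
  win <- generate_windows(out$reported_prenatal, config$window_agreement)
  out <- cbind(out, as.data.frame(win$windows))
  out$consistency <- win$consistency
  out <- out[order(-out$outcome), , drop = FALSE]
  out$id <- seq_len(nrow(out))
  rownames(out) <- NULL
  cols <- c("id", "outcome", "true_prenatal", "reported_prenatal",
            WINDOW_COLS, "consistency", charge_covariates())
  validate_cohort(out[, cols])
  out[, cols]
}

# Frequency matching: allocate the requested number of controls across
# sex-by-region strata in proportion to the realized case distribution
# (largest-remainder rounding), then sample controls without replacement
# within each stratum.
sample_matched_controls <- function(outcome, stratum, idx_cases, n_controls) {
  case_tab <- table(stratum[idx_cases])
  target <- n_controls * as.numeric(case_tab) / sum(case_tab)
  alloc <- floor(target)
  rem <- n_controls - sum(alloc)
  if (rem > 0) {
    order_frac <- order(target - alloc, decreasing = TRUE)
    alloc[order_frac[seq_len(rem)]] <- alloc[order_frac[seq_len(rem)]] + 1L
  }
  names(alloc) <- names(case_tab)
  idx_controls <- integer(0)
  for (s in names(alloc)) {
    if (alloc[[s]] == 0L) next
    pool <- which(outcome == 0L & as.character(stratum) == s)
    if (length(pool) < alloc[[s]]) {
      stop("source population supplied only ", length(pool),
           " controls in stratum '", s, "' for the ", alloc[[s]],
           " requested (shortfall ", alloc[[s]] - length(pool), ")")
    }
    idx_controls <- c(idx_controls, sample(pool, alloc[[s]]))
  }
  idx_controls
}

#' Inject missingness completely at random
#'
#' Sets each selected cell to `NA` independently with probability `rate`
#' (missing completely at random), to exercise complete-case filtering.
#'
#' @param cohort Cohort data frame.
#' @param columns Columns to perturb.
#' @param rate Per-cell missingness probability.
#' @param seed Optional local seed.
#' @return The cohort with `NA`s injected.
#' @export
inject_missing <- function(cohort, columns, rate, seed = NULL) {
  stopifnot(all(columns %in% names(cohort)), rate >= 0, rate <= 1)
  with_seed(seed, {
    for (cl in columns) {
      miss <- stats::runif(nrow(cohort)) < rate
      cohort[[cl]][miss] <- NA
    }
  })
  cohort
}

# Reorder a named coefficient vector to design-column order, requiring an
# exact one-to-one match.
align_named_coeffs <- function(coeffs, labels) {
  if (!setequal(names(coeffs), labels)) {
    stop("coefficient names do not match design columns; missing: ",
         paste(setdiff(labels, names(coeffs)), collapse = ", "),
         "; extra: ", paste(setdiff(names(coeffs), labels), collapse = ", "))
  }
  coeffs[labels]
}

# Evaluate `expr` under a locally seeded RNG when `seed` is non-NULL,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
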