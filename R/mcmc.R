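#' MCMC configuration
#'
#' Defaults follow common practice for this model class: three chains of
#' 15,000 iterations including a 2,000-iteration burn-in, no thinning, and a
#' split-R-hat convergence threshold of 1.1. Each chain gets its own seed
#' (`seed`, `seed + 1`, ...); supplying identical chain seeds is an error
#' because the convergence diagnostic would be vacuous.
#'
#' @param n_chains Number of chains (>= 2 so R-hat is defined).
#' @param n_iterations Iterations per chain, including burn-in.
#' @param n_burnin Burn-in iterations discarded per chain.
#' @param seed Base integer seed.
#' @param thinning Keep every `thinning`-th post-burn-in draw.
#' @param rhat_threshold Split-R-hat above which a run is declared
#'   non-converged.
#' @param chain_seeds Optional explicit per-chain seeds (distinct integers).
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3, n_iterations = 15000, n_burnin = 2000,
                        seed = 20140123, thinning = 1, rhat_threshold = 1.1,
                        chain_seeds = NULL) {
  stopifnot(n_chains >= 2, n_burnin >= 0, n_burnin < n_iterations,
            thinning >= 1, rhat_threshold > 1)
  if (is.null(chain_seeds)) chain_seeds <- seed + seq_len(n_chains) - 1L
  if (length(chain_seeds) != n_chains) {
    stop("chain_seeds must supply one seed per chain")
  }
  if (anyDuplicated(chain_seeds)) {
    stop("identical chain seeds: chains would not be independent replicates")
  }
  structure(
    list(n_chains = as.integer(n_chains),
         n_iterations = as.integer(n_iterations),
         n_burnin = as.integer(n_burnin), seed = as.integer(seed),
         thinning = as.integer(thinning), rhat_threshold = rhat_threshold,
         chain_seeds = as.integer(chain_seeds)),
    class = "mcmc_config"
  )
}

#' Joint misclassification model specification
#'
#' The correction jointly estimates three linked models: a logistic
#' *exposure model* for the probability of true exposure given covariates
#' (coefficients `alpha`, default tight N(0, 1) priors), a *measurement
#' model* giving the probability of the retrospective report given true
#' exposure and case status (the scenario's sensitivity / false-positive
#' probability, fixed constants), and a logistic *outcome model* for case
#' status given true exposure and covariates (coefficients `beta`, priors per
#' `outcome_priors`, default vague N(0, 10)). The exposure-model design
#' equals the outcome-model design minus the exposure term.
#'
#' @param scenario A [misclass_scenario()] treated as known.
#' @param outcome_priors Optional [prior_set()] over the outcome design
#'   columns; default vague.
#' @param exposure_priors Optional [prior_set()] over the exposure design
#'   columns; default tight.
#' @param exposure Name of the reported-exposure column.
#' @param covariates Covariate columns (default [charge_covariates()]).
#' @return A list of class `joint_model_spec`.
#' @export
joint_model_spec <- function(scenario, outcome_priors = NULL,
                             exposure_priors = NULL,
                             exposure = "reported_prenatal",
                             covariates = charge_covariates()) {
  stopifnot(inherits(scenario, "misclass_scenario"))
  structure(
    list(scenario = scenario, outcome_priors = outcome_priors,
         exposure_priors = exposure_priors, exposure = exposure,
         covariates = covariates),
    class = "joint_model_spec"
  )
}

# Resolve design matrices, priors and measurement rates for a cohort + spec.
joint_inputs <- function(cohort, spec) {
  dsn <- build_design(cohort, exposure = spec$exposure,
                      covariates = spec$covariates)
  ex <- dsn$exposure_col
  Xb <- dsn$X
  Xa <- Xb[, -ex, drop = FALSE]
  bp <- if (is.null(spec$outcome_priors)) prior_preset(colnames(Xb), "vague")
        else spec$outcome_priors
  ap <- if (is.null(spec$exposure_priors)) prior_preset(colnames(Xa), "tight")
        else spec$exposure_priors
  rates <- scenario_rates(spec$scenario, dsn$y)
  list(Xa = Xa, Xb = Xb, ex_col = ex, y = dsn$y,
       reported = Xb[, ex], n_dropped = dsn$n_dropped,
       a_prior = align_priors(ap, colnames(Xa)),
       b_prior = align_priors(bp, colnames(Xb)),
       se = rates$se, fpp = rates$fpp)
}

#' Run the data-augmentation MCMC for the joint misclassification model
#'
#' Alternates an exact Gibbs draw of each record's latent true exposure from
#' its full conditional with adaptive random-walk Metropolis sweeps over the
#' exposure-model and outcome-model coefficients (adaptation is confined to
#' the burn-in). Chains are initialized at overdispersed random coefficient
#' values and latent exposure equal to the report. Post-burn-in draws are
#' pooled across chains; the exposure log odds ratio is summarized by the
#' median and the 2.5th/97.5th percentiles on the log scale, then
#' exponentiated.
#'
#' @param cohort Cohort data frame.
#' @param spec A [joint_model_spec()].
#' @param config An [mcmc_config()].
#' @param on_nonconvergence What to do when any split-R-hat exceeds the
#'   threshold: `"error"` (default), `"warn"`, or `"none"`.
#' @param model_label Label carried into the effect estimate.
#' @return A list of class `mcmc_run`: `alpha_draws` and `beta_draws`
#'   (iteration x chain x coefficient arrays), `latent_prob` (posterior
#'   probability of true exposure per record), `accept` rates per chain,
#'   `convergence` (split-R-hat and effective sample size per coefficient),
#'   `summary` (posterior coefficient table), and `estimate`
#'   (an [effect_estimate()] for the exposure odds ratio).
#' @export
run_mcmc <- function(cohort, spec, config = mcmc_config(),
                     on_nonconvergence = c("error", "warn", "none"),
                     model_label = "corrected") {
  on_nonconvergence <- match.arg(on_nonconvergence)
  stopifnot(inherits(spec, "joint_model_spec"),
            inherits(config, "mcmc_config"))
  inp <- joint_inputs(cohort, spec)
  run_da_chains(inp, config, update_latent = TRUE,
                on_nonconvergence = on_nonconvergence,
                model_label = model_label,
                scenario_label = spec$scenario$label)
}

# Shared chain loop for the joint model and its naive reduction.
run_da_chains <- function(inp, config, update_latent, on_nonconvergence,
                          model_label, scenario_label) {
  pa <- ncol(inp$Xa); pb <- ncol(inp$Xb)
  n_keep <- (config$n_iterations - config$n_burnin) %/% config$thinning
  alpha_draws <- array(NA_real_, c(n_keep, config$n_chains, pa),
                       dimnames = list(NULL, NULL, colnames(inp$Xa)))
  beta_draws <- array(NA_real_, c(n_keep, config$n_chains, pb),
                      dimnames = list(NULL, NULL, colnames(inp$Xb)))
  accept <- data.frame(chain = seq_len(config$n_chains),
                       alpha = NA_real_, beta = NA_real_)
  latent_prob <- 0
  for (k in seq_len(config$n_chains)) {
    set.seed(config$chain_seeds[k])
    a0 <- stats::rnorm(pa, 0, 0.5)
    b0 <- stats::rnorm(pb, 0, 0.5)
    ch <- da_chain_cpp(
      Xa = inp$Xa, Xb = inp$Xb, ex_col = inp$ex_col - 1L,
      y = as.integer(inp$y), reported = as.integer(inp$reported),
      se = inp$se, fpp = inp$fpp,
      a_mean = inp$a_prior$mean, a_sd = inp$a_prior$sd,
      b_mean = inp$b_prior$mean, b_sd = inp$b_prior$sd,
      alpha_init = a0, beta_init = b0,
      n_iter = config$n_iterations, n_burnin = config$n_burnin,
      thin = config$thinning, accept_target = 0.38,
      update_latent = update_latent
    )
    alpha_draws[, k, ] <- ch$alpha
    beta_draws[, k, ] <- ch$beta
    accept$alpha[k] <- ch$accept_alpha
    accept$beta[k] <- ch$accept_beta
    latent_prob <- latent_prob + ch$latent_mean / config$n_chains
  }
  monitored <- if (update_latent) {
    abind_params(beta_draws, alpha_draws)
  } else beta_draws
  convergence <- gelman_rubin(monitored)
  bad <- convergence$rhat > config$rhat_threshold | !is.finite(convergence$rhat)
  if (any(bad) && on_nonconvergence != "none") {
    report <- paste(sprintf("%s: R-hat %.3f", convergence$coefficient[bad],
                            convergence$rhat[bad]), collapse = "; ")
    msg <- paste0("MCMC did not converge (threshold ",
                  config$rhat_threshold, "): ", report)
    if (on_nonconvergence == "error") {
      cond <- simpleError(msg)
      cond$convergence <- convergence
      stop(cond)
    }
    warning(msg)
  }
  pooled_beta <- apply(beta_draws, 3, identity) # (iter*chain) x coef
  qs <- t(apply(pooled_beta, 2, stats::quantile, c(0.5, 0.025, 0.975)))
  summary_tab <- data.frame(
    coefficient = colnames(inp$Xb), median = qs[, 1],
    q2.5 = qs[, 2], q97.5 = qs[, 3], row.names = NULL
  )
  ex_name <- colnames(inp$Xb)[inp$ex_col]
  log_or <- stats::quantile(pooled_beta[, inp$ex_col], c(0.5, 0.025, 0.975))
  estimate <- effect_estimate(
    or_point = exp(log_or[[1]]), ci_lower = exp(log_or[[2]]),
    ci_upper = exp(log_or[[3]]), model_label = model_label,
    interval_kind = "credible"
  )
  structure(
    list(alpha_draws = if (update_latent) alpha_draws else NULL,
         beta_draws = beta_draws,
         latent_prob = if (update_latent) latent_prob else NULL,
         accept = accept, convergence = convergence, summary = summary_tab,
         estimate = estimate, exposure_term = ex_name,
         n_dropped = inp$n_dropped, config = config,
         scenario_label = scenario_label, model_label = model_label),
    class = "mcmc_run"
  )
}

# Concatenate two (iter x chain x coef) draw arrays along the coefficient
# axis, prefixing names to keep them unique.
abind_params <- function(beta, alpha) {
  out <- array(NA_real_,
               c(dim(beta)[1], dim(beta)[2], dim(beta)[3] + dim(alpha)[3]))
  out[, , seq_len(dim(beta)[3])] <- beta
  out[, , dim(beta)[3] + seq_len(dim(alpha)[3])] <- alpha
  dimnames(out) <- list(NULL, NULL,
                        c(paste0("outcome:", dimnames(beta)[[3]]),
                          paste0("exposure:", dimnames(alpha)[[3]])))
  out
}

#' Naive Bayesian logistic regression
#'
#' Fits the outcome logistic model treating the reported exposure as the true
#' exposure, with independent normal priors, using the same random-walk
#' Metropolis kernel as the joint model (the latent exposure is pinned to the
#' report, i.e. the perfect-classification reduction). The posterior odds
#' ratio is the exponentiated median of the exposure coefficient with a 95%
#' credible interval from the 2.5th and 97.5th percentiles.
#'
#' @param design A [build_design()] result with an exposure term.
#' @param priors Optional [prior_set()] over the design columns (default
#'   vague N(0, 10)).
#' @param config An [mcmc_config()].
#' @param on_nonconvergence See [run_mcmc()].
#' @return An `mcmc_run` (see [run_mcmc()]); `$estimate` holds the credible
#'   effect estimate labelled `"naive Bayes"`.
#' @export
fit_bayes_logistic <- function(design, priors = NULL, config = mcmc_config(),
                               on_nonconvergence = c("error", "warn", "none")) {
  on_nonconvergence <- match.arg(on_nonconvergence)
  stopifnot(inherits(design, "design_matrix"), !is.na(design$exposure_col))
  Xb <- design$X
  bp <- if (is.null(priors)) prior_preset(colnames(Xb), "vague") else priors
  inp <- list(
    Xa = Xb[, -design$exposure_col, drop = FALSE], Xb = Xb,
    ex_col = design$exposure_col, y = design$y,
    reported = Xb[, design$exposure_col], n_dropped = design$n_dropped,
    a_prior = list(mean = rep(0, ncol(Xb) - 1), sd = rep(1, ncol(Xb) - 1)),
    b_prior = align_priors(bp, colnames(Xb)),
    se = rep(1, nrow(Xb)), fpp = rep(0, nrow(Xb))
  )
  run_da_chains(inp, config, update_latent = FALSE,
                on_nonconvergence = on_nonconvergence,
                model_label = "naive Bayes", scenario_label = "none")
}

#' Full conditional probability of latent true exposure
#'
#' For each record, the probability that the true exposure is 1 given the
#' reported exposure, the outcome and the covariates, under current
#' exposure-model coefficients `alpha` and outcome-model coefficients `beta`:
#' proportional to `P(report | X = 1, Y) * P(Y | X = 1, C) * P(X = 1 | C)`,
#' normalized against the `X = 0` branch. The measurement factor uses the
#' scenario's case/control-specific sensitivity and false-positive
#' probability. This is the exact Gibbs conditional used by the sampler; the
#' R implementation serves as a readable reference and testing oracle.
#'
#' @param reported,outcome Binary vectors.
#' @param Xa Exposure-model design matrix (covariates, with intercept).
#' @param Xb Outcome-model design matrix including the exposure column
#'   (whose stored values are ignored).
#' @param ex_col Column index of the exposure term in `Xb`.
#' @param alpha,beta Coefficient vectors conforming to `Xa` / `Xb`.
#' @param scenario A [misclass_scenario()].
#' @return Numeric vector of probabilities.
#' @export
latent_exposure_conditional <- function(reported, outcome, Xa, Xb, ex_col,
                                        alpha, beta, scenario) {
  stopifnot(length(reported) == nrow(Xa), nrow(Xa) == nrow(Xb),
            length(outcome) == length(reported),
            length(alpha) == ncol(Xa), length(beta) == ncol(Xb))
  rates <- scenario_rates(scenario, outcome)
  if (any(rates$se == rates$fpp)) {
    warning("sensitivity equals false-positive probability for some records:",
            " the report carries no information about true exposure")
  }
  la <- stats::plogis(drop(Xa %*% alpha))            # P(X=1 | C)
  eta0 <- drop(Xb[, -ex_col, drop = FALSE] %*% beta[-ex_col])
  p1 <- stats::plogis(eta0 + beta[ex_col])           # P(Y=1 | X=1, C)
  p0 <- stats::plogis(eta0)                          # P(Y=1 | X=0, C)
  py1 <- ifelse(outcome == 1, p1, 1 - p1)
  py0 <- ifelse(outcome == 1, p0, 1 - p0)
  m1 <- ifelse(reported == 1, rates$se, 1 - rates$se)
  m0 <- ifelse(reported == 1, rates$fpp, 1 - rates$fpp)
  f1 <- m1 * py1 * la
  f0 <- m0 * py0 * (1 - la)
  ifelse(f1 + f0 > 0, f1 / (f1 + f0), la)
}

#' One Gibbs sweep over the latent exposure vector
#'
#' Redraws each record's latent true exposure as an independent Bernoulli
#' draw from [latent_exposure_conditional()] (records are conditionally
#' independent given the coefficients).
#'
#' @inheritParams latent_exposure_conditional
#' @param seed Optional local seed.
#' @return Binary vector of updated latent exposures.
#' @export
gibbs_update_latent <- function(reported, outcome, Xa, Xb, ex_col,
                                alpha, beta, scenario, seed = NULL) {
  p <- latent_exposure_conditional(reported, outcome, Xa, Xb, ex_col,
                                   alpha, beta, scenario)
  with_seed(seed, stats::rbinom(length(p), 1L, p))
}

#' One Metropolis sweep over logistic regression coefficients
#'
#' Reference (pure R) componentwise random-walk Metropolis transition
#' targeting the posterior of Bernoulli-logistic coefficients under
#' independent normal priors — the same target as the compiled sampler's
#' coefficient step. One proposal per coefficient; fixed step sizes, so the
#' kernel satisfies detailed balance exactly.
#'
#' @param current Coefficient vector.
#' @param X Design matrix.
#' @param y Binary response (for the exposure model, the latent exposure).
#' @param priors A [prior_set()] over `colnames(X)`.
#' @param step_sizes Proposal standard deviations (scalar or per coefficient).
#' @return List with `coefficients` and `accepted` (logical per coefficient).
#' @export
update_coefficients <- function(current, X, y, priors, step_sizes = 0.2) {
  stopifnot(length(current) == ncol(X), all(y %in% c(0, 1)))
  pr <- align_priors(priors, colnames(X))
  step_sizes <- rep_len(step_sizes, ncol(X))
  eta <- drop(X %*% current)
  loglik <- function(eta) sum(ifelse(y == 1, stats::plogis(eta, log.p = TRUE),
                                     stats::plogis(-eta, log.p = TRUE)))
  ll <- loglik(eta)
  accepted <- logical(ncol(X))
  for (j in seq_len(ncol(X))) {
    delta <- stats::rnorm(1, 0, step_sizes[j])
    prop <- current[j] + delta
    eta_prop <- eta + X[, j] * delta
    ll_prop <- loglik(eta_prop)
    lp_diff <- stats::dnorm(prop, pr$mean[j], pr$sd[j], log = TRUE) -
      stats::dnorm(current[j], pr$mean[j], pr$sd[j], log = TRUE)
    if (log(stats::runif(1)) < ll_prop - ll + lp_diff) {
      current[j] <- prop
      eta <- eta_prop
      ll <- ll_prop
      accepted[j] <- TRUE
    }
  }
  list(coefficients = current, accepted = accepted)
}
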