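#' Maximum-likelihood logistic regression with Wald interval
#'
#' Fits the unconditional logistic model by IRLS ([stats::glm()]) and
#' packages the exposure odds ratio with a 95% Wald interval on the log
#' scale (the default), or a profile-likelihood interval when requested.
#' Complete-case filtering happens upstream in [build_design()]; the count of
#' dropped records travels with the design. Separation or non-convergence is
#' an error carrying the iteration trace rather than a silently unstable
#' estimate.
#'
#' @param design A [build_design()] result with an exposure term.
#' @param ci_method `"wald"` (default) or `"profile"`.
#' @param model_label Label for the effect estimate.
#' @return A list of class `logistic_fit`: `coefficients`, `vcov`, `fit`
#'   (the glm object) and `estimate` (an [effect_estimate()]).
#' @export
fit_logistic_mle <- function(design, ci_method = c("wald", "profile"),
                             model_label = "fully adjusted") {
  ci_method <- match.arg(ci_method)
  stopifnot(inherits(design, "design_matrix"), !is.na(design$exposure_col))
  dat <- as.data.frame(design$X[, -1, drop = FALSE])
  dat$.y <- design$y
  fit <- stats::glm(.y ~ ., data = dat, family = stats::binomial())
  co <- stats::coef(fit)
  V <- stats::vcov(fit)
  se_all <- sqrt(diag(V))
  if (!fit$converged || any(!is.finite(se_all)) || any(se_all > 50)) {
    stop("logistic fit failed (separation or non-convergence) after ",
         fit$iter, " IRLS iterations; coefficient scale: ",
         paste(sprintf("%s=%.2f", names(co), co), collapse = ", "))
  }
  # glm mangles column names via make.names; map by position (intercept first)
  ex <- design$exposure_col
  log_or <- co[ex]
  if (ci_method == "wald") {
    se <- se_all[ex]
    lims <- log_or + c(-1, 1) * stats::qnorm(0.975) * se
  } else {
    if (!requireNamespace("MASS", quietly = TRUE)) {
      stop("profile intervals require the MASS package")
    }
    ci <- suppressMessages(stats::confint(fit, parm = ex, level = 0.95))
    lims <- as.numeric(ci)
  }
  names(co) <- design$labels
  dimnames(V) <- list(design$labels, design$labels)
  structure(
    list(coefficients = co, vcov = V, fit = fit,
         n_dropped = design$n_dropped,
         estimate = effect_estimate(
           or_point = exp(log_or), ci_lower = exp(lims[1]),
           ci_upper = exp(lims[2]), model_label = model_label,
           interval_kind = "confidence")),
    class = "logistic_fit"
  )
}

#' Crude, matching-factors-only and fully adjusted frequentist estimates
#'
#' The three misclassification-naive frequentist models for the prenatal
#' exposure odds ratio: crude (exposure only), matching factors only (sex,
#' centered age, region), and fully adjusted (all covariates selected a
#' priori).
#'
#' @param cohort Cohort data frame.
#' @param exposure Reported-exposure column name.
#' @return A data frame of stacked [effect_estimate()] rows.
#' @export
fit_naive_models <- function(cohort, exposure = "reported_prenatal") {
  rows <- list(
    fit_logistic_mle(build_design(cohort, exposure, covariates = character(0)),
                     model_label = "crude")$estimate,
    fit_logistic_mle(build_design(cohort, exposure, matching_covariates()),
                     model_label = "matching factors only")$estimate,
    fit_logistic_mle(build_design(cohort, exposure, charge_covariates()),
                     model_label = "fully adjusted")$estimate
  )
  do.call(rbind, rows)
}

#' Per-window susceptibility analysis
#'
#' One fully adjusted unconditional logistic model per exposure-window
#' indicator (three months pre-conception, each trimester, each of the first
#' three years of life), in window order for forest plotting. A window whose
#' model cannot be fit (e.g. an empty exposure stratum) is returned flagged
#' unestimable with the failure message, never silently dropped.
#'
#' @param cohort Cohort data frame with `win_*` columns.
#' @param covariates Adjustment set.
#' @return A data frame of [effect_estimate()] rows, one per window, with a
#'   `window` column.
#' @export
fit_window_models <- function(cohort, covariates = charge_covariates()) {
  rows <- lapply(seq_along(WINDOW_COLS), function(i) {
    est <- tryCatch(
      fit_logistic_mle(build_design(cohort, WINDOW_COLS[i], covariates),
                       model_label = paste0("window: ", WINDOW_NAMES[i])
      )$estimate,
      error = function(e) effect_estimate(
        NA, NA, NA, model_label = paste0("window: ", WINDOW_NAMES[i]),
        interval_kind = "confidence", estimable = FALSE,
        note = conditionMessage(e))
    )
    est$window <- WINDOW_NAMES[i]
    est
  })
  do.call(rbind, rows)
}

#' Consistency-stratified estimates
#'
#' Two fully adjusted models comparing each reported-use stratum with the
#' unexposed: *occasional* users (less than monthly during pregnancy) vs
#' unexposed, and *consistent* users (at least monthly throughout pregnancy)
#' vs unexposed. By default each contrast is a separate fit excluding the
#' other exposed stratum; `joint = TRUE` instead fits one model with a
#' three-level exposure factor. An empty stratum yields a flagged
#' unestimable row; the other stratum is unaffected.
#'
#' @param cohort Cohort data frame with a `consistency` column.
#' @param covariates Adjustment set.
#' @param joint Fit a single three-level-exposure model instead of two
#'   restricted fits.
#' @return A data frame of [effect_estimate()] rows.
#' @export
fit_consistency_strata <- function(cohort, covariates = charge_covariates(),
                                   joint = FALSE) {
  lab <- as.character(cohort$consistency)
  if (joint) {
    sub <- cohort
    sub$exp_occasional <- as.integer(lab == "occasional")
    sub$exp_consistent <- as.integer(lab == "consistent")
    dsn <- build_design(sub, exposure = "exp_occasional",
                        covariates = c("exp_consistent", covariates))
    fit <- fit_logistic_mle(dsn, model_label = "occasional vs unexposed")
    est_occ <- fit$estimate
    # consistent term: same fit, other coefficient
    idx <- match("exp_consistent", names(fit$coefficients))
    se <- sqrt(fit$vcov[idx, idx])
    lims <- fit$coefficients[idx] + c(-1, 1) * stats::qnorm(0.975) * se
    est_con <- effect_estimate(exp(fit$coefficients[idx]), exp(lims[1]),
                               exp(lims[2]),
                               model_label = "consistent vs unexposed",
                               interval_kind = "confidence")
    return(rbind(est_occ, est_con))
  }
  one <- function(stratum) {
    keep <- lab %in% c("unexposed", stratum)
    label <- paste0(stratum, " vs unexposed")
    if (!any(lab[keep] == stratum)) {
      return(effect_estimate(NA, NA, NA, model_label = label,
                             estimable = FALSE,
                             note = paste0("no ", stratum, " users in cohort")))
    }
    sub <- cohort[keep, , drop = FALSE]
    sub$exp_stratum <- as.integer(as.character(sub$consistency) == stratum)
    tryCatch(
      fit_logistic_mle(build_design(sub, "exp_stratum", covariates),
                       model_label = label)$estimate,
      error = function(e) effect_estimate(NA, NA, NA, model_label = label,
                                          estimable = FALSE,
                                          note = conditionMessage(e))
    )
  }
  rbind(one("occasional"), one("consistent"))
}
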