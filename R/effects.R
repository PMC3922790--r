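#' Construct an effect estimate record
#'
#' A one-row data frame holding an odds ratio with its 95% interval, the
#' limit ratio (upper limit / lower limit, a unitless precision measure),
#' a model label and the interval kind (confidence for frequentist fits,
#' credible for posterior summaries).
#'
#' @param or_point Odds ratio point estimate (positive).
#' @param ci_lower,ci_upper Lower and upper 95% limits (positive).
#' @param model_label Character label identifying the model.
#' @param interval_kind Either `"confidence"` or `"credible"`.
#' @param estimable Logical; `FALSE` marks a stratum or window where the
#'   model could not be fit. Limits may then be `NA`.
#' @param note Free-text diagnostic note (e.g. why a fit was unestimable).
#' @return A one-row `data.frame` of class `effect_estimate` with columns
#'   `model_label`, `or_point`, `ci_lower`, `ci_upper`, `limit_ratio`,
#'   `interval_kind`, `estimable`, `note`.
#' @export
effect_estimate <- function(or_point, ci_lower, ci_upper, model_label,
                            interval_kind = c("confidence", "credible"),
                            estimable = TRUE, note = "") {
  interval_kind <- match.arg(interval_kind)
  if (estimable) {
    stopifnot(is.finite(or_point), or_point > 0,
              is.finite(ci_lower), is.finite(ci_upper),
              ci_lower > 0, ci_upper > 0)
    if (ci_lower > or_point + 1e-12 || or_point > ci_upper + 1e-12) {
      stop("interval does not bracket the point estimate: [",
           ci_lower, ", ", ci_upper, "] vs ", or_point)
    }
    lr <- limit_ratio(ci_lower, ci_upper)
  } else {
    or_point <- NA_real_; ci_lower <- NA_real_; ci_upper <- NA_real_
    lr <- NA_real_
  }
  out <- data.frame(
    model_label = model_label, or_point = or_point,
    ci_lower = ci_lower, ci_upper = ci_upper, limit_ratio = lr,
    interval_kind = interval_kind, estimable = estimable, note = note,
    stringsAsFactors = FALSE
  )
  class(out) <- c("effect_estimate", class(out))
  out
}

#' Confidence/credible limit ratio
#'
#' The upper 95% limit divided by the lower 95% limit, a scale-free
#' summary of the precision of a ratio estimate (CLR for confidence
#' intervals, CrLR for credible intervals). Invariant to rescaling both
#' limits by the same positive constant.
#'
#' @param lower,upper Positive interval limits with `lower <= upper`.
#' @return `upper / lower`, a value `>= 1`.
#' @examples
#' limit_ratio(0.79, 2.2) # 2.78...
#' @export
limit_ratio <- function(lower, upper) {
  if (!is.numeric(lower) || !is.numeric(upper) ||
      any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(lower <= 0) || any(upper <= 0)) {
    stop("limit_ratio() requires positive finite limits")
  }
  if (any(upper < lower)) stop("upper limit smaller than lower limit")
  upper / lower
}

#' Crude odds ratio from a 2x2 table
#'
#' Cross-product odds ratio for exposed/unexposed cases and controls with a
#' Wald 95% confidence interval on the log scale, using the standard error
#' `sqrt(1/a + 1/b + 1/c + 1/d)`. If any single cell is zero the Haldane
#' continuity correction (0.5 added to every cell) is applied and noted; a
#' zero *margin* (no cases, no controls, no exposed or no unexposed at all)
#' is an error because the odds ratio is undefined.
#'
#' @param a Exposed cases.
#' @param b Unexposed cases.
#' @param c_ Exposed controls.
#' @param d Unexposed controls.
#' @param conf_level Confidence level, default 0.95.
#' @return An [effect_estimate()] labelled `"crude"`.
#' @examples
#' crude_or_2x2(70, 491, 40, 300) # OR 1.07, as in a 943-child cohort
#' @export
crude_or_2x2 <- function(a, b, c_, d, conf_level = 0.95) {
  cells <- c(a = a, b = b, c = c_, d = d)
  if (any(!is.finite(cells)) || any(cells < 0)) {
    stop("cell counts must be non-negative finite numbers")
  }
  margins <- c(cases = a + b, controls = c_ + d,
               exposed = a + c_, unexposed = b + d)
  if (any(margins == 0)) {
    stop("degenerate 2x2 table: zero margin(s): ",
         paste(names(margins)[margins == 0], collapse = ", "))
  }
  note <- ""
  if (any(cells == 0)) {
    cells <- cells + 0.5
    note <- "Haldane 0.5 continuity correction applied (zero cell)"
  }
  log_or <- log(cells["a"]) + log(cells["d"]) - log(cells["b"]) - log(cells["c"])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  effect_estimate(
    or_point = exp(log_or),
    ci_lower = exp(log_or - z * se),
    ci_upper = exp(log_or + z * se),
    model_label = "crude", interval_kind = "confidence", note = note
  )
}
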