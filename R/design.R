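WINDOW_NAMES <- c("preconception", "trimester1", "trimester2", "trimester3",
                  "year1", "year2", "year3")
WINDOW_COLS <- paste0("win_", WINDOW_NAMES)

EDUCATION_LEVELS <- c("college_degree", "high_school", "some_college")
RACE_LEVELS <- c("white_non_hispanic", "other")
REGION_LEVELS <- paste0("region", 1:5)
CONSISTENCY_LEVELS <- c("unexposed", "occasional", "consistent")

#' Covariate sets for the adjusted models
#'
#' `charge_covariates()` lists the full confounder set selected a priori for
#' the adjusted models: maternal education (reference: college degree),
#' race/ethnicity (reference: white non-Hispanic), parity (ordinal integer),
#' pet ownership during pregnancy, and the frequency-matching factors —
#' child's sex (male = 0), age at interview (years, centered) and region of
#' birth (5 indicator-coded levels, reference: region1).
#' `matching_covariates()` lists the matching factors alone.
#'
#' @return Character vector of cohort column names.
#' @export
charge_covariates <- function() {
  c("education", "race_eth", "parity", "pet_ownership",
    "sex", "age_centered", "region")
}

#' @rdname charge_covariates
#' @export
matching_covariates <- function() c("sex", "age_centered", "region")

#' Validate a cohort table
#'
#' Checks the column schema written by the generator: presence of the
#' required columns, binary columns actually binary, factor columns within
#' their level sets, and internal consistency between the reported prenatal
#' exposure, the window flags and the consistency label. Returns an itemized
#' error naming each violated column.
#'
#' @param cohort A cohort `data.frame`.
#' @param require_windows Also require the window flags/consistency columns.
#' @return The cohort, invisibly, coerced so categorical columns are factors
#'   with the canonical level order.
#' @export
validate_cohort <- function(cohort, require_windows = TRUE) {
  required <- c("outcome", "reported_prenatal", charge_covariates())
  if (require_windows) {
    required <- c(required, WINDOW_COLS, "consistency")
  }
  problems <- character(0)
  missing <- setdiff(required, names(cohort))
  if (length(missing)) {
    problems <- c(problems, paste0("missing column(s): ",
                                   paste(missing, collapse = ", ")))
  } else {
    is_binary <- function(v) all(v %in% c(0, 1) | is.na(v))
    bin_cols <- c("outcome", "reported_prenatal", "pet_ownership", "sex",
                  if (require_windows) WINDOW_COLS)
    if ("true_prenatal" %in% names(cohort)) bin_cols <- c(bin_cols, "true_prenatal")
    for (cl in bin_cols) {
      if (!is_binary(cohort[[cl]])) {
        problems <- c(problems, paste0("column '", cl, "' is not binary 0/1"))
      }
    }
    chk_levels <- list(education = EDUCATION_LEVELS, race_eth = RACE_LEVELS,
                       region = REGION_LEVELS)
    if (require_windows) chk_levels$consistency <- CONSISTENCY_LEVELS
    for (cl in names(chk_levels)) {
      bad <- setdiff(unique(stats::na.omit(as.character(cohort[[cl]]))),
                     chk_levels[[cl]])
      if (length(bad)) {
        problems <- c(problems, paste0("column '", cl,
                                       "' has unknown level(s): ",
                                       paste(bad, collapse = ", ")))
      } else {
        cohort[[cl]] <- factor(cohort[[cl]], levels = chk_levels[[cl]])
      }
    }
    if (!all(cohort$parity >= 1, na.rm = TRUE)) {
      problems <- c(problems, "column 'parity' must be an integer >= 1")
    }
    if (require_windows && !length(problems)) {
      cc <- stats::complete.cases(
        cohort[, c("reported_prenatal", WINDOW_COLS, "consistency")])
      rep1 <- cohort$reported_prenatal[cc] == 1
      prenatal_any <- rowSums(cohort[cc, WINDOW_COLS[1:4], drop = FALSE]) > 0
      if (any(prenatal_any & !rep1)) {
        problems <- c(problems,
                      "prenatal window flag set for record(s) with reported_prenatal = 0")
      }
      lab <- as.character(cohort$consistency[cc])
      if (any((lab != "unexposed") != rep1)) {
        problems <- c(problems,
                      "consistency label inconsistent with reported_prenatal")
      }
    }
  }
  if (length(problems)) {
    stop("cohort schema violations:\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  invisible(cohort)
}

#' Build a logistic design matrix from a cohort
#'
#' Indicator-codes the categorical covariates against their reference levels
#' (college degree, white non-Hispanic, region1), keeps parity as an ordinal
#' integer and age as centered years, and prepends an intercept. The exposure
#' term, when present, is placed immediately after the intercept. Rows with
#' missing values in any used column are dropped (complete-case filtering)
#' and the number dropped is recorded.
#'
#' @param cohort Cohort data frame (see [validate_cohort()]).
#' @param exposure Name of the binary exposure column, or `NULL` for a
#'   covariate-only design (used by the latent exposure model).
#' @param covariates Character vector of covariate column names.
#' @return A list of class `design_matrix`: `X` (numeric matrix with
#'   intercept), `y` (response), `exposure_col` (column index of the exposure
#'   term or `NA`), `labels`, `n_dropped`, and `rows_kept` (row indices into
#'   the original cohort).
#' @export
build_design <- function(cohort, exposure = "reported_prenatal",
                         covariates = charge_covariates()) {
  used <- c("outcome", exposure, covariates)
  stopifnot(all(used %in% names(cohort)))
  dat <- cohort[, used, drop = FALSE]
  cc <- stats::complete.cases(dat)
  n_dropped <- sum(!cc)
  dat <- dat[cc, , drop = FALSE]
  for (cl in intersect(names(dat),
                       c("education", "race_eth", "region", "consistency"))) {
    lev <- switch(cl, education = EDUCATION_LEVELS, race_eth = RACE_LEVELS,
                  region = REGION_LEVELS, consistency = CONSISTENCY_LEVELS)
    dat[[cl]] <- factor(as.character(dat[[cl]]), levels = lev)
  }
  rhs <- paste(c(if (!is.null(exposure)) exposure, covariates),
               collapse = " + ")
  fml <- stats::as.formula(paste("outcome ~", rhs))
  X <- stats::model.matrix(fml, data = dat)
  colnames(X)[1] <- "intercept"
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  structure(
    list(X = X, y = dat$outcome,
         exposure_col = if (is.null(exposure)) NA_integer_
                        else match(exposure, colnames(X)),
         labels = colnames(X), n_dropped = n_dropped,
         rows_kept = which(cc)),
    class = "design_matrix"
  )
}
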