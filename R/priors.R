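#' Normal prior set for logistic regression coefficients
#'
#' One independent normal prior (mean, variance) per design column. Presets:
#' `"vague"` is N(0, 10) on every coefficient, `"tight"` is N(0, 1);
#' `"informative"` priors are study-specific and must be supplied as a table
#' (see [read_prior_table()]), with any column not listed falling back to the
#' vague prior.
#'
#' @param columns Character vector of design-matrix column labels.
#' @param mean,variance Scalars or vectors recycled over `columns`.
#' @return A data frame of class `prior_set` with columns `column`, `mean`,
#'   `variance`.
#' @export
prior_set <- function(columns, mean = 0, variance = 10) {
  stopifnot(length(columns) >= 1, all(nzchar(columns)),
            !anyDuplicated(columns))
  mean <- rep_len(mean, length(columns))
  variance <- rep_len(variance, length(columns))
  if (any(!is.finite(variance)) || any(variance <= 0)) {
    stop("prior variances must be positive and finite")
  }
  out <- data.frame(column = columns, mean = mean, variance = variance,
                    stringsAsFactors = FALSE)
  class(out) <- c("prior_set", class(out))
  out
}

#' @rdname prior_set
#' @param preset One of `"vague"` (N(0,10)) or `"tight"` (N(0,1)).
#' @export
prior_preset <- function(columns, preset = c("vague", "tight")) {
  preset <- match.arg(preset)
  v <- switch(preset, vague = 10, tight = 1)
  prior_set(columns, mean = 0, variance = v)
}

#' Read a user-supplied prior table from JSON
#'
#' The JSON file is a list of objects with fields `column`, `mean`,
#' `variance`. Columns of the target design matrix not present in the table
#' receive the vague N(0, 10) prior, so a partial table (say, informative
#' priors for maternal education, race/ethnicity and parity only) is valid.
#'
#' @param path JSON file path.
#' @param columns Design-matrix column labels the prior set must cover.
#' @return A `prior_set` covering every column in `columns`.
#' @export
read_prior_table <- function(path, columns) {
  tab <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(all(c("column", "mean", "variance") %in% names(tab)))
  unknown <- setdiff(tab$column, columns)
  if (length(unknown)) {
    warning("prior table names columns absent from the design: ",
            paste(unknown, collapse = ", "))
  }
  base <- prior_set(columns)
  idx <- match(columns, tab$column)
  hit <- !is.na(idx)
  base$mean[hit] <- tab$mean[idx[hit]]
  base$variance[hit] <- tab$variance[idx[hit]]
  base
}

#' Match a prior set to design columns
#'
#' @param priors A `prior_set`.
#' @param columns Design column labels, in design order.
#' @return List with numeric vectors `mean` and `sd` aligned to `columns`.
#' @keywords internal
align_priors <- function(priors, columns) {
  stopifnot(inherits(priors, "prior_set"))
  idx <- match(columns, priors$column)
  if (anyNA(idx)) {
    stop("no prior supplied for design column(s): ",
         paste(columns[is.na(idx)], collapse = ", "))
  }
  list(mean = priors$mean[idx], sd = sqrt(priors$variance[idx]))
}
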