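#' Define a misclassification scenario
#'
#' A scenario fixes the four measurement probabilities of retrospective
#' exposure report, treated as known constants ("certain misclassification"):
#' sensitivity (probability a truly exposed participant reports exposure) and
#' false-positive probability (FPP, probability a truly unexposed participant
#' reports exposure; 1 - specificity), each separately for cases and controls.
#'
#' Scenarios are classified into four differential-recall groups:
#' \describe{
#'   \item{1}{sensitivity and FPP greater among controls,}
#'   \item{2}{non-differential (equal between cases and controls),}
#'   \item{3}{sensitivity and FPP greater among cases,}
#'   \item{4}{sensitivity greater among cases, FPP equal.}
#' }
#'
#' Identifiability requires the report to carry information about true
#' exposure, i.e. sensitivity strictly above FPP in each group. Scenarios
#' violating that are rejected unless `allow_nonidentifiable = TRUE`, in
#' which case a warning is issued and computation proceeds.
#'
#' @param se_case,se_control Sensitivity among cases / controls, in `[0, 1]`.
#' @param fpp_case,fpp_control False-positive probability among cases /
#'   controls, in `[0, 1]`.
#' @param label Scenario label (defaults to a compact Se/FPP string).
#' @param group Integer 1-4 differential-recall group, or `NA` if unknown.
#' @param allow_nonidentifiable Downgrade the Se <= FPP guard to a warning.
#' @return A list of class `misclass_scenario`.
#' @export
misclass_scenario <- function(se_case, se_control, fpp_case, fpp_control,
                              label = NULL, group = NA_integer_,
                              allow_nonidentifiable = FALSE) {
  p <- c(se_case = se_case, se_control = se_control,
         fpp_case = fpp_case, fpp_control = fpp_control)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("scenario probabilities must lie in [0, 1]: ",
         paste(sprintf("%s=%s", names(p), p), collapse = ", "))
  }
  ident <- se_case > fpp_case && se_control > fpp_control
  if (!ident) {
    msg <- paste0("non-identifiable scenario: sensitivity must exceed the ",
                  "false-positive probability in each group (cases: Se=",
                  se_case, ", FPP=", fpp_case, "; controls: Se=", se_control,
                  ", FPP=", fpp_control, ")")
    if (allow_nonidentifiable) warning(msg) else stop(msg)
  }
  if (is.null(label)) {
    label <- sprintf("Se %.2f/%.2f FPP %.2f/%.2f",
                     se_case, se_control, fpp_case, fpp_control)
  }
  if (!is.na(group)) stopifnot(group %in% 1:4)
  structure(
    list(se_case = se_case, se_control = se_control,
         fpp_case = fpp_case, fpp_control = fpp_control,
         label = label, group = as.integer(group),
         identifiable = ident),
    class = "misclass_scenario"
  )
}

#' Perfect-classification scenario
#'
#' Sensitivity 1 and FPP 0 in both groups; under it the reported exposure
#' equals the true exposure and the corrected model reduces to the naive one.
#' @return A `misclass_scenario`.
#' @export
perfect_scenario <- function() {
  misclass_scenario(1, 1, 0, 0, label = "perfect classification", group = 2L)
}

#' Per-record sensitivity and false-positive probability
#'
#' Expands a scenario into record-level `se` and `fpp` vectors according to
#' each record's case/control status.
#'
#' @param scenario A [misclass_scenario()].
#' @param outcome Binary vector (1 = case, 0 = control).
#' @return A list with numeric vectors `se` and `fpp`.
#' @keywords internal
scenario_rates <- function(scenario, outcome) {
  stopifnot(inherits(scenario, "misclass_scenario"),
            all(outcome %in% c(0, 1)))
  list(se  = ifelse(outcome == 1, scenario$se_case, scenario$se_control),
       fpp = ifelse(outcome == 1, scenario$fpp_case, scenario$fpp_control))
}

#' Build a sensitivity/false-positive-probability scenario grid
#'
#' Constructs the cross-product of baseline sensitivity and FPP values in the
#' four differential-recall groups. The baseline values apply to the group
#' with the *lower* reporting accuracy; the favored group's parameter is
#' shifted up by `differential_offset`:
#' group 1 adds the offset to the controls' Se and FPP, group 2 uses equal
#' values, group 3 adds it to the cases' Se and FPP, and group 4 adds it to
#' the cases' Se only. Scenarios whose shifted probabilities leave `[0, 1]`,
#' or that fail the identifiability guard (Se <= FPP in either group), are
#' dropped with a message.
#'
#' @param se_steps Baseline sensitivities, typically within `[0.70, 1.00]`.
#' @param fpp_steps Baseline false-positive probabilities, typically within
#'   `[0.00, 0.20]`.
#' @param differential_offset Amount added to the favored group's
#'   probabilities in groups 1, 3 and 4 (default 0.10).
#' @param groups Which of the four groups to include.
#' @param quiet Suppress the message listing dropped scenarios.
#' @return A list of `misclass_scenario` objects with class `scenario_grid`.
#' @export
build_grid <- function(se_steps = c(0.70, 0.80, 0.90, 1.00),
                       fpp_steps = c(0.00, 0.05, 0.10, 0.20),
                       differential_offset = 0.10,
                       groups = 1:4, quiet = FALSE) {
  stopifnot(all(se_steps >= 0 & se_steps <= 1),
            all(fpp_steps >= 0 & fpp_steps <= 1),
            differential_offset >= 0, all(groups %in% 1:4))
  out <- list()
  dropped <- character(0)
  for (g in sort(unique(as.integer(groups)))) {
    for (se in se_steps) {
      for (fpp in fpp_steps) {
        off <- differential_offset
        par <- switch(as.character(g),
          "1" = c(se, se + off, fpp, fpp + off),
          "2" = c(se, se, fpp, fpp),
          "3" = c(se + off, se, fpp + off, fpp),
          "4" = c(se + off, se, fpp, fpp)
        ) # order: se_case, se_control, fpp_case, fpp_control
        lab <- sprintf("g%d Se %.2f FPP %.2f", g, se, fpp)
        sc <- tryCatch(
          misclass_scenario(par[1], par[2], par[3], par[4],
                            label = lab, group = g),
          error = function(e) conditionMessage(e)
        )
        if (inherits(sc, "misclass_scenario")) {
          out[[length(out) + 1L]] <- sc
        } else {
          dropped <- c(dropped, paste0(lab, ": ", sc))
        }
      }
    }
  }
  if (length(dropped) && !quiet) {
    message(length(dropped), " inadmissible scenario(s) dropped:\n  ",
            paste(dropped, collapse = "\n  "))
  }
  if (!length(out)) stop("no admissible scenarios in the requested grid")
  structure(out, class = "scenario_grid", dropped = dropped)
}

#' Read / write scenario lists as JSON
#'
#' @param path File path.
#' @param grid A `scenario_grid` or list of `misclass_scenario` objects.
#' @return `read_scenarios` returns a `scenario_grid`.
#' @export
read_scenarios <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(raw, function(s) {
    misclass_scenario(s$se_case, s$se_control, s$fpp_case, s$fpp_control,
                      label = s$label,
                      group = if (is.null(s$group)) NA_integer_ else s$group)
  })
  structure(out, class = "scenario_grid")
}

#' @rdname read_scenarios
#' @export
write_scenarios <- function(grid, path) {
  payload <- lapply(grid, function(s) {
    s[c("se_case", "se_control", "fpp_case", "fpp_control", "label", "group")]
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Tabulate a scenario grid
#'
#' @param x A `scenario_grid`.
#' @param ... Ignored.
#' @return A data frame with one row per scenario.
#' @export
as.data.frame.scenario_grid <- function(x, ...) {
  do.call(rbind, lapply(x, function(s) {
    data.frame(label = s$label, group = s$group,
               se_case = s$se_case, se_control = s$se_control,
               fpp_case = s$fpp_case, fpp_control = s$fpp_control,
               stringsAsFactors = FALSE)
  }))
}
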