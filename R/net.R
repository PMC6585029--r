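#' Net DALY score
#'
#' The net human-health effect of a scenario: patient DALYs plus
#' environmental DALYs, both in person-years, merged into a single score.
#'
#' @param daly_patient Patient DALYs (YLD + YLL).
#' @param daly_env Environmental Human Health DALYs.
#' @return `daly_patient + daly_env`.
#' @export
net_daly <- function(daly_patient, daly_env) {
  if (!is.finite(daly_patient) || !is.finite(daly_env))
    stop("inputs must be finite", call. = FALSE)
  daly_patient + daly_env
}

#' Assemble a scenario result
#'
#' @param scenario Scenario id.
#' @param outcomes An [compute_outcomes()] summary.
#' @param daly_env Environmental DALYs of the scenario.
#' @return An object of class `scenario_result` with `yld`, `yll`,
#'   `daly_patient`, `qaly`, `daly_env`, `daly_net`.
#' @export
scenario_result <- function(scenario, outcomes, daly_env) {
  structure(list(scenario = scenario,
                 yld = outcomes$yld, yll = outcomes$yll,
                 daly_patient = outcomes$daly, qaly = outcomes$qaly,
                 daly_env = daly_env,
                 daly_net = net_daly(outcomes$daly, daly_env)),
            class = "scenario_result")
}

result_metrics <- c("yld", "yll", "daly_patient", "qaly", "daly_env", "daly_net")

#' Compare a scenario against a reference
#'
#' Absolute deltas (`treatment - reference`; negative = avoided burden)
#' and percentage deltas (`100 * delta / reference`) for every metric.
#' A zero reference metric yields `NA` for the percentage.
#'
#' @param result A [scenario_result()] for the treatment.
#' @param reference A [scenario_result()] for the reference scenario
#'   (treatment interruption by convention).
#' @return An object of class `comparison_result`: data frame with one row
#'   per metric (`metric`, `treatment`, `reference`, `delta`, `pct`).
#' @export
compare_scenarios <- function(result, reference) {
  stopifnot(inherits(result, "scenario_result"),
            inherits(reference, "scenario_result"))
  tr <- unlist(result[result_metrics])
  rf <- unlist(reference[result_metrics])
  delta <- tr - rf
  pct <- ifelse(rf == 0, NA_real_, 100 * delta / rf)
  structure(data.frame(metric = result_metrics, treatment = tr,
                       reference = rf, delta = delta, pct = pct,
                       row.names = NULL),
            class = c("comparison_result", "data.frame"),
            scenarios = c(result$scenario, reference$scenario))
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result> ", x$scenario, "\n", sep = "")
  cat(sprintf("  YLD %.2f  YLL %.2f  patient DALY %.2f  QALY %.2f\n",
              x$yld, x$yll, x$daly_patient, x$qaly))
  cat(sprintf("  environmental DALY %.3f  net DALY %.2f\n", x$daly_env, x$daly_net))
  invisible(x)
}

#' @export
print.comparison_result <- function(x, ...) {
  sc <- attr(x, "scenarios")
  cat("<comparison_result> ", sc[1], " vs ", sc[2], "\n", sep = "")
  y <- x
  for (col in c("treatment", "reference", "delta", "pct"))
    y[[col]] <- round(y[[col]], 2)
  print.data.frame(y)
  invisible(x)
}
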