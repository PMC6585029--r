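#' Years Lived with Disability of a cohort trace
#'
#' Accumulates `dw(i) * p(i, t) / 12` over the distributions in force each
#' month: both stable states carry the residual-state weight, all tunnel
#' (relapse) states the acute-state weight. The death state is excluded —
#' fatal burden enters once, through YLL.
#'
#' @param trace A [run_cohort()] trace.
#' @param dw Disability weights, default [default_disability_weights()].
#' @return Total YLD in person-years, with a `per_cycle` attribute.
#' @export
compute_yld <- function(trace, dw = default_disability_weights()) {
  stopifnot(inherits(trace, "cohort_trace"))
  occ <- state_months(trace)
  sp <- trace$space
  if (!all(c(sp$stable, sp$relapse) %in% colnames(occ)))
    stop("trace and state space do not match", call. = FALSE)
  per_cycle <- (dw$dw_stable * rowSums(occ[, sp$stable, drop = FALSE]) +
                dw$dw_relapse * rowSums(occ[, sp$relapse, drop = FALSE])) / 12
  structure(sum(per_cycle), per_cycle = per_cycle)
}

#' Years of Life Lost of a cohort trace
#'
#' Each death is weighted by the residual life expectancy at the attained
#' age of the month it occurs in, so the cohort "ages" month by month and
#' later deaths cost fewer life-years. No discounting is applied.
#'
#' @param trace A [run_cohort()] trace.
#' @param life_table Life table used for the residual-life-expectancy
#'   lookup.
#' @param method `"lookup"` evaluates the life table at each age of death;
#'   `"linear"` decrements the starting value linearly by 1/12 year per
#'   month (an alternative reading of the monthly aging adjustment).
#' @return Total YLL in person-years, with a `per_cycle` attribute.
#' @export
compute_yll <- function(trace, life_table, method = c("lookup", "linear")) {
  stopifnot(inherits(trace, "cohort_trace"))
  method <- match.arg(method)
  d <- trace$deaths
  rle <- switch(method,
    lookup = residual_life_expectancy(life_table, d$age),
    linear = residual_life_expectancy(life_table, d$age - (d$cycle - 1) / 12) -
      (d$cycle - 1) / 12)
  per_cycle <- d$deaths * rle
  structure(sum(per_cycle), per_cycle = per_cycle)
}

#' Disability-Adjusted Life Years
#'
#' @param yld Years Lived with Disability (>= 0).
#' @param yll Years of Life Lost (>= 0).
#' @return `yld + yll`.
#' @export
compute_daly <- function(yld, yll) {
  if (yld < 0 || yll < 0) stop("YLD and YLL must be >= 0", call. = FALSE)
  as.numeric(yld) + as.numeric(yll)
}

#' Quality-Adjusted Life Years of a cohort trace
#'
#' Accumulates `u(i) * p(i, t) / 12` over the monthly distributions. The
#' stable-state utilities are reduced by the expected adverse-event
#' decrement `sum(p_AE * decrement_AE)` (medication-related adverse events
#' are charged in both stable states); relapse months carry the relapse
#' utility; death contributes zero. Adjusted utilities below zero are
#' clamped to zero with a warning.
#'
#' @param trace A [run_cohort()] trace.
#' @param utilities A [default_utilities()] set.
#' @param ae An [make_ae_incidence()] bundle (default: no adverse events).
#' @return Total QALY in person-years, with a `per_cycle` attribute.
#' @export
compute_qaly <- function(trace, utilities, ae = make_ae_incidence(0, 0, 0)) {
  stopifnot(inherits(trace, "cohort_trace"))
  occ <- state_months(trace)
  sp <- trace$space
  dec <- sum(unclass(ae)[names(utilities$decrements)] * utilities$decrements)
  u_sa <- utilities$u_stable_adherent - dec
  u_sn <- utilities$u_stable_nonadherent - dec
  if (u_sa < 0 || u_sn < 0) {
    warning("adverse-event decrement drives a stable utility below 0; clamped")
    u_sa <- max(u_sa, 0); u_sn <- max(u_sn, 0)
  }
  per_cycle <- (u_sa * occ[, "StableAdherent"] +
                u_sn * occ[, "StableNonAdherent"] +
                utilities$u_relapse * rowSums(occ[, sp$relapse, drop = FALSE]) +
                utilities$u_death * occ[, "Death"]) / 12
  structure(sum(per_cycle), per_cycle = per_cycle)
}

#' Full patient-outcome summary for a trace
#'
#' @param trace A [run_cohort()] trace.
#' @param life_table Life table for YLL.
#' @param dw Disability weights.
#' @param utilities Utility set (default chosen from the trace's scenario).
#' @param ae Adverse-event incidence.
#' @param yll_method Passed to [compute_yll()].
#' @return An object of class `outcome_summary`: list with `yld`, `yll`,
#'   `daly`, `qaly` and per-cycle series.
#' @export
compute_outcomes <- function(trace, life_table,
                             dw = default_disability_weights(),
                             utilities = NULL,
                             ae = make_ae_incidence(),
                             yll_method = "lookup") {
  if (is.null(utilities)) utilities <- default_utilities(trace$scenario)
  yld <- compute_yld(trace, dw)
  yll <- compute_yll(trace, life_table, yll_method)
  qaly <- compute_qaly(trace, utilities, ae)
  structure(list(yld = as.numeric(yld), yll = as.numeric(yll),
                 daly = compute_daly(yld, yll), qaly = as.numeric(qaly),
                 per_cycle = data.frame(
                   month = seq_len(trace$T),
                   yld = attr(yld, "per_cycle"),
                   yll = attr(yll, "per_cycle"),
                   qaly = attr(qaly, "per_cycle")),
                 scenario = trace$scenario),
            class = "outcome_summary")
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat("<outcome_summary> scenario ", x$scenario, "\n", sep = "")
  cat(sprintf("  YLD %.2f  YLL %.2f  DALY %.2f  QALY %.2f person-years\n",
              x$yld, x$yll, x$daly, x$qaly))
  invisible(x)
}
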