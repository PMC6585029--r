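#' Default transition-parameter bundle for a treatment scenario
#'
#' Bundles the published monthly transition probabilities for the three
#' maintenance-treatment scenarios — once-monthly injection (`pp1m`),
#' three-monthly injection (`pp3m`) and treatment interruption (`ti`) —
#' together with the synthetic life table and hospital-discharge schedule
#' into a runnable parameter set.
#'
#' Point values (all monthly unless noted): relapse from the stable
#' adherent state 0.0086 (PP1M) / 0.0075 (PP3M); relapse from the stable
#' non-adherent state 0.0639 (PP1M and TI) / 0.0282 (PP3M); 69% of relapses
#' hospitalized; 72% of recoveries return to adherence; discontinuation
#' 0.1200 per month (PP1M) or 0.2816 per 3 months (PP3M); restart after
#' discontinuation 0.1489; SMR 2.58 in stable states and 6.2 in relapse.
#' In `ti` mode patients are adherent only in the first cycle (remaining
#' drug coverage), never restart, and recovered patients re-enter the
#' non-adherent state.
#'
#' @param scenario One of `"pp1m"`, `"pp3m"`, `"ti"`.
#' @param life_table Life table; default [make_life_table()].
#' @param discharge_schedule Discharge schedule; default
#'   [make_discharge_schedule()].
#' @param start_age Cohort mean age (years) at model start.
#' @param cohort_size Number of patients simulated.
#' @return An object of class `transition_parameters`.
#' @export
make_default_parameters <- function(scenario = c("pp1m", "pp3m", "ti"),
                                    life_table = make_life_table(),
                                    discharge_schedule = make_discharge_schedule(),
                                    start_age = 41.61,
                                    cohort_size = 1000) {
  scenario <- match.arg(scenario)
  base <- list(
    scenario = scenario,
    p_relapse_adherent = switch(scenario, pp1m = 0.0086, pp3m = 0.0075, ti = 0.0086),
    p_relapse_nonadherent = switch(scenario, pp1m = 0.0639, pp3m = 0.0282, ti = 0.0639),
    hosp_fraction = 0.69,
    p_return_adherent = 0.72,
    p_discontinue = switch(scenario, pp1m = 0.1200, pp3m = 0.2816, ti = 0),
    discontinuation_period = switch(scenario, pp1m = 1L, pp3m = 3L, ti = 1L),
    p_restart = switch(scenario, pp1m = 0.1489, pp3m = 0.1489, ti = 0),
    smr_stable = 2.58,
    smr_relapse = 6.2,
    ti_mode = identical(scenario, "ti"),
    start_age = start_age,
    cohort_size = cohort_size,
    life_table = life_table,
    discharge_schedule = discharge_schedule)
  validate_parameters(structure(base, class = "transition_parameters"))
}

#' Validate a transition-parameter bundle
#'
#' @param params A `transition_parameters` object.
#' @return The object, invisibly checked; errors on violation.
#' @export
validate_parameters <- function(params) {
  probs <- c("p_relapse_adherent", "p_relapse_nonadherent", "hosp_fraction",
             "p_return_adherent", "p_discontinue", "p_restart")
  for (nm in probs) {
    v <- params[[nm]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop(nm, " must be a probability in [0, 1]", call. = FALSE)
  }
  if (!params$discontinuation_period %in% c(1L, 3L))
    stop("discontinuation_period must be 1 or 3", call. = FALSE)
  if (params$smr_stable < 1 || params$smr_relapse < 1)
    stop("SMRs must be >= 1", call. = FALSE)
  if (!inherits(params$life_table, "life_table"))
    stop("life_table must be a life_table object", call. = FALSE)
  if (!inherits(params$discharge_schedule, "discharge_schedule"))
    stop("discharge_schedule must be a discharge_schedule object", call. = FALSE)
  params
}

#' @export
print.transition_parameters <- function(x, ...) {
  cat("<transition_parameters> scenario ", x$scenario,
      if (x$ti_mode) " (treatment interruption)", "\n", sep = "")
  cat("  relapse adherent/non-adherent: ", x$p_relapse_adherent, " / ",
      x$p_relapse_nonadherent, "; hospitalized fraction ", x$hosp_fraction, "\n", sep = "")
  cat("  discontinue ", x$p_discontinue, " per ", x$discontinuation_period,
      " cycle(s); restart ", x$p_restart, "; SMR ", x$smr_stable, "/",
      x$smr_relapse, "\n", sep = "")
  invisible(x)
}

#' Disability weights of the health states
#'
#' Global Burden of Disease weights: 0.588 for residual (stable)
#' schizophrenia, 0.778 for the acute state (relapse). Death is listed with
#' weight 1.000 in the source table but is excluded from YLD accumulation —
#' fatal burden is counted once, through YLL.
#'
#' @return Named list with `dw_stable`, `dw_relapse`, `dw_death_listed`.
#' @export
default_disability_weights <- function() {
  list(dw_stable = 0.588, dw_relapse = 0.778, dw_death_listed = 1.000)
}

#' Utility values of the health states for a scenario
#'
#' Layperson time-trade-off utilities: 0.865 for stable states (0.916 for
#' the stable adherent state under the three-monthly injection, reflecting
#' the added benefit of less frequent injections), 0.479 in relapse, 0 in
#' death. Adverse-event decrements: acute extrapyramidal symptoms 0.291,
#' weight gain 0.086, diabetes 0.153.
#'
#' @param scenario One of `"pp1m"`, `"pp3m"`, `"ti"`.
#' @return Named list with `u_stable_adherent`, `u_stable_nonadherent`,
#'   `u_relapse`, `u_death`, and `decrements`.
#' @export
default_utilities <- function(scenario = c("pp1m", "pp3m", "ti")) {
  scenario <- match.arg(scenario)
  list(u_stable_adherent = if (scenario == "pp3m") 0.916 else 0.865,
       u_stable_nonadherent = 0.865,
       u_relapse = 0.479,
       u_death = 0,
       decrements = c(eps = 0.291, weight_gain = 0.086, diabetes = 0.153))
}

#' Monthly adverse-event incidence among stable patients
#'
#' The trials report utility decrements weighted by adverse-event
#' incidence, but the incidence values themselves are not published; these
#' defaults are synthetic, trial-plausible monthly probabilities and are
#' flagged as such in the returned object. Decrements apply in both stable
#' states.
#'
#' @param p_eps Monthly probability of acute extrapyramidal symptoms.
#' @param p_weight_gain Monthly probability of clinically relevant (>7%)
#'   weight gain.
#' @param p_diabetes Monthly probability of incident diabetes.
#' @return An object of class `ae_incidence` (named numeric vector with a
#'   `synthetic` attribute).
#' @export
make_ae_incidence <- function(p_eps = 0.010, p_weight_gain = 0.018,
                              p_diabetes = 0.0025) {
  p <- c(eps = p_eps, weight_gain = p_weight_gain, diabetes = p_diabetes)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("adverse-event probabilities must be in [0, 1]", call. = FALSE)
  structure(p, class = "ae_incidence", synthetic = TRUE)
}

#' End-of-life drug mass-flow parameters
#'
#' Fractions governing how much administered paliperidone reaches
#' freshwater: 41% is metabolized in the patient and 64% of the remainder
#' is removed in the wastewater treatment plant. The mg-equivalent dose
#' labels map to paliperidone palmitate mass as 100 mg-eq = 156 mg and
#' 350 mg-eq = 546 mg (factor 1.56).
#'
#' @param fraction_metabolized Fraction of API metabolized in the patient.
#' @param fraction_wwtp_removed Fraction removed in the treatment plant.
#' @return Named list of class `eol_parameters`.
#' @export
make_eol_parameters <- function(fraction_metabolized = 0.41,
                                fraction_wwtp_removed = 0.64) {
  if (fraction_metabolized < 0 || fraction_metabolized > 1 ||
      fraction_wwtp_removed < 0 || fraction_wwtp_removed > 1)
    stop("fractions must be in [0, 1]", call. = FALSE)
  structure(list(fraction_metabolized = fraction_metabolized,
                 fraction_wwtp_removed = fraction_wwtp_removed,
                 mg_per_mg_eq = 1.56),
            class = "eol_parameters")
}
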