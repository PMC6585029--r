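#' Per-state monthly health-care use rates
#'
#' Builds the consumption matrix (states x pathway elements) encoding the
#' monthly use of care per patient in each health state: stable patients on
#' the once-monthly injection use 1 syringe, on the three-monthly injection
#' 0.33 syringes, all stable patients see the GP 0.33 times and the
#' psychiatrist 3 times per month; ambulatory relapse brings 6.2
#' psychiatrist and 2.17 home-nurse visits; the first hospital month is 2
#' general plus 28 psychiatric bed days, later hospital months 30
#' psychiatric bed days. Treatment-interruption patients use no syringes.
#' The death row is all zeros.
#'
#' @param scenario One of `"pp1m"`, `"pp3m"`, `"ti"`.
#' @param space State space, default depth-8 tunnels.
#' @return An object of class `consumption_matrix`: numeric matrix states x
#'   elements with the scenario attached.
#' @export
make_consumption_matrix <- function(scenario = c("pp1m", "pp3m", "ti"),
                                    space = expand_tunnel_states(8)) {
  scenario <- match.arg(scenario)
  elements <- c("syringe_1m", "syringe_3m", "gp_visits", "psychiatrist_visits",
                "ambulatory_visits", "general_bed_days", "psychiatric_bed_days")
  m <- matrix(0, space$n, length(elements),
              dimnames = list(space$states, elements))
  stable_care <- c(gp_visits = 0.33, psychiatrist_visits = 3)
  m[space$stable, names(stable_care)] <- rep(stable_care, each = 2)
  if (scenario == "pp1m") m["StableAdherent", "syringe_1m"] <- 1
  if (scenario == "pp3m") m["StableAdherent", "syringe_3m"] <- 0.33
  m[space$amb, "psychiatrist_visits"] <- 6.2
  m[space$amb, "ambulatory_visits"] <- 2.17
  m["RelapseHosp1", c("general_bed_days", "psychiatric_bed_days")] <- c(2, 28)
  if (space$K > 1)
    m[space$hosp[-1], "psychiatric_bed_days"] <- 30
  structure(m, class = c("consumption_matrix", "matrix"), scenario = scenario)
}

#' Accumulate the consumption profile of a trace
#'
#' Element totals are `sum_t sum_i rate(i, element) * occupancy(i, t)` over
#' the monthly distributions in force — the functional unit of the
#' environmental assessment (use of pathway elements by 1000 patients over
#' one year).
#'
#' @param trace A [run_cohort()] trace.
#' @param matrix A [make_consumption_matrix()] (default built from the
#'   trace's scenario).
#' @return An object of class `consumption_profile`: named numeric vector
#'   of element totals.
#' @export
accumulate_consumption <- function(trace, matrix = NULL) {
  stopifnot(inherits(trace, "cohort_trace"))
  if (is.null(matrix)) matrix <- make_consumption_matrix(trace$scenario, trace$space)
  occ <- state_months(trace)
  if (!all(colnames(occ) %in% rownames(matrix)))
    stop("consumption matrix is missing state rows: ",
         paste(setdiff(colnames(occ), rownames(matrix)), collapse = ", "),
         call. = FALSE)
  totals <- colSums(occ %*% unclass(matrix)[colnames(occ), , drop = FALSE])
  structure(totals, class = "consumption_profile",
            scenario = attr(matrix, "scenario"))
}

#' Re-initiation regimen after a return to adherence
#'
#' Patients returning to the stable adherent state re-initiate their
#' long-acting injection. For the three-monthly product the recommended
#' re-initiation runs on once-monthly syringes for a configurable window
#' (default 2 months — a configuration default, not a published value),
#' which is why the three-monthly scenario's profile contains once-monthly
#' syringes. For the once-monthly product the state rate already charges
#' one syringe per month, so no extra syringes are added.
#'
#' @param scenario One of `"pp1m"`, `"pp3m"`, `"ti"`.
#' @param window_months Re-initiation window (months on PP1M syringes).
#' @param syringes_per_month Syringes charged per re-initiation month.
#' @return List of class `reinitiation_regimen`.
#' @export
make_reinitiation_regimen <- function(scenario = c("pp1m", "pp3m", "ti"),
                                      window_months = 2,
                                      syringes_per_month = 1) {
  scenario <- match.arg(scenario)
  if (window_months < 0 || syringes_per_month < 0)
    stop("regimen counts must be >= 0", call. = FALSE)
  active <- scenario == "pp3m"
  structure(list(scenario = scenario, active = active,
                 window_months = if (active) window_months else 0,
                 syringes_per_month = syringes_per_month),
            class = "reinitiation_regimen")
}

#' Restart flows into the stable adherent state
#'
#' Per-cycle persons entering `StableAdherent` from the non-adherent state
#' or from relapse recovery — the events that trigger re-initiation.
#'
#' @param trace A [run_cohort()] trace.
#' @param schedule The schedule the trace was run with.
#' @return Numeric vector of length T (persons restarting in each cycle).
#' @export
restart_flows <- function(trace, schedule) {
  stopifnot(inherits(trace, "cohort_trace"),
            inherits(schedule, "transition_schedule"))
  sp <- trace$space
  from <- c("StableNonAdherent", sp$relapse)
  vapply(seq_len(trace$T), function(t) {
    sum(trace$occupancy[t, from] *
          schedule$matrices[[t]][from, "StableAdherent"])
  }, numeric(1))
}

#' Syringes charged by re-initiation events
#'
#' @param restarts Persons restarting per cycle (from [restart_flows()]).
#' @param regimen A [make_reinitiation_regimen()].
#' @return Named numeric vector of additional syringes by type.
#' @export
reinitiation_consumption <- function(restarts, regimen) {
  stopifnot(inherits(regimen, "reinitiation_regimen"))
  if (any(restarts < 0)) stop("restart flows must be >= 0", call. = FALSE)
  extra <- if (regimen$active)
    sum(restarts) * regimen$syringes_per_month * regimen$window_months else 0
  c(syringe_1m = extra, syringe_3m = 0)
}

#' Full consumption profile including re-initiation syringes
#'
#' @param trace A [run_cohort()] trace.
#' @param schedule The schedule the trace was run with.
#' @param matrix Consumption matrix (default from scenario).
#' @param regimen Re-initiation regimen (default from scenario).
#' @return A `consumption_profile`.
#' @export
consumption_profile <- function(trace, schedule, matrix = NULL, regimen = NULL) {
  prof <- accumulate_consumption(trace, matrix)
  if (is.null(regimen)) regimen <- make_reinitiation_regimen(trace$scenario)
  extra <- reinitiation_consumption(restart_flows(trace, schedule), regimen)
  prof["syringe_1m"] <- prof["syringe_1m"] + extra["syringe_1m"]
  prof["syringe_3m"] <- prof["syringe_3m"] + extra["syringe_3m"]
  prof
}

#' @export
print.consumption_profile <- function(x, ...) {
  cat("<consumption_profile> scenario ", attr(x, "scenario"), "\n", sep = "")
  print(round(unclass(x), 1))
  invisible(x)
}
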