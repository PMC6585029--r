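#' Run the cohort through a transition schedule
#'
#' Iterates the occupancy vector through the cycle-indexed matrices:
#' `occupancy(t) = occupancy(t-1) %*% matrix(t)`, with row 0 the initial
#' distribution (by default all patients in the stable adherent state).
#' Deaths in cycle `t` are the inflow to the death state under matrix `t`,
#' tagged with the attained age of that month. The distribution *in force
#' during* month `t` is row `t - 1` (no half-cycle correction), which is
#' the convention all accumulation (YLD, QALY, consumption) uses.
#'
#' @param schedule A [build_transition_schedule()] object.
#' @param initial Initial occupancy vector (persons per state); default all
#'   patients in `StableAdherent`.
#' @param cohort_size Cohort size; default taken from the schedule.
#' @return An object of class `cohort_trace`: list with `occupancy`
#'   ((T+1) x n matrix, rows cycle 0..T), `deaths` (data frame `cycle`,
#'   `age`, `deaths`), `space`, `cohort_size`, `scenario`.
#' @export
run_cohort <- function(schedule, initial = NULL, cohort_size = NULL) {
  stopifnot(inherits(schedule, "transition_schedule"))
  bad <- validate_schedule(schedule)
  if (nrow(bad))
    stop("invalid transition schedule: ", nrow(bad), " violation(s); ",
         "first: cycle ", bad$cycle[1], " state ", bad$state[1], " (",
         bad$problem[1], ")", call. = FALSE)
  space <- schedule$space
  n <- space$n
  if (is.null(cohort_size)) cohort_size <- schedule$cohort_size
  if (is.null(initial)) {
    initial <- stats::setNames(numeric(n), space$states)
    initial["StableAdherent"] <- cohort_size
  }
  if (length(initial) != n) stop("initial occupancy has wrong length", call. = FALSE)
  if (abs(sum(initial) - cohort_size) > 1e-6)
    stop("initial occupancy must sum to the cohort size", call. = FALSE)

  T <- schedule$T
  occ <- matrix(0, T + 1, n, dimnames = list(paste0("cycle", 0:T), space$states))
  occ[1, ] <- initial
  deaths <- numeric(T)
  for (t in seq_len(T)) {
    occ[t + 1, ] <- occ[t, ] %*% schedule$matrices[[t]]
    deaths[t] <- occ[t + 1, "Death"] - occ[t, "Death"]
  }
  structure(list(occupancy = occ,
                 deaths = data.frame(cycle = seq_len(T),
                                     age = schedule$ages,
                                     deaths = deaths),
                 space = space, cohort_size = cohort_size,
                 scenario = schedule$scenario, T = T),
            class = "cohort_trace")
}

#' Occupancy in force during each model month
#'
#' @param trace A [run_cohort()] trace.
#' @return T x n matrix; row `t` is the distribution in force during month
#'   `t` (trace row `t - 1`).
#' @export
state_months <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  m <- trace$occupancy[seq_len(trace$T), , drop = FALSE]
  rownames(m) <- paste0("month", seq_len(trace$T))
  m
}

#' Export a cohort trace as a per-cycle data frame
#'
#' One row per cycle (0..T), one column per state, plus cumulative deaths.
#'
#' @param trace A `cohort_trace`.
#' @param path Optional CSV path; if given, the data frame is also written.
#' @return The data frame, invisibly when `path` is given.
#' @export
trace_as_data_frame <- function(trace, path = NULL) {
  stopifnot(inherits(trace, "cohort_trace"))
  df <- data.frame(cycle = 0:trace$T, trace$occupancy, check.names = FALSE,
                   row.names = NULL)
  df$deaths_in_cycle <- c(0, trace$deaths$deaths)
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat("<cohort_trace> scenario ", x$scenario, ", ", x$cohort_size,
      " patients, ", x$T, " cycles\n", sep = "")
  cat("  final: ", round(x$occupancy[x$T + 1, "Death"], 2), " dead, ",
      round(sum(x$occupancy[x$T + 1, x$space$relapse]), 2), " in relapse\n", sep = "")
  invisible(x)
}
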