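#' Build the cycle-indexed transition schedule
#'
#' Constructs one row-stochastic matrix per monthly cycle over the
#' tunnel-expanded state space. Matrix `t` moves the cohort from the
#' distribution in force during month `t` to the one in force during month
#' `t + 1`; the cohort's attained age during month `t` is
#' `start_age + (t - 1) / 12`, and that age's mortality enters matrix `t`.
#'
#' Events within a cycle are resolved in a fixed order: death first (with
#' the SMR of the state at cycle start), then relapse among survivors
#' (split `hosp_fraction` : 1 - `hosp_fraction` into the first hospital /
#' ambulatory tunnel month), then discontinuation or restart among
#' survivors who did not relapse. Tunnel month `k` discharges with hazard
#' `d_k`, recovered patients splitting 72 : 28 into the adherent /
#' non-adherent stable states; the last tunnel month self-loops with
#' probability `1 - d_K`. Discontinuation applies only in cycles divisible
#' by `discontinuation_period`. In `ti_mode` all surviving, non-relapsing
#' adherent mass moves to the non-adherent state (the one month of
#' remaining drug coverage ends), restart is disabled, and all recovered
#' patients enter the non-adherent state.
#'
#' @param params A [make_default_parameters()] bundle.
#' @param space A [expand_tunnel_states()] state space; its depth must
#'   match the discharge schedule's.
#' @param T Number of monthly cycles (default 12).
#' @return An object of class `transition_schedule`: list of `T` matrices
#'   plus the attained age per cycle.
#' @export
build_transition_schedule <- function(params, space = NULL, T = 12) {
  params <- validate_parameters(params)
  if (T < 1) stop("T must be >= 1", call. = FALSE)
  K <- params$discharge_schedule$K
  if (is.null(space)) space <- expand_tunnel_states(K)
  if (!is_state_space(space)) stop("space must be a state_space", call. = FALSE)
  if (space$K != K)
    stop("state-space tunnel depth (", space$K, ") does not match the ",
         "discharge schedule (", K, ")", call. = FALSE)

  d <- params$discharge_schedule$d
  ages <- params$start_age + (seq_len(T) - 1) / 12
  s <- space$states
  n <- space$n
  mats <- vector("list", T)

  for (t in seq_len(T)) {
    M <- matrix(0, n, n, dimnames = list(s, s))
    q_s <- monthly_mortality(ages[t], params$life_table, params$smr_stable)
    q_r <- monthly_mortality(ages[t], params$life_table, params$smr_relapse)

    split_recover <- function(mass) {
      if (params$ti_mode) c(StableAdherent = 0, StableNonAdherent = mass)
      else c(StableAdherent = mass * params$p_return_adherent,
             StableNonAdherent = mass * (1 - params$p_return_adherent))
    }

    # Stable: Adherent
    p_rel <- params$p_relapse_adherent
    disc <- if (params$ti_mode) 1
            else if (t %% params$discontinuation_period == 0) params$p_discontinue
            else 0
    surv <- 1 - q_s
    M["StableAdherent", "Death"] <- q_s
    M["StableAdherent", "RelapseHosp1"] <- surv * p_rel * params$hosp_fraction
    M["StableAdherent", "RelapseAmb1"] <- surv * p_rel * (1 - params$hosp_fraction)
    M["StableAdherent", "StableNonAdherent"] <- surv * (1 - p_rel) * disc
    M["StableAdherent", "StableAdherent"] <- surv * (1 - p_rel) * (1 - disc)

    # Stable: Non-adherent
    p_rel <- params$p_relapse_nonadherent
    restart <- if (params$ti_mode) 0 else params$p_restart
    M["StableNonAdherent", "Death"] <- q_s
    M["StableNonAdherent", "RelapseHosp1"] <- surv * p_rel * params$hosp_fraction
    M["StableNonAdherent", "RelapseAmb1"] <- surv * p_rel * (1 - params$hosp_fraction)
    M["StableNonAdherent", "StableAdherent"] <- surv * (1 - p_rel) * restart
    M["StableNonAdherent", "StableNonAdherent"] <- surv * (1 - p_rel) * (1 - restart)

    # relapse tunnels (hospital and ambulatory share the discharge hazards)
    for (branch in c("RelapseHosp", "RelapseAmb")) {
      for (k in seq_len(K)) {
        from <- paste0(branch, k)
        stay_to <- paste0(branch, min(k + 1, K))
        rec <- split_recover((1 - q_r) * d[k])
        M[from, "Death"] <- q_r
        M[from, "StableAdherent"] <- rec["StableAdherent"]
        M[from, "StableNonAdherent"] <- rec["StableNonAdherent"]
        M[from, stay_to] <- M[from, stay_to] + (1 - q_r) * (1 - d[k])
      }
    }

    M["Death", "Death"] <- 1
    mats[[t]] <- M
  }

  structure(list(matrices = mats, ages = ages, space = space, T = T,
                 scenario = params$scenario, cohort_size = params$cohort_size),
            class = "transition_schedule")
}

#' Diagnostic validation of a transition schedule
#'
#' Reports rows that violate stochasticity (sum != 1), negativity, or the
#' absorbing-death contract. An empty data frame means the schedule is
#' valid.
#'
#' @param schedule A `transition_schedule`.
#' @param tol Row-sum tolerance (default 1e-9).
#' @return Data frame with columns `cycle`, `state`, `problem`, `value`.
#' @export
validate_schedule <- function(schedule, tol = 1e-9) {
  stopifnot(inherits(schedule, "transition_schedule"))
  out <- list()
  for (t in seq_along(schedule$matrices)) {
    M <- schedule$matrices[[t]]
    rs <- rowSums(M)
    bad_sum <- which(abs(rs - 1) > tol)
    for (i in bad_sum)
      out[[length(out) + 1]] <- data.frame(cycle = t, state = rownames(M)[i],
                                           problem = "row sum != 1", value = rs[i])
    neg <- which(apply(M, 1, function(r) any(r < -tol)))
    for (i in neg)
      out[[length(out) + 1]] <- data.frame(cycle = t, state = rownames(M)[i],
                                           problem = "negative entry", value = min(M[i, ]))
    drow <- M["Death", ]
    if (abs(drow["Death"] - 1) > tol || any(abs(drow[names(drow) != "Death"]) > tol))
      out[[length(out) + 1]] <- data.frame(cycle = t, state = "Death",
                                           problem = "death not absorbing",
                                           value = drow["Death"])
  }
  if (!length(out))
    return(data.frame(cycle = integer(), state = character(),
                      problem = character(), value = numeric()))
  rn <- do.call(rbind, out); rownames(rn) <- NULL; rn
}

#' @export
print.transition_schedule <- function(x, ...) {
  cat("<transition_schedule> scenario ", x$scenario, ", ", x$T,
      " monthly cycles, ", x$space$n, " states\n", sep = "")
  cat("  cohort ages ", round(min(x$ages), 2), " to ", round(max(x$ages), 2), " y\n", sep = "")
  invisible(x)
}
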