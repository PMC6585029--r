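# Test helpers: independent oracles and stub objects.

# life table with zero mortality (for limit checks where death is switched off)
zero_mortality_life_table <- function(max_age = 110) {
  structure(data.frame(age = 0:max_age, qx = 0),
            class = c("life_table", "data.frame"))
}

# parameter bundle with all event probabilities zeroed (absorbing stability)
inert_parameters <- function(scenario = "pp1m") {
  p <- make_default_parameters(scenario)
  p$p_relapse_adherent <- 0
  p$p_relapse_nonadherent <- 0
  p$p_discontinue <- 0
  p$p_restart <- 0
  p$life_table <- zero_mortality_life_table()
  p
}

# minimal cohort trace with a prescribed death pattern (for YLL unit checks)
stub_trace_with_deaths <- function(deaths_df, T = 12, space = expand_tunnel_states(8)) {
  occ <- matrix(0, T + 1, space$n, dimnames = list(paste0("cycle", 0:T), space$states))
  occ[, "StableAdherent"] <- 1000
  structure(list(occupancy = occ, deaths = deaths_df, space = space,
                 cohort_size = 1000, scenario = "pp1m", T = T),
            class = "cohort_trace")
}

# Individual-level microsimulation of a transition schedule: n_walkers
# independent patients stepped through the cycle matrices by multinomial
# draws (the sum of iid categorical moves per state is multinomial).
# Returns expected-scale occupancy (fraction * n_walkers) per cycle.
microsim_trace <- function(schedule, n_walkers = 1e5, seed = 42) {
  set.seed(seed)
  s <- schedule$space$states
  n <- length(s)
  counts <- matrix(0, schedule$T + 1, n, dimnames = list(NULL, s))
  counts[1, "StableAdherent"] <- n_walkers
  for (t in seq_len(schedule$T)) {
    M <- schedule$matrices[[t]]
    nxt <- numeric(n)
    for (i in seq_len(n)) {
      ni <- counts[t, i]
      if (ni > 0) nxt <- nxt + drop(stats::rmultinom(1, ni, M[i, ]))
    }
    counts[t + 1, ] <- nxt
  }
  counts
}

# classical abridged life-table accumulation at integer ages (independent
# of the monthly-grid integration in the package)
rle_accumulation_oracle <- function(life_table, age) {
  stopifnot(age == floor(age))
  qx <- life_table$qx[life_table$age >= age]
  lx <- cumprod(c(1, 1 - qx))
  Lx <- (lx[-length(lx)] + lx[-1]) / 2
  sum(Lx)
}

env_fixture_factors <- function() {
  derive_unit_factors(load_env_burden_table(), load_consumption_counts())
}

# published consumption counts as a named profile vector for one scenario
printed_profile <- function(scenario) {
  counts <- load_consumption_counts()
  b <- counts[counts$scenario == scenario, ]
  structure(stats::setNames(b$count, b$element), class = "consumption_profile",
            scenario = scenario)
}

# fabricate a scenario_result from bare numbers (for published-value checks)
manual_result <- function(scenario, yld, yll, qaly, daly_env) {
  scenario_result(scenario,
                  list(yld = yld, yll = yll, daly = yld + yll, qaly = qaly),
                  daly_env)
}
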