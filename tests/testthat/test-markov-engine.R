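test_that("tunnel expansion produces the canonical state ordering", {
  for (K in c(1, 3, 8)) {
    sp <- expand_tunnel_states(K)
    expect_equal(sp$n, 2 * K + 3)
    expect_equal(sp$states,
                 c("StableAdherent", "StableNonAdherent",
                   paste0("RelapseHosp", seq_len(K)),
                   paste0("RelapseAmb", seq_len(K)), "Death"))
    expect_equal(sp$states[sp$n], "Death")
  }
  expect_equal(expand_tunnel_states(8)$n, 19)
  expect_equal(expand_tunnel_states(1)$states,
               c("StableAdherent", "StableNonAdherent", "RelapseHosp1",
                 "RelapseAmb1", "Death"))
  expect_error(expand_tunnel_states(0), "K must be")
  expect_error(expand_tunnel_states(2.5), "K must be")
})

test_that("cycle-probability rescaling follows constant-hazard algebra", {
  expect_equal(convert_cycle_probability(0, 12, 1), 0)
  expect_equal(convert_cycle_probability(1, 12, 1), 1)
  expect_equal(convert_cycle_probability(0.5, 3, 3), 0.5)
  # annual 0.12 to monthly, direct power evaluation as oracle
  expect_equal(convert_cycle_probability(0.12, 12, 1), 1 - 0.88^(1 / 12))
  expect_equal(convert_cycle_probability(0.12, 12, 1), 0.010595,
               tolerance = 5e-4)
  # round trip monthly -> 3-monthly -> monthly
  p3 <- convert_cycle_probability(0.1, 1, 3)
  expect_equal(convert_cycle_probability(p3, 3, 1), 0.1)
  expect_error(convert_cycle_probability(1.2, 12, 1), "\\[0, 1\\]")
})

test_that("monthly mortality applies SMR to the rescaled annual rate and clamps", {
  lt <- structure(data.frame(age = 0:110, qx = 0.012),
                  class = c("life_table", "data.frame"))
  expect_equal(monthly_mortality(50, lt, 1), 1 - 0.988^(1 / 12))
  expect_equal(monthly_mortality(50, lt, 1), 0.0010053, tolerance = 3e-4)
  expect_equal(monthly_mortality(50, lt, 2.58),
               2.58 * (1 - 0.988^(1 / 12)))
  expect_equal(monthly_mortality(50, lt, 5000), 1)  # clamp
  expect_error(monthly_mortality(200, lt, 1), "support")
})

test_that("transition matrices encode the published probabilities under the event ordering", {
  params <- make_default_parameters("pp1m")
  sched <- build_transition_schedule(params)
  expect_equal(validate_schedule(sched), validate_schedule(sched)[0, ])
  M2 <- sched$matrices[[2]]
  q <- monthly_mortality(sched$ages[2], params$life_table, 2.58)
  expect_equal(M2["StableAdherent", "RelapseHosp1"], (1 - q) * 0.0086 * 0.69)
  expect_equal(M2["StableAdherent", "RelapseAmb1"], (1 - q) * 0.0086 * 0.31)
  expect_equal(M2["StableAdherent", "StableNonAdherent"],
               (1 - q) * (1 - 0.0086) * 0.12)
  expect_equal(M2["StableNonAdherent", "StableAdherent"],
               (1 - q) * (1 - 0.0639) * 0.1489)
  # tunnel month k advances to k+1 and discharges 72/28
  d <- params$discharge_schedule$d
  qr <- monthly_mortality(sched$ages[2], params$life_table, 6.2)
  expect_equal(M2["RelapseHosp3", "RelapseHosp4"], (1 - qr) * (1 - d[3]))
  expect_equal(M2["RelapseHosp3", "StableAdherent"], (1 - qr) * d[3] * 0.72)
  # month-8 tunnel self-loops
  expect_equal(M2["RelapseHosp8", "RelapseHosp8"], (1 - qr) * (1 - d[8]))
  expect_equal(M2["RelapseAmb8", "RelapseAmb8"], (1 - qr) * (1 - d[8]))
})

test_that("three-monthly product can only discontinue in cycles divisible by 3", {
  sched <- build_transition_schedule(make_default_parameters("pp3m"))
  for (t in 1:12) {
    disc <- sched$matrices[[t]]["StableAdherent", "StableNonAdherent"]
    if (t %% 3 == 0) expect_gt(disc, 0) else expect_equal(disc, 0)
  }
  # and the applied probability is the printed 3-monthly value
  q <- monthly_mortality(sched$ages[3],
                         make_default_parameters("pp3m")$life_table, 2.58)
  expect_equal(sched$matrices[[3]]["StableAdherent", "StableNonAdherent"],
               (1 - q) * (1 - 0.0075) * 0.2816)
})

test_that("treatment interruption forces non-adherence after the first cycle", {
  params <- make_default_parameters("ti")
  sched <- build_transition_schedule(params)
  trace <- run_cohort(sched)
  # adherent only in month 1 (remaining coverage); exactly 0 afterwards
  expect_equal(unname(trace$occupancy[1, "StableAdherent"]), 1000)
  expect_true(all(trace$occupancy[-1, "StableAdherent"] == 0))
  # recovered TI patients re-enter the non-adherent state, never adherent
  M <- sched$matrices[[5]]
  expect_equal(M["RelapseHosp2", "StableAdherent"], 0)
  expect_gt(M["RelapseHosp2", "StableNonAdherent"], 0)
  expect_equal(M["StableNonAdherent", "StableAdherent"], 0)  # restart disabled
})

test_that("cohort iteration conserves mass and absorbs into death monotonically", {
  for (sc in c("pp1m", "pp3m", "ti")) {
    trace <- run_cohort(build_transition_schedule(make_default_parameters(sc)))
    expect_true(all(abs(rowSums(trace$occupancy) - 1000) < 1e-6))
    expect_true(all(diff(trace$occupancy[, "Death"]) >= -1e-12))
    expect_true(all(trace$occupancy >= -1e-12))
    expect_equal(sum(trace$deaths$deaths),
                 unname(trace$occupancy[13, "Death"]))
  }
})

test_that("identity dynamics leave the occupancy constant", {
  params <- inert_parameters()
  trace <- run_cohort(build_transition_schedule(params))
  expect_true(all(trace$occupancy[, "StableAdherent"] == 1000))
  expect_true(all(trace$occupancy[, colnames(trace$occupancy) != "StableAdherent"] == 0))
})

test_that("cohort trace matches an individual-level microsimulation within 3 SE", {
  sched <- build_transition_schedule(make_default_parameters("pp1m"))
  trace <- run_cohort(sched)
  n_walk <- 1e5
  sim <- microsim_trace(sched, n_walkers = n_walk, seed = 7)
  p_exp <- trace$occupancy / 1000
  p_obs <- sim / n_walk
  se <- sqrt(p_exp * (1 - p_exp) / n_walk)
  # 3 binomial SE per state per cycle (exact-zero cells must agree exactly)
  expect_true(all(abs(p_obs - p_exp) <= 3 * se + 1e-12))
})

test_that("schedule diagnostics flag constructed defects", {
  sched <- build_transition_schedule(make_default_parameters("pp1m"))
  expect_equal(nrow(validate_schedule(sched)), 0)
  bad <- sched
  bad$matrices[[4]]["StableAdherent", "StableAdherent"] <-
    bad$matrices[[4]]["StableAdherent", "StableAdherent"] - 0.1
  rep <- validate_schedule(bad)
  expect_equal(rep$cycle, 4)
  expect_equal(rep$state, "StableAdherent")
  expect_match(rep$problem, "row sum")
  worse <- sched
  worse$matrices[[2]]["Death", "Death"] <- 0.5
  worse$matrices[[2]]["Death", "StableAdherent"] <- 0.5
  rep2 <- validate_schedule(worse)
  expect_true(any(rep2$problem == "death not absorbing"))
  expect_error(run_cohort(bad), "invalid transition schedule")
})

test_that("state space depth must match the discharge schedule", {
  params <- make_default_parameters("pp1m")
  expect_error(build_transition_schedule(params, expand_tunnel_states(4)),
               "does not match")
})
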