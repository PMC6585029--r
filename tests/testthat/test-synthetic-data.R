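test_that("life table calibrates to the residual-life-expectancy anchor", {
  lt <- make_life_table()
  expect_equal(residual_life_expectancy(lt, 41.61), 39.54,
               tolerance = 0.01 / 39.54)
  expect_equal(residual_life_expectancy(lt, 110), 0)
  # RLE strictly decreasing across the support
  ages <- seq(19, 109, by = 5)
  rles <- residual_life_expectancy(lt, ages)
  expect_true(all(diff(rles) < 0))
  # qx valid and non-decreasing beyond age 30
  expect_true(all(lt$qx > 0 & lt$qx <= 1))
  expect_true(all(diff(lt$qx[lt$age >= 30]) >= 0))
})

test_that("calibration is idempotent and the monthly integration agrees with the accumulation oracle", {
  lt1 <- make_life_table()
  lt2 <- make_life_table()
  expect_identical(lt1$qx, lt2$qx)
  for (a in c(30, 42, 65, 90))
    expect_equal(residual_life_expectancy(lt1, a),
                 rle_accumulation_oracle(lt1, a), tolerance = 0.005)
})

test_that("raising the age-independent hazard lowers RLE at every age", {
  lt <- make_life_table()
  b <- attr(lt, "gompertz_b")
  # fixed (uncalibrated) table pair at the same Gompertz level, via the oracle
  mk <- function(A) {
    age <- 0:110
    ch <- A + (b / 0.095) * exp(0.095 * age) * (exp(0.095) - 1)
    q <- 1 - exp(-ch); q[length(q)] <- 1
    structure(data.frame(age = age, qx = q), class = c("life_table", "data.frame"))
  }
  for (a in c(20, 40, 60, 80))
    expect_lt(rle_accumulation_oracle(mk(2 * 5e-4), a),
              rle_accumulation_oracle(mk(5e-4), a))
})

test_that("discharge schedule discretizes a right-skewed stay distribution", {
  ds <- make_discharge_schedule(60, 0.8)
  expect_true(all(ds$d >= 0 & ds$d <= 1))
  expect_equal(length(ds$d), 8)
  # probability conservation: discharge mass plus tail equals 1
  surv <- cumprod(1 - ds$d)
  p_exit <- ds$d * c(1, head(surv, -1))
  expect_equal(sum(p_exit) + surv[8], 1)
  # analytic realized mean hits the target within 2%
  expect_equal(ds$mean_los_days, 60, tolerance = 0.02)
})

test_that("sampled stays reproduce the target mean and right skew", {
  ds <- make_discharge_schedule(60, 0.8)
  set.seed(11)
  los <- sample_los(ds, 1e5)
  expect_equal(mean(los), 60, tolerance = 0.02)
  expect_lt(median(los), mean(los))  # most patients leave before the mean
})

test_that("degenerate dispersion puts all discharge in the month containing the mean", {
  ds <- make_discharge_schedule(45, 0)
  expect_equal(ds$d, c(0, 1, rep(0, 6)))
  set.seed(3)
  expect_true(all(sample_los(ds, 100) == 45))
})

test_that("default parameter bundles carry the published point estimates", {
  p1 <- make_default_parameters("pp1m")
  expect_equal(p1$p_relapse_adherent, 0.0086)
  expect_equal(p1$p_relapse_nonadherent, 0.0639)
  expect_equal(p1$p_discontinue, 0.1200)
  expect_equal(p1$discontinuation_period, 1L)
  expect_equal(p1$p_restart, 0.1489)
  expect_equal(p1$hosp_fraction, 0.69)
  expect_equal(p1$p_return_adherent, 0.72)
  expect_equal(p1$smr_stable, 2.58)
  expect_equal(p1$smr_relapse, 6.2)
  p3 <- make_default_parameters("pp3m")
  expect_equal(p3$p_relapse_adherent, 0.0075)
  expect_equal(p3$p_relapse_nonadherent, 0.0282)
  expect_equal(p3$p_discontinue, 0.2816)
  expect_equal(p3$discontinuation_period, 3L)
  ti <- make_default_parameters("ti")
  expect_true(ti$ti_mode)
  expect_equal(ti$p_restart, 0)
  expect_error(make_default_parameters("other"))
})

test_that("adverse-event bundles validate and are flagged synthetic", {
  ae <- make_ae_incidence(p_eps = 0.1, p_weight_gain = 0, p_diabetes = 0)
  expect_true(attr(ae, "synthetic"))
  u <- default_utilities("pp1m")
  expect_equal(sum(unclass(ae)[names(u$decrements)] * u$decrements), 0.0291)
  expect_error(make_ae_incidence(p_eps = -0.1), "\\[0, 1\\]")
  expect_error(make_ae_incidence(p_eps = 1.1), "\\[0, 1\\]")
})

test_that("parameter sampling is seed-deterministic and respects zero variance", {
  base <- make_default_parameters("pp1m")
  dists <- default_psa_distributions(base)
  s1 <- sample_parameter_set(base, dists, seed = 99)
  s2 <- sample_parameter_set(base, dists, seed = 99)
  expect_identical(s1$p_relapse_adherent, s2$p_relapse_adherent)
  expect_identical(s1$discharge_schedule$d, s2$discharge_schedule$d)
  frozen <- lapply(dists, function(d) { d$sd <- 0; d })
  s0 <- sample_parameter_set(base, frozen, seed = 1)
  expect_equal(s0$p_relapse_adherent, base$p_relapse_adherent)
  expect_equal(s0$smr_relapse, base$smr_relapse)
})

test_that("beta draws match the method-of-moments mean", {
  base <- make_default_parameters("pp1m")
  spec <- default_psa_distributions(base)$p_relapse_nonadherent
  set.seed(5)
  draws <- vapply(runif(10000), function(u) netdaly:::draw_from_spec(spec, u),
                  numeric(1))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - spec$mean), 3 * se + 1e-4)
  expect_true(all(draws > 0 & draws < 1))
})
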