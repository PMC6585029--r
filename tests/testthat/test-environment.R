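test_that("the shipped burden fixture has the published layout", {
  tab <- load_env_burden_table()
  expect_setequal(unique(tab$scenario), c("ti", "pp1m", "pp3m"))
  expect_equal(length(unique(tab$resource)), 11)
  expect_equal(length(unique(tab$element[tab$scenario == "pp1m"])), 10)
  # TI block carries no supply chain (printed N/A)
  expect_equal(length(unique(tab$element[tab$scenario == "ti"])), 5)
  # energy-recovery credits are negative cells
  expect_lt(min(tab$daly), 0)
})

test_that("unit factors reproduce the worked division examples", {
  f <- env_fixture_factors()
  expect_equal(f$care["transport", "psychiatrist_visits"], 3.06e-1 / 34109)
  expect_equal(round(f$care["transport", "psychiatrist_visits"], 9), 8.971e-6)
  expect_equal(f$care["electricity", "psychiatric_bed_days"], 3.79e-1 / 43864)
  # cross-scenario check: the factor scales to the other block's printed cell
  expect_equal(35224 * f$care["transport", "psychiatrist_visits"], 3.16e-1,
               tolerance = 0.01)
  expect_equal(16406 * f$care["electricity", "psychiatric_bed_days"], 1.42e-1,
               tolerance = 0.01)
  # zero burden cell -> zero factor
  expect_equal(f$care["nitrogen", "gp_visits"], 0)
})

test_that("TI-derived care factors reproduce every non-supply cell of the other blocks within 1%", {
  tab <- load_env_burden_table()
  counts <- load_consumption_counts()
  f <- env_fixture_factors()
  for (sc in c("pp1m", "pp3m")) {
    block <- scenario_block(tab, sc)
    for (el in colnames(f$care)) {
      n <- counts$count[counts$scenario == sc & counts$element == el]
      pred <- f$care[, el] * n
      printed <- block[names(pred), el]
      nz <- printed != 0
      expect_true(all(abs(pred[nz] / printed[nz] - 1) < 0.01),
                  label = paste(sc, el, "cells within 1%"))
      expect_true(all(pred[!nz] == 0))
    }
  }
})

test_that("burden computation is linear and reproduces the block totals from printed counts", {
  f <- env_fixture_factors()
  tab <- load_env_burden_table()
  for (sc in c("ti", "pp1m", "pp3m")) {
    bd <- compute_env_burden(printed_profile(sc), f)
    expect_equal(bd$total, sum(scenario_block(tab, sc)), tolerance = 0.005)
    expect_equal(bd$total, sum(bd$element_totals))
    expect_equal(bd$total, sum(bd$resource_totals))
  }
  # homogeneity of degree 1
  p <- printed_profile("pp1m")
  half <- p; half[] <- unclass(p) / 2
  expect_equal(compute_env_burden(half, f)$total,
               compute_env_burden(p, f)$total / 2)
  # all-zero profile
  z <- p; z[] <- 0
  expect_equal(compute_env_burden(z, f)$total, 0)
})

test_that("solve attribution separates re-initiation syringes and still matches the block sum", {
  tab <- load_env_burden_table()
  fs <- derive_unit_factors(tab, attribution = "solve")
  fb <- derive_unit_factors(tab, attribution = "blended")
  # both attributions reproduce the pp3m supply block total on printed counts
  sup3 <- sum(scenario_block(tab, "pp3m")[, c("api", "drug_production",
                                              "packaging", "distribution_supply",
                                              "end_of_life")])
  expect_equal(594 * sum(fs$supply$pp1m) + 2564 * sum(fs$supply$pp3m), sup3)
  expect_equal(3158 * sum(fb$supply$pp3m), sup3)
})

test_that("contribution shares close to 100% and flag degenerate totals", {
  f <- env_fixture_factors()
  for (sc in c("ti", "pp1m", "pp3m")) {
    sh <- contribution_shares(compute_env_burden(printed_profile(sc), f))
    expect_equal(sum(sh$element), 100, tolerance = 0.1 / 100)
    expect_equal(sum(sh$resource), 100, tolerance = 0.1 / 100)
  }
  single <- matrix(2.5, 1, 1, dimnames = list("transport", "gp_visits"))
  expect_equal(unname(contribution_shares(single)$element), 100)
  expect_error(contribution_shares(single * 0), "zero")
})

test_that("hospital resource shares are computed on on-site use (transport excluded)", {
  tab <- load_env_burden_table()
  rs <- resource_shares(scenario_block(tab, "ti"), "general_bed_days")
  expect_equal(unname(rs["electricity"]), 57.66, tolerance = 0.01)
  expect_equal(unname(rs["fuel"]), 40.93, tolerance = 0.01)
})

test_that("end-of-life mass flow subtracts metabolism and treatment removal", {
  expect_equal(eol_emitted_mass(100)$emitted_mg_eq, 100 * 0.59 * 0.36)
  expect_equal(eol_emitted_mass(100)$emitted_mg_eq, 21.24)
  expect_equal(eol_emitted_mass(12 * 100)$emitted_mg_eq, 254.88)
  expect_equal(eol_emitted_mass(100)$emitted_mg_palmitate, 21.24 * 1.56)
  expect_equal(eol_emitted_mass(50, make_eol_parameters(0.41, 1))$emitted_mg_eq, 0)
  expect_error(make_eol_parameters(1.5, 0.5), "\\[0, 1\\]")
  expect_error(eol_emitted_mass(-1), ">= 0")
})

test_that("grand totals stay positive despite negative credit cells", {
  f <- env_fixture_factors()
  for (sc in c("ti", "pp1m", "pp3m")) {
    bd <- compute_env_burden(printed_profile(sc), f)
    expect_gt(bd$total, 0)
    if (sc != "ti") expect_lt(min(bd$cells), 0)
  }
})
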