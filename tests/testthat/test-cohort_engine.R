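test_that("trace occupancy is conserved, bounded and absorbing", {
  b <- default_parameters()
  for (arm in b$arms) {
    tr <- compute_trace(arm, b$settings)
    expect_equal(tr$pfs + tr$pd + tr$death, rep(1, nrow(tr)),
                 tolerance = 1e-9)
    expect_true(all(diff(tr$death) >= -1e-12))
    expect_true(all(tr$pfs >= 0 & tr$pfs <= 1))
    expect_true(all(tr$pd >= 0 & tr$pd <= 1))
    expect_equal(unlist(tr[1L, c("pfs", "pd", "death")]),
                 c(pfs = 1, pd = 0, death = 0))
    # over 99% of the cohort dead at the 15-year horizon
    expect_gt(tr$death[nrow(tr)], 0.99)
  }
})

test_that("partitioned occupancy matches the direct-formula oracle", {
  b <- default_parameters()
  arm <- b$arms$placebo
  tr <- compute_trace(arm, b$settings)
  t <- tr$t_months
  s_os <- weibull_survival(arm$os, t)
  s_pfs <- weibull_survival(arm$pfs, t)
  expect_equal(tr$pd, ifelse(s_pfs < s_os, s_os - s_pfs, 0),
               tolerance = 1e-12)
})

test_that("markov-chain structure agrees with partitioned occupancy", {
  b <- default_parameters()
  for (arm in b$arms) {
    tr1 <- compute_trace(arm, b$settings, "partitioned")
    tr2 <- compute_trace(arm, b$settings, "markov_chain")
    # identical wherever the curves have not crossed
    uncrossed <- weibull_survival(arm$pfs, tr1$t_months) <=
      weibull_survival(arm$os, tr1$t_months)
    expect_equal(tr2$pfs[uncrossed], tr1$pfs[uncrossed], tolerance = 1e-9)
    expect_equal(tr2$death, tr1$death, tolerance = 1e-9)
  }
})

test_that("degenerate rewards make QALYs equal life-years", {
  b <- default_parameters()
  tr <- compute_trace(b$arms$osimertinib, b$settings)
  country <- toy_country(drug = 0, bsc = 0, pall = 0, ae = 0, r = 0)
  out <- accumulate_outcomes(tr, country, toy_utilities(1, 1, FALSE),
                             "osimertinib", b$settings)
  expect_equal(out$total_qaly, out$undiscounted$ly, tolerance = 1e-9)
  expect_equal(out$total_cost, 0)
})

test_that("a fully progression-free toy cohort accrues u * time", {
  st <- model_settings(n_cycles = 2, horizon_years = 28 * 2 / 365.25,
                       half_cycle_correction = FALSE)
  tr <- data.frame(cycle = 0:2, t_months = (0:2) * st$months_per_cycle,
                   pfs = 1, pd = 0, death = 0)
  class(tr) <- c("cohort_trace", "data.frame")
  attr(tr, "settings") <- st
  out <- accumulate_outcomes(tr, toy_country(drug = 0, ae = 0, r = 0),
                             utility_inputs(0.5, 0.5), "placebo", st)
  expect_equal(out$total_qaly, 2 * st$months_per_cycle / 12 * 0.5,
               tolerance = 1e-12)
})

test_that("drug price moves only costs; discounting only shrinks totals", {
  b <- default_parameters()
  base <- run_country(b, "usa")
  b2 <- set_param(b, "usa.drug_cost_per_cycle",
                  2 * b$countries$usa$drug_cost_per_cycle)
  dbl <- run_country(b2, "usa")
  expect_gt(dbl$osimertinib$total_cost, base$osimertinib$total_cost)
  expect_equal(dbl$osimertinib$total_qaly, base$osimertinib$total_qaly)
  expect_equal(dbl$osimertinib$total_ly, base$osimertinib$total_ly)
  # discounted <= undiscounted for every stream
  for (arm in base) {
    expect_lte(arm$discounted$cost, arm$undiscounted$cost)
    expect_lte(arm$discounted$qaly, arm$undiscounted$qaly)
    expect_lte(arm$discounted$ly, arm$undiscounted$ly)
  }
  # r = 0 strictly exceeds r = 0.05 on every discounted outcome
  b0 <- set_param(b, "usa.discount_rate_annual", 0)
  b5 <- set_param(b, "usa.discount_rate_annual", 0.05)
  o0 <- run_country(b0, "usa")$osimertinib
  o5 <- run_country(b5, "usa")$osimertinib
  expect_gt(o0$total_cost, o5$total_cost)
  expect_gt(o0$total_qaly, o5$total_qaly)
  expect_gt(o0$discounted$ly, o5$discounted$ly)
})

test_that("half-cycle correction shifts totals by less than one cycle", {
  b_on <- default_parameters()
  b_off <- default_parameters()
  b_off$settings$half_cycle_correction <- FALSE
  on <- run_country(b_on, "usa")$osimertinib
  off <- run_country(b_off, "usa")$osimertinib
  u_years <- b_on$settings$months_per_cycle / 12
  expect_lt(abs(on$total_qaly - off$total_qaly), u_years)
  max_cycle_cost <- max(rowSums(
    on$ledger[, c("cost_drug_pfs", "cost_pd", "cost_palliative")]))
  expect_lt(abs(on$total_cost - off$total_cost), max_cycle_cost)
})

test_that("mismatched settings raise a configuration error", {
  b <- default_parameters()
  tr <- compute_trace(b$arms$placebo, b$settings)
  st2 <- model_settings(horizon_years = 5)
  expect_error(accumulate_outcomes(tr, b$countries$usa, b$utilities,
                                   "placebo", st2),
               "configuration error")
})
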