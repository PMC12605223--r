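test_that("tornado at a degenerate range reproduces the base-case ICER", {
  b <- default_parameters()
  base <- osimcea:::country_icer(b, "usa")$icer_per_qaly
  drug <- b$countries$usa$drug_cost_per_cycle
  rng <- list("usa.drug_cost_per_cycle" = param_range(drug, drug, drug,
                                                      "fixed"))
  tor <- one_way_tornado(b, "usa", rng)
  expect_equal(tor$icer_at_low, base, tolerance = 1e-12)
  expect_equal(tor$icer_at_high, base, tolerance = 1e-12)
  expect_equal(tor$spread, 0)
})

test_that("inert parameters have zero spread; PFS utility ranks first", {
  b <- default_parameters()
  tor <- one_way_tornado(b, "usa")
  expect_equal(tor$spread[tor$parameter == "usa.ae_cost_placebo"], 0)
  expect_identical(tor$parameter[1L], "utilities.u_pfs")
  expect_true(all(diff(tor$spread) <= 1e-9))
  # ICER decreases as the PFS utility rises (published ordering)
  u <- tor[tor$parameter == "utilities.u_pfs", ]
  expect_gt(u$icer_at_low, u$icer_at_high)
})

test_that("scenario analysis is the identity at baseline utilities", {
  b <- default_parameters()
  base <- osimcea:::country_icer(b, "china")
  sc <- scenario_analysis(b, "china",
                          list(u_pfs = 0.791, u_pd = 0.653), "baseline")
  expect_equal(sc$icer_per_qaly, base$icer_per_qaly, tolerance = 1e-12)
  # collapsed utilities: QALY separation comes from survival alone
  eq <- scenario_analysis(b, "china", list(u_pfs = 0.6, u_pd = 0.6))
  res <- run_country(set_param(set_param(b, "utilities.u_pfs", 0.6),
                               "utilities.u_pd", 0.6), "china")
  for (arm in res) {
    aed <- b$utilities$ae_disutilities
    ae_loss <- if (arm$arm_label == "osimertinib")
      sum(aed$disutility * aed$incidence) else 0
    expect_equal(arm$total_qaly, 0.6 * arm$discounted$ly - ae_loss,
                 tolerance = 1e-9)
  }
  # conservative utilities raise the ICER (smaller dQALY, same dCost)
  lo <- scenario_analysis(b, "china", list(u_pfs = 0.65, u_pd = 0.55))
  expect_gt(lo$icer_per_qaly, base$icer_per_qaly)
  expect_equal(lo$delta_cost, base$delta_cost, tolerance = 1e-9)
})

test_that("distribution sampling matches its method-of-moments target", {
  set.seed(1)
  rb <- expand_range(0.791, 0.2, "beta")
  xb <- sample_distribution(rb, n = 1e5)
  expect_equal(mean(xb), 0.791, tolerance = 0.005)
  expect_true(all(xb > 0 & xb < 1))
  se <- (rb$high - rb$low) / (2 * 1.96)
  expect_equal(stats::sd(xb), se, tolerance = 0.02)

  rg <- expand_range(18034, 0.2, "gamma")
  xg <- sample_distribution(rg, n = 1e5)
  expect_true(all(xg > 0))
  expect_equal(mean(xg), 18034, tolerance = 0.005)

  # degenerate range is a point mass
  rf <- param_range(5, 5, 5, "gamma")
  expect_equal(sample_distribution(rf, n = 10), rep(5, 10))

  # infeasible beta variance falls back to uniform with a warning
  rbad <- param_range(0.01, 0.0001, 0.9, "beta")
  expect_warning(x <- sample_distribution(rbad, n = 100), "uniform")
  expect_true(all(x >= rbad$low & x <= rbad$high))
})

test_that("PSA is seed-reproducible and internally consistent", {
  b <- default_parameters()
  p1 <- run_psa(b, "usa", n_draws = 300, seed = 42)
  p2 <- run_psa(b, "usa", n_draws = 300, seed = 42)
  expect_identical(p1$draws, p2$draws)
  expect_identical(p1$ceac, p2$ceac)
  # CEAC at any wtp equals the empirical positive-INMB fraction
  for (i in c(1L, 50L, 150L, 201L)) {
    w <- p1$ceac$wtp[i]
    expect_equal(p1$ceac$p_osimertinib[i],
                 mean(w * p1$draws$delta_qaly - p1$draws$delta_cost > 0))
  }
  expect_equal(p1$ceac$p_osimertinib + p1$ceac$p_placebo,
               rep(1, nrow(p1$ceac)))
  # effect gains are near-certain here, so the CEAC is non-decreasing
  expect_gt(mean(p1$draws$delta_qaly > 0), 0.99)
  expect_true(all(diff(p1$ceac$p_osimertinib) >= -1e-12))
  # limit behaviour: at WTP far above every ICER the acceptance
  # probability is the fraction of draws with any QALY gain
  expect_equal(mean(1e9 * p1$draws$delta_qaly - p1$draws$delta_cost > 0),
               mean(p1$draws$delta_qaly > 0))
})

test_that("independent seeds agree on the CEAC within binomial noise", {
  b <- default_parameters()
  n <- 2000L
  pa <- run_psa(b, "china", n_draws = n, seed = 1)
  pb <- run_psa(b, "china", n_draws = n, seed = 2)
  p <- (pa$prob_cost_effective + pb$prob_cost_effective) / 2
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(pa$prob_cost_effective - pb$prob_cost_effective), 3 * se)
})
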