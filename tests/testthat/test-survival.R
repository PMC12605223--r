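test_that("Weibull survival satisfies S(0) = 1 and the closed-form median", {
  set.seed(42)
  for (i in 1:20) {
    p <- weibull_params(exp(stats::runif(1, -8, 0)),
                        exp(stats::runif(1, -1, 1.2)))
    expect_equal(weibull_survival(p, 0), 1)
    grid <- seq(0, 120, length.out = 200)
    s <- weibull_survival(p, grid)
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= 1))
    # independent root-finding oracle for the median
    med_oracle <- stats::uniroot(function(t) weibull_survival(p, t) - 0.5,
                                 c(1e-9, 1e6), tol = 1e-10)$root
    expect_equal(weibull_median(p), med_oracle, tolerance = 1e-6)
  }
  expect_equal(weibull_median(weibull_params(log(2), 1)), 1)
  expect_error(weibull_survival(pfs_pla, -1), "domain")
})

test_that("fitted PFS medians are plausible against the trial medians", {
  # trial medians 38.9 (treated) and 7.3 (placebo) months; the fitted
  # laws should land in their neighbourhood, not equal them
  expect_equal(weibull_median(pfs_osi), 35.7, tolerance = 0.02)
  expect_equal(weibull_median(pfs_pla), 6.09, tolerance = 0.01)
})

test_that("the 2.93-shape OS law leaves under 1% alive at 15 years", {
  expect_lt(weibull_survival(os_short, 180), 0.01)
})

test_that("proportional hazards raises survival to the power hr", {
  expect_identical(apply_hazard_ratio(pfs_pla, 1), pfs_pla)
  p2 <- apply_hazard_ratio(pfs_pla, 2)
  grid <- seq(0, 60, by = 0.5)
  expect_equal(weibull_survival(p2, grid), weibull_survival(pfs_pla, grid)^2,
               tolerance = 1e-12)
  p033 <- apply_hazard_ratio(pfs_pla, 0.33)
  expect_equal(p033$scale, 0.0400554)
  expect_equal(p033$shape, pfs_pla$shape)
  expect_error(apply_hazard_ratio(pfs_pla, -1), "domain")
})

test_that("cycle transition probabilities telescope back to the curve", {
  u <- 28 * 12 / 365.25
  # memorylessness: exponential (shape 1) has constant transition prob
  pe <- weibull_params(0.1, 1)
  tp <- cycle_transition_prob(pe, 1:50, u)
  expect_equal(tp, rep(1 - exp(-0.1 * u), 50), tolerance = 1e-12)
  # first-cycle probability equals 1 - S(u)
  expect_equal(cycle_transition_prob(pfs_pla, 1, u),
               1 - exp(-0.12138 * u^0.96416), tolerance = 1e-12)
  expect_equal(cycle_transition_prob(pfs_pla, 1, u), 0.106, tolerance = 1e-2)
  # vanishing cycle length
  expect_lt(cycle_transition_prob(pfs_pla, 1, 1e-10), 1e-9)
  # telescoping: prod(1 - tp_k) = S(K u)
  for (p in list(pfs_osi, pfs_pla, os_short)) {
    K <- 120
    tp <- cycle_transition_prob(p, 1:K, u)
    expect_equal(prod(1 - tp), weibull_survival(p, K * u),
                 tolerance = 1e-12)
  }
})

test_that("all five families are valid survival curves", {
  params <- list(
    exponential = c(rate = 0.1),
    weibull = c(scale = 0.03, shape = 1.4),
    lognormal = c(meanlog = 2, sdlog = 0.8),
    loglogistic = c(alpha = 12, beta = 1.6),
    gompertz = c(b = 0.01, c = 0.05))
  for (fam in names(params)) {
    cv <- survival_curve(fam, params[[fam]])
    expect_equal(cv$sf(0), 1, info = fam)
    s <- cv$sf(seq(0, 200, length.out = 300))
    expect_true(all(diff(s) <= 1e-12), info = fam)
    expect_true(all(s >= 0 & s <= 1), info = fam)
  }
  # negative-c gompertz (decreasing hazard, defective tail allowed in fit
  # range) still monotone on the horizon
  cv <- survival_curve("gompertz", c(b = 0.05, c = -0.02))
  s <- cv$sf(seq(0, 200, length.out = 300))
  expect_true(all(diff(s) <= 1e-12))
})

test_that("maximum likelihood recovers Weibull parameters within 5%", {
  ipd <- generate_ipd(pfs_pla, 5000, seed = 7)
  fit <- fit_parametric(ipd, "weibull")
  expect_true(fit$converged)
  expect_equal(unname(fit$curve$params[["scale"]]), pfs_pla$scale,
               tolerance = 0.05)
  expect_equal(unname(fit$curve$params[["shape"]]), pfs_pla$shape,
               tolerance = 0.05)
  # information-criterion identities
  expect_equal(fit$aic, 2 * 2 - 2 * fit$loglik)
  expect_equal(fit$bic, 2 * log(fit$n_obs) - 2 * fit$loglik)
})

test_that("weibull fit of exponential data finds shape near 1", {
  ipd <- generate_ipd(weibull_params(0.15, 1), 3000, seed = 11)
  fit <- fit_parametric(ipd, "weibull")
  expect_equal(unname(fit$curve$params[["shape"]]), 1, tolerance = 0.05)
})

test_that("AIC prefers the exponential on exponential data (majority)", {
  wins <- 0L
  for (s in 1:20) {
    ipd <- generate_ipd(weibull_params(0.12, 1), 300, seed = 100 + s)
    fe <- fit_parametric(ipd, "exponential")
    fw <- fit_parametric(ipd, "weibull")
    if (fe$aic < fw$aic) wins <- wins + 1L
  }
  expect_gt(wins, 10L)
})

test_that("median relative MLE error over 20 replicates at n = 2000 is < 5%", {
  errs <- t(vapply(1:20, function(s) {
    ipd <- generate_ipd(pfs_osi, 2000, seed = 200 + s)
    fit <- fit_parametric(ipd, "weibull")
    abs(c(fit$curve$params[["scale"]] / pfs_osi$scale,
          fit$curve$params[["shape"]] / pfs_osi$shape) - 1)
  }, numeric(2L)))
  expect_lt(stats::median(errs[, 1L]), 0.05)
  expect_lt(stats::median(errs[, 2L]), 0.05)
})

test_that("family selection identifies the generating family", {
  # high-shape Weibull data (OS-like)
  wins <- vapply(1:5, function(s) {
    ipd <- generate_ipd(weibull_params(1e-5, 2.9), 1500, seed = 300 + s)
    select_best_family(ipd)$family
  }, character(1L))
  expect_gt(sum(wins == "weibull"), 2L)
  # lognormal data
  wins_ln <- vapply(1:5, function(s) {
    set.seed(400 + s)
    tv <- stats::rlnorm(1500, meanlog = 2.5, sdlog = 0.6)
    select_best_family(pseudo_ipd(tv, rep(1L, 1500)))$family
  }, character(1L))
  expect_gt(sum(wins_ln == "lognormal"), 2L)
  # degenerate single-family menu
  ipd <- generate_ipd(pfs_pla, 200, seed = 1)
  expect_identical(select_best_family(ipd, "exponential")$family,
                   "exponential")
  # ranking table is attached and sorted
  best <- select_best_family(ipd)
  tab <- attr(best, "ranking")
  expect_identical(nrow(tab), 5L)
  expect_true(!is.unsorted(tab$aic, na.rm = TRUE))
})

test_that("the fit agrees with an independent fitting library", {
  library(flexsurv)
  ipd <- generate_ipd(pfs_pla, 1500, censor_rate = 0.2,
                      max_followup_months = 40, seed = 5)
  d <- as.data.frame(ipd)
  ours <- fit_parametric(ipd, "weibull")
  ref <- flexsurvreg(Surv(time, event) ~ 1, data = d, dist = "weibull")
  expect_equal(ours$loglik, ref$loglik, tolerance = 1e-4)
  # flexsurv uses the AFT (shape, scale-time) form; convert to ours
  sh <- ref$res["shape", "est"]; sc <- ref$res["scale", "est"]
  expect_equal(unname(ours$curve$params[["shape"]]), sh, tolerance = 1e-2)
  expect_equal(unname(ours$curve$params[["scale"]]), sc^(-sh),
               tolerance = 1e-2)
})
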