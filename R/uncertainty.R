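# Sensitivity machinery: one-way (tornado) analysis, scenario analysis,
# parameter-distribution sampling and probabilistic sensitivity analysis
# with cost-effectiveness acceptability curves.

country_param_labels <- function(bundle, country_label) {
  other <- setdiff(names(bundle$countries), country_label)
  labs <- names(bundle$ranges)
  labs[!vapply(labs, function(l)
    any(startsWith(l, paste0(other, "."))), logical(1L))]
}

country_icer <- function(bundle, country_label) {
  res <- run_country(bundle, country_label)
  compare(res$placebo, res$osimertinib,
          bundle$countries[[country_label]]$wtp_per_qaly)
}

#' One-way (tornado) sensitivity analysis
#'
#' For every parameter with a sensitivity range, sets the parameter to its
#' low and high bound (all others at baseline), recomputes the ICER per
#' QALY, and returns the entries sorted by descending spread.
#'
#' @param bundle A `cea_bundle`.
#' @param country_label Country to analyse.
#' @param ranges Named [param_range()] list; defaults to `bundle$ranges`
#'   restricted to this country's scope.
#' @return A `data.frame` (class `tornado_result`) with columns
#'   `parameter`, `low`, `high`, `icer_at_low`, `icer_at_high`, `spread`,
#'   sorted by descending spread; the base-case ICER is attached as
#'   attribute `icer_base`.
#' @export
one_way_tornado <- function(bundle, country_label, ranges = NULL) {
  if (is.null(ranges))
    ranges <- bundle$ranges[country_param_labels(bundle, country_label)]
  base <- country_icer(bundle, country_label)
  rows <- list()
  for (label in names(ranges)) {
    r <- ranges[[label]]
    icers <- vapply(c(r$low, r$high), function(v) {
      b2 <- tryCatch(set_param(bundle, label, v), error = function(e) NULL)
      if (is.null(b2)) return(NA_real_)
      suppressWarnings(country_icer(b2, country_label)$icer_per_qaly)
    }, numeric(1L))
    if (all(is.na(icers))) {
      warning(sprintf("skipping '%s': no valid ICER on its range", label))
      next
    }
    rows[[label]] <- data.frame(
      parameter = label, low = r$low, high = r$high,
      icer_at_low = icers[1L], icer_at_high = icers[2L],
      spread = abs(icers[2L] - icers[1L]))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tornado_result", "data.frame")
  attr(out, "icer_base") <- base$icer_per_qaly
  attr(out, "country_label") <- country_label
  out
}

#' Scenario analysis with overridden utilities
#'
#' Reruns the base-case pipeline under a named set of utility overrides.
#'
#' @param bundle A `cea_bundle`.
#' @param country_label Country to analyse.
#' @param scenario Named list of overrides among `u_pfs`, `u_pd` (values in
#'   `[0, 1]`).
#' @param label Scenario label attached to the result.
#' @return An `incremental_result` with attribute `scenario_label`.
#' @export
scenario_analysis <- function(bundle, country_label, scenario = list(),
                              label = "scenario") {
  for (nm in names(scenario)) {
    if (!nm %in% c("u_pfs", "u_pd"))
      stop(sprintf("unknown utility override '%s'", nm), call. = FALSE)
    v <- scenario[[nm]]
    if (v < 0 || v > 1)
      stop(sprintf("range error: '%s' must lie in [0, 1]", nm),
           call. = FALSE)
    bundle <- set_param(bundle, paste0("utilities.", nm), v)
  }
  out <- country_icer(bundle, country_label)
  attr(out, "scenario_label") <- label
  out
}

#' Sample from a parameter's uncertainty distribution
#'
#' Method-of-moments parameterisation with mean equal to the baseline and
#' standard error `(high - low) / (2 * 1.96)`:
#' beta `alpha = m (m(1-m)/SE^2 - 1)`, `beta = alpha (1-m)/m`;
#' gamma `shape = m^2/SE^2`, `rate = m/SE^2`; uniform on `[low, high]`.
#' A beta request whose variance is infeasible (`SE^2 >= m(1-m)`) falls
#' back to uniform with a warning. Degenerate ranges return the baseline.
#' Draws use R's global RNG, so results are reproducible under
#' [set.seed()].
#'
#' @param range A [param_range()].
#' @param kind Distribution family; defaults to the range's own.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_distribution <- function(range, kind = range$distribution, n = 1L) {
  m <- range$baseline
  se <- (range$high - range$low) / (2 * 1.96)
  if (kind == "fixed" || se == 0) return(rep(m, n))
  switch(kind,
    uniform = stats::runif(n, range$low, range$high),
    gamma = {
      if (m <= 0) return(rep(m, n))
      stats::rgamma(n, shape = m^2 / se^2, rate = m / se^2)
    },
    beta = {
      if (se^2 >= m * (1 - m) || m <= 0 || m >= 1) {
        warning("beta variance infeasible; falling back to uniform")
        return(stats::runif(n, range$low, range$high))
      }
      a <- m * (m * (1 - m) / se^2 - 1)
      stats::rbeta(n, a, a * (1 - m) / m)
    },
    stop(sprintf("unknown distribution '%s'", kind), call. = FALSE))
}

apply_draw <- function(bundle, labels, values) {
  # fast in-place bundle update for PSA draws (inputs already validated
  # by construction of the sampling distributions)
  for (i in seq_along(labels)) {
    bundle <- set_param(bundle, labels[i], values[[i]])
  }
  bundle
}

#' Probabilistic sensitivity analysis
#'
#' Jointly resamples every distributed parameter (costs from gamma,
#' utilities / incidences / therapy rates from beta, discount rate from
#' uniform; survival parameters held fixed), reruns both strategies per
#' draw, and records the incremental cost and QALY pair. The
#' cost-effectiveness acceptability curve reports, at each
#' willingness-to-pay value `w`, the fraction of draws with positive
#' incremental net monetary benefit `w dQ - dC` for osimertinib and the
#' complement for placebo.
#'
#' @param bundle A `cea_bundle`.
#' @param country_label Country to analyse.
#' @param n_draws Number of Monte-Carlo draws (default 10000).
#' @param seed RNG seed; same seed, same result bit for bit.
#' @param wtp_grid WTP grid for the CEAC; default 201 points from 0 to
#'   500,000 (100,000 for China).
#' @param survival_uncertainty The published inputs assign the Weibull
#'   survival parameters no distribution (and no covariance matrix), so
#'   they are held fixed by default. Setting this to `TRUE` additionally
#'   draws each Weibull scale from a lognormal centred on its base value
#'   (coefficient of variation `survival_cv`) for exploration.
#' @param survival_cv Lognormal coefficient of variation used when
#'   `survival_uncertainty = TRUE`.
#' @return An object of class `psa_result`: `draws` (`data.frame` with
#'   `delta_cost`, `delta_qaly`, `inmb`), `ceac` (`data.frame` with `wtp`,
#'   `p_osimertinib`, `p_placebo`), `prob_cost_effective` at the country
#'   WTP, `n_draws`, `seed`.
#' @export
run_psa <- function(bundle, country_label, n_draws = 10000L, seed = 1L,
                    wtp_grid = NULL, survival_uncertainty = FALSE,
                    survival_cv = 0.1) {
  stopifnot(n_draws >= 1L)
  country <- bundle$countries[[country_label]]
  if (is.null(wtp_grid))
    wtp_grid <- seq(0, if (country$wtp_per_qaly < 1e5) 1e5 else 5e5,
                    length.out = 201L)
  labels <- country_param_labels(bundle, country_label)
  labels <- labels[vapply(labels, function(l)
    bundle$ranges[[l]]$distribution != "fixed", logical(1L))]
  set.seed(seed)
  draws_mat <- vapply(labels, function(l)
    sample_distribution(bundle$ranges[[l]], n = n_draws), numeric(n_draws))
  # with fixed survival parameters the traces are draw-invariant
  traces <- lapply(bundle$arms, compute_trace, settings = bundle$settings,
                   structure = bundle$conventions$structure)
  sdlog <- sqrt(log(1 + survival_cv^2))
  scale_mult <- if (survival_uncertainty)
    matrix(stats::rlnorm(4L * n_draws, -sdlog^2 / 2, sdlog), ncol = 4L)
  else NULL
  d_cost <- d_qaly <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    b2 <- apply_draw(bundle, labels, draws_mat[i, ])
    cc <- b2$countries[[country_label]]
    if (survival_uncertainty) {
      j <- 0L
      for (arm in names(b2$arms)) {
        a <- b2$arms[[arm]]
        b2$arms[[arm]] <- arm_survival(
          weibull_params(a$os$scale * scale_mult[i, j + 1L], a$os$shape),
          weibull_params(a$pfs$scale * scale_mult[i, j + 2L], a$pfs$shape),
          arm)
        j <- j + 2L
      }
      traces <- lapply(b2$arms, compute_trace, settings = b2$settings,
                       structure = b2$conventions$structure)
    }
    out <- lapply(names(traces), function(arm)
      accumulate_outcomes(traces[[arm]], cc, b2$utilities, arm,
                          b2$settings, b2$conventions))
    names(out) <- names(traces)
    d_cost[i] <- out$osimertinib$total_cost - out$placebo$total_cost
    d_qaly[i] <- out$osimertinib$total_qaly - out$placebo$total_qaly
  }
  inmb <- country$wtp_per_qaly * d_qaly - d_cost
  ceac <- data.frame(
    wtp = wtp_grid,
    p_osimertinib = vapply(wtp_grid, function(w)
      mean(w * d_qaly - d_cost > 0), numeric(1L)))
  ceac$p_placebo <- 1 - ceac$p_osimertinib
  structure(list(
    draws = data.frame(delta_cost = d_cost, delta_qaly = d_qaly,
                       inmb = inmb),
    ceac = ceac,
    prob_cost_effective = mean(inmb > 0),
    country_label = country_label, wtp = country$wtp_per_qaly,
    n_draws = n_draws, seed = seed),
    class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf(
    "PSA (%s): %d draws, seed %s\n  P(osimertinib cost-effective at WTP $%s) = %.3f\n",
    x$country_label, x$n_draws, format(x$seed),
    format(x$wtp, big.mark = ","), x$prob_cost_effective))
  invisible(x)
}

#' Export tornado / PSA / CEAC results to CSV
#'
#' @param x A `tornado_result`, `psa_result` draws table, or CEAC table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(x, path) {
  if (inherits(x, "psa_result"))
    stop("pass x$draws or x$ceac, not the psa_result itself", call. = FALSE)
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
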