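# Three-state cohort engine: occupancy trace and discounted accrual of
# costs, life-years and QALYs per strategy and country.

#' Compute the three-state occupancy trace
#'
#' Runs the cohort over the horizon. Under the default partitioned-survival
#' structure, occupancy is read directly off the two curves: at `t = k u`
#' months, `death = 1 - S_OS(t)`, `pfs = min(S_PFS(t), S_OS(t))` and `pd`
#' is the remainder; the whole cohort starts progression free. The
#' `"markov_chain"` structure instead propagates per-cycle transition
#' probabilities ([cycle_transition_prob()]); it agrees with the
#' partitioned occupancy while the curves do not cross.
#'
#' @param arm An [arm_survival()] object.
#' @param settings A [model_settings()] object.
#' @param structure `"partitioned"` (default) or `"markov_chain"`.
#' @return An object of class `cohort_trace`: `data.frame` with columns
#'   `cycle`, `t_months`, `pfs`, `pd`, `death` (fractions summing to 1).
#' @export
compute_trace <- function(arm, settings = model_settings(),
                          structure = c("partitioned", "markov_chain")) {
  structure <- match.arg(structure)
  n <- settings$n_cycles
  u <- settings$months_per_cycle
  t <- (0:n) * u
  if (structure == "partitioned") {
    s_os <- weibull_survival(arm$os, t)
    s_pfs <- weibull_survival(arm$pfs, t)
    pfs <- pmin(s_pfs, s_os)
    death <- 1 - s_os
    pd <- pmax(0, 1 - death - pfs)
  } else {
    tp_pfs <- cycle_transition_prob(arm$pfs, 1:n, u)
    tp_os <- cycle_transition_prob(arm$os, 1:n, u)
    pfs <- pd <- death <- numeric(n + 1L)
    pfs[1L] <- 1
    alive <- 1
    for (k in 1:n) {
      # progression-free occupancy follows the PFS curve; deaths follow the
      # OS curve for everyone alive, so overall survival reproduces S_OS
      pfs[k + 1L] <- pfs[k] * (1 - tp_pfs[k])
      alive <- alive * (1 - tp_os[k])
      pfs[k + 1L] <- min(pfs[k + 1L], alive)
      pd[k + 1L] <- alive - pfs[k + 1L]
      death[k + 1L] <- 1 - alive
    }
  }
  out <- data.frame(cycle = 0:n, t_months = t, pfs = pfs, pd = pd,
                    death = death)
  class(out) <- c("cohort_trace", "data.frame")
  attr(out, "arm_label") <- arm$arm_label
  attr(out, "settings") <- settings
  out
}

#' Accrue discounted costs, life-years and QALYs over a trace
#'
#' Accrual rules per cycle: progression-free members accrue drug cost
#' (treated arm only), optional monitoring cost and `u_pfs` utility;
#' progressed members accrue subsequent-therapy drug cost (drug price times
#' the arm's subsequent-therapy rate) plus best-supportive-care cost for
#' the non-recipients and `u_pd` utility; each cycle's death increment
#' accrues the one-off palliative cost; the treated arm takes a one-off
#' adverse-event cost and incidence-weighted QALY decrement at entry.
#' Flows are discounted at `(1 + r)^(-t_years)`; with half-cycle
#' correction, occupancy and time are evaluated mid-cycle.
#'
#' @param trace A [compute_trace()] result.
#' @param country A [country_inputs()] object.
#' @param utilities A [utility_inputs()] object.
#' @param arm_label `"osimertinib"` (treated) or `"placebo"`.
#' @param settings The [model_settings()] used for the trace.
#' @param conventions A [model_conventions()] object.
#' @return An object of class `outcome_summary`: discounted and
#'   undiscounted totals (`total_cost`, `total_ly`, `total_qaly`,
#'   `undiscounted` twins), the headline `ly` (discounted or not per
#'   `conventions$discount_ly`), and a per-cycle `ledger` data frame.
#' @export
accumulate_outcomes <- function(trace, country, utilities, arm_label,
                                settings = attr(trace, "settings"),
                                conventions = model_conventions()) {
  if (!identical(nrow(trace), settings$n_cycles + 1L))
    stop("configuration error: trace and settings disagree on n_cycles",
         call. = FALSE)
  arm_label <- match.arg(arm_label, c("osimertinib", "placebo"))
  treated <- arm_label == "osimertinib"
  n <- settings$n_cycles
  u <- settings$months_per_cycle
  cyc_years <- u / 12

  occ <- function(x) if (settings$half_cycle_correction)
    (x[-1L] + x[-(n + 1L)]) / 2 else x[-1L]
  a_pfs <- occ(trace$pfs)
  a_pd <- occ(trace$pd)
  d_death <- diff(trace$death)
  t_mid <- if (settings$half_cycle_correction) ((1:n) - 0.5) * u else (1:n) * u
  disc <- (1 + country$discount_rate_annual)^(-t_mid / 12)

  mon <- country$lab_cost_per_cycle + country$radiology_cost_per_cycle
  mon_pfs <- if (conventions$monitoring_in %in% c("pfs", "both")) mon else 0
  mon_pd <- if (conventions$monitoring_in %in% c("pd", "both")) mon else 0
  rate <- country$subsequent_therapy_rate[[arm_label]]
  cost_pfs_cycle <- (if (treated) country$drug_cost_per_cycle else 0) + mon_pfs
  cost_pd_cycle <- country$drug_cost_per_cycle * rate +
    (if (conventions$bsc_for_nonrecipients)
      country$bsc_cost_per_cycle * (1 - rate) else 0) + mon_pd
  pall <- if (conventions$palliative_at_death)
    country$palliative_cost_oneoff else 0

  ae_cost <- if (treated && conventions$ae_at_entry)
    country$ae_cost_oneoff[[arm_label]] else 0
  aed <- utilities$ae_disutilities
  ae_qaly_loss <- if (treated && conventions$ae_at_entry && nrow(aed) > 0)
    sum(aed$disutility * aed$incidence) else 0

  cost_cycle <- a_pfs * cost_pfs_cycle + a_pd * cost_pd_cycle +
    d_death * pall
  qaly_cycle <- (a_pfs * utilities$u_pfs + a_pd * utilities$u_pd) * cyc_years
  ly_cycle <- (a_pfs + a_pd) * cyc_years

  ledger <- data.frame(
    cycle = 1:n, t_months = t_mid, discount = disc,
    cost_drug_pfs = a_pfs * cost_pfs_cycle,
    cost_pd = a_pd * cost_pd_cycle,
    cost_palliative = d_death * pall,
    ly = ly_cycle, qaly = qaly_cycle)

  und <- c(cost = sum(cost_cycle) + ae_cost, ly = sum(ly_cycle),
           qaly = sum(qaly_cycle) - ae_qaly_loss)
  dsc <- c(cost = sum(disc * cost_cycle) + ae_cost,
           ly = sum(disc * ly_cycle),
           qaly = sum(disc * qaly_cycle) - ae_qaly_loss)

  structure(list(
    arm_label = arm_label, country_label = country$country_label,
    total_cost = dsc[["cost"]],
    total_ly = if (conventions$discount_ly) dsc[["ly"]] else und[["ly"]],
    total_qaly = dsc[["qaly"]],
    discounted = as.list(dsc), undiscounted = as.list(und),
    ledger = ledger, conventions = conventions),
    class = "outcome_summary")
}

#' Run one strategy end to end
#'
#' Composes [compute_trace()] and [accumulate_outcomes()].
#'
#' @inheritParams accumulate_outcomes
#' @param arm An [arm_survival()] object.
#' @return An `outcome_summary`.
#' @export
run_strategy <- function(arm, country, utilities,
                         settings = model_settings(),
                         conventions = model_conventions()) {
  trace <- compute_trace(arm, settings, conventions$structure)
  accumulate_outcomes(trace, country, utilities, arm$arm_label, settings,
                      conventions)
}

#' Run both strategies for one country of a bundle
#'
#' @param bundle A `cea_bundle`.
#' @param country_label A name of `bundle$countries`.
#' @return Named list of `outcome_summary` objects
#'   (`osimertinib`, `placebo`).
#' @export
run_country <- function(bundle, country_label) {
  country <- bundle$countries[[country_label]]
  if (is.null(country))
    stop(sprintf("unknown country '%s'", country_label), call. = FALSE)
  lapply(bundle$arms, function(arm)
    run_strategy(arm, country, bundle$utilities, bundle$settings,
                 bundle$conventions))
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat(sprintf("%s (%s): cost $%s, %.2f LY, %.2f QALY (discounted QALY/cost)\n",
              x$arm_label, x$country_label,
              format(round(x$total_cost), big.mark = ","),
              x$total_ly, x$total_qaly))
  invisible(x)
}

#' Export a cohort trace (with its ledger) to CSV
#'
#' @param trace A `cohort_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
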