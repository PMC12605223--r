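# Subgroup analyses driven by subgroup-specific PFS hazard ratios.

subgroup_bundle <- function(bundle, hr,
                            method = c("control_ph", "treated_rescale"),
                            hr_overall = 0.19) {
  method <- match.arg(method)
  base_pfs <- switch(method,
    control_ph = apply_hazard_ratio(bundle$arms$placebo$pfs, hr),
    treated_rescale = apply_hazard_ratio(bundle$arms$osimertinib$pfs,
                                         hr / hr_overall))
  bundle$arms$osimertinib <- arm_survival(bundle$arms$osimertinib$os,
                                          base_pfs, "osimertinib")
  bundle
}

#' Analyse one subgroup
#'
#' Applies the subgroup's PFS hazard ratio to the treated arm: by default
#' the subgroup osimertinib PFS curve is the placebo-arm base PFS raised
#' to the power `hr` (proportional hazards on the control baseline); the
#' placebo arm and both OS curves stay at base case. The deterministic
#' pipeline is rerun per country, and a (reduced-size) PSA supplies the
#' cost-effectiveness probability at the country WTP.
#'
#' @param spec A [subgroup_spec()].
#' @param bundle A `cea_bundle`.
#' @param country_label Country to analyse.
#' @param psa_draws PSA size for the probability column (default 1000;
#'   set to 0 to skip).
#' @param seed PSA seed.
#' @param method `"control_ph"` (default) scales the placebo PFS baseline
#'   by `hr`; `"treated_rescale"` rescales the treated arm's fitted curve
#'   by `hr / hr_overall`.
#' @param hr_overall Trial-wide PFS hazard ratio used by
#'   `"treated_rescale"`.
#' @return A one-row `data.frame`: subgroup, hr, deltas, ICER per QALY,
#'   INHB, and `prob_cost_effective` (NA when `psa_draws = 0` or `hr` is
#'   NA).
#' @export
analyze_subgroup <- function(spec, bundle, country_label, psa_draws = 1000L,
                             seed = 1L,
                             method = c("control_ph", "treated_rescale"),
                             hr_overall = 0.19) {
  if (is.na(spec$pfs_hr)) {
    return(data.frame(subgroup = spec$subgroup_label, pfs_hr = NA_real_,
                      country = country_label, delta_cost = NA_real_,
                      delta_qaly = NA_real_, icer_per_qaly = NA_real_,
                      inhb = NA_real_, prob_cost_effective = NA_real_))
  }
  b2 <- subgroup_bundle(bundle, spec$pfs_hr, method, hr_overall)
  inc <- country_icer(b2, country_label)
  prob <- NA_real_
  if (psa_draws > 0L)
    prob <- run_psa(b2, country_label, n_draws = psa_draws,
                    seed = seed)$prob_cost_effective
  data.frame(subgroup = spec$subgroup_label, pfs_hr = spec$pfs_hr,
             country = country_label, delta_cost = inc$delta_cost,
             delta_qaly = inc$delta_qaly,
             icer_per_qaly = inc$icer_per_qaly, inhb = inc$inhb,
             prob_cost_effective = prob)
}

#' Run every subgroup for every country
#'
#' @param bundle A `cea_bundle` (its `subgroups` list drives the rows;
#'   rows without a reported hazard ratio are emitted with NA flags).
#' @param countries Country labels; default all.
#' @inheritParams analyze_subgroup
#' @return A `data.frame`, one row per subgroup per country.
#' @export
run_all_subgroups <- function(bundle, countries = names(bundle$countries),
                              psa_draws = 1000L, seed = 1L,
                              method = c("control_ph", "treated_rescale")) {
  method <- match.arg(method)
  rows <- list()
  for (cl in countries) {
    for (s in bundle$subgroups) {
      rows[[paste(cl, s$subgroup_label)]] <-
        analyze_subgroup(s, bundle, cl, psa_draws, seed, method)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
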