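# Incremental cost-effectiveness accounting: ICER, INHB, NMB, dominance.

#' Incremental cost-effectiveness ratio
#'
#' Exact quotient of unrounded increments. When the signs of the cost and
#' effect increments disagree no ratio is reported: a cheaper-and-better
#' comparator is `"dominant"`, a costlier-and-worse one `"dominated"`.
#'
#' @param delta_cost Incremental cost (comparator minus reference), USD.
#' @param delta_effect Incremental effect (QALYs or LYs).
#' @return A list with `value` (the ratio, or `NA`) and `flag`
#'   (`"icer"`, `"dominant"`, `"dominated"`, `"undefined"`).
#' @export
icer <- function(delta_cost, delta_effect) {
  if (delta_effect == 0)
    return(list(value = NA_real_, flag = "undefined"))
  if (delta_cost <= 0 && delta_effect > 0)
    return(list(value = if (delta_cost == 0) 0 else NA_real_,
                flag = if (delta_cost == 0) "icer" else "dominant"))
  if (delta_cost > 0 && delta_effect < 0)
    return(list(value = NA_real_, flag = "dominated"))
  list(value = delta_cost / delta_effect, flag = "icer")
}

#' Pairwise incremental comparison
#'
#' Computes increments at full precision (never from rounded summaries),
#' ICERs per QALY and per LY, the incremental net health benefit
#' `INHB = dE - dC / WTP` (QALYs) and the net monetary benefit
#' `NMB = WTP dE - dC` (USD).
#'
#' @param reference,comparator `outcome_summary` objects from the same
#'   country and settings; increments are comparator minus reference.
#' @param wtp Willingness-to-pay threshold, USD per QALY.
#' @return An object of class `incremental_result`.
#' @export
compare <- function(reference, comparator, wtp) {
  if (!identical(reference$country_label, comparator$country_label))
    stop("configuration error: summaries come from different countries",
         call. = FALSE)
  d_cost <- comparator$total_cost - reference$total_cost
  d_ly <- comparator$total_ly - reference$total_ly
  d_qaly <- comparator$total_qaly - reference$total_qaly
  iq <- icer(d_cost, d_qaly)
  il <- icer(d_cost, d_ly)
  inhb <- d_qaly - d_cost / wtp
  structure(list(
    reference = reference$arm_label, comparator = comparator$arm_label,
    country_label = reference$country_label,
    delta_cost = d_cost, delta_ly = d_ly, delta_qaly = d_qaly,
    icer_per_qaly = iq$value, icer_per_qaly_flag = iq$flag,
    icer_per_ly = il$value, icer_per_ly_flag = il$flag,
    inhb = inhb, nmb = wtp * inhb, wtp_used = wtp),
    class = "incremental_result")
}

#' @export
print.incremental_result <- function(x, ...) {
  cat(sprintf("%s vs %s (%s):\n", x$comparator, x$reference,
              x$country_label))
  cat(sprintf("  dCost $%s  dLY %.2f  dQALY %.2f\n",
              format(round(x$delta_cost), big.mark = ","), x$delta_ly,
              x$delta_qaly))
  fmt <- function(v, f) if (f == "icer") paste0("$",
    format(round(v), big.mark = ",")) else f
  cat(sprintf("  ICER %s/QALY  %s/LY  INHB %.2f QALY (WTP $%s)\n",
              fmt(x$icer_per_qaly, x$icer_per_qaly_flag),
              fmt(x$icer_per_ly, x$icer_per_ly_flag), x$inhb,
              format(x$wtp_used, big.mark = ",")))
  invisible(x)
}

#' Base-case table for one or both countries
#'
#' Runs both strategies per country and assembles the per-arm totals with
#' the incremental columns (ICER per LY and per QALY, INHB).
#'
#' @param bundle A `cea_bundle`.
#' @param countries Country labels; default all in the bundle.
#' @return A `data.frame` with one row per strategy per country; dollar
#'   and effect columns unrounded.
#' @export
base_case_table <- function(bundle, countries = names(bundle$countries)) {
  rows <- list()
  for (cl in countries) {
    res <- run_country(bundle, cl)
    inc <- compare(res$placebo, res$osimertinib,
                   bundle$countries[[cl]]$wtp_per_qaly)
    rows[[paste0(cl, ".placebo")]] <- data.frame(
      country = cl, strategy = "placebo",
      total_cost = res$placebo$total_cost, total_ly = res$placebo$total_ly,
      total_qaly = res$placebo$total_qaly, icer_per_ly = NA_real_,
      icer_per_qaly = NA_real_, inhb = NA_real_)
    rows[[paste0(cl, ".osimertinib")]] <- data.frame(
      country = cl, strategy = "osimertinib",
      total_cost = res$osimertinib$total_cost,
      total_ly = res$osimertinib$total_ly,
      total_qaly = res$osimertinib$total_qaly,
      icer_per_ly = inc$icer_per_ly, icer_per_qaly = inc$icer_per_qaly,
      inhb = inc$inhb)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
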