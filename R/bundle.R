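# Parameter-bundle assembly: YAML config I/O and the built-in presets.

#' Load a full parameter bundle from a YAML config
#'
#' Reads survival parameters, country cost/utility inputs, sensitivity
#' ranges, subgroup hazard ratios and run settings from a structured YAML
#' file and returns a validated bundle. Missing keys raise named validation
#' errors; out-of-bound values raise range errors identifying the field.
#'
#' @param config_source Path to a YAML file, or a pre-parsed list.
#' @param conventions A [model_conventions()] object; defaults to the
#'   package defaults.
#' @return An object of class `cea_bundle`: a list with elements `arms`
#'   (per-arm [arm_survival()]), `countries` (per-country
#'   [country_inputs()]), `utilities`, `settings`, `conventions`,
#'   `ranges` (named [param_range()] list per country scope) and
#'   `subgroups`.
#' @seealso [default_parameters()] for the built-in presets,
#'   [write_parameters()] for the inverse operation.
#' @export
load_parameters <- function(config_source,
                            conventions = model_conventions()) {
  cfg <- if (is.character(config_source)) {
    yaml::read_yaml(config_source)
  } else if (is.list(config_source)) {
    config_source
  } else {
    stop("config_source must be a file path or a list", call. = FALSE)
  }
  need <- function(x, key, where) {
    if (is.null(x[[key]]))
      stop(sprintf("missing key: '%s' in section '%s'", key, where),
           call. = FALSE)
    x[[key]]
  }
  sv <- need(cfg, "survival", "top level")
  wb <- function(arm, endpoint) {
    row <- need(need(sv, arm, "survival"), endpoint, paste0("survival/", arm))
    weibull_params(need(row, "scale", endpoint), need(row, "shape", endpoint))
  }
  printed <- list(
    osimertinib = list(os = wb("osimertinib", "os"),
                       pfs = wb("osimertinib", "pfs")),
    placebo = list(os = wb("placebo", "os"), pfs = wb("placebo", "pfs")))
  arms <- build_arms(printed, conventions$os_assignment)

  countries <- list()
  for (cl in names(need(cfg, "countries", "top level"))) {
    cc <- cfg$countries[[cl]]
    countries[[cl]] <- country_inputs(
      country_label = cl,
      drug_cost_per_cycle = need(cc, "drug_cost_per_cycle", cl),
      ae_cost_oneoff = unlist(need(cc, "ae_cost_oneoff", cl)),
      lab_cost_per_cycle = need(cc, "lab_cost_per_cycle", cl),
      radiology_cost_per_cycle = need(cc, "radiology_cost_per_cycle", cl),
      bsc_cost_per_cycle = need(cc, "bsc_cost_per_cycle", cl),
      palliative_cost_oneoff = need(cc, "palliative_cost_oneoff", cl),
      discount_rate_annual = need(cc, "discount_rate_annual", cl),
      wtp_per_qaly = need(cc, "wtp_per_qaly", cl),
      subsequent_therapy_rate = unlist(need(cfg, "subsequent_therapy_rate",
                                            "top level")))
  }

  ut <- need(cfg, "utilities", "top level")
  ae <- need(cfg, "adverse_events", "top level")
  ae_df <- do.call(rbind, lapply(ae, function(a)
    data.frame(event = a$event, disutility = a$disutility,
               incidence = a$incidence)))
  utilities <- utility_inputs(need(ut, "u_pfs", "utilities"),
                              need(ut, "u_pd", "utilities"), ae_df)

  st <- cfg$settings
  settings <- model_settings(
    cycle_length_days = st$cycle_length_days %||% 28,
    horizon_years = st$horizon_years %||% 15,
    n_cycles = st$n_cycles,
    half_cycle_correction = st$half_cycle_correction %||% TRUE)

  subgroups <- lapply(cfg$subgroups %||% list(), function(s)
    subgroup_spec(s$label, s$pfs_hr %||% NA_real_,
                  s$ci_low %||% NA_real_, s$ci_high %||% NA_real_))

  bundle <- structure(list(arms = arms, printed_survival = printed,
                           countries = countries, utilities = utilities,
                           settings = settings, conventions = conventions,
                           subgroups = subgroups),
                      class = "cea_bundle")
  bundle$ranges <- build_ranges(bundle, cfg$ranges)
  bundle
}

build_arms <- function(printed, os_assignment) {
  os_o <- printed$osimertinib$os
  os_p <- printed$placebo$os
  if (identical(os_assignment, "corrected")) {
    # assign the longer-survival OS law to the treated arm (trial OS HR < 1)
    if (weibull_mean(os_o) < weibull_mean(os_p)) {
      tmp <- os_o; os_o <- os_p; os_p <- tmp
    }
  }
  list(osimertinib = arm_survival(os_o, printed$osimertinib$pfs,
                                  "osimertinib"),
       placebo = arm_survival(os_p, printed$placebo$pfs, "placebo"))
}

# Sensitivity/PSA ranges. Config may override any entry; defaults are the
# +/-20% rule with the published distribution families, except the discount
# rates whose printed ranges are asymmetric (0-0.05 US, 0-0.08 China).
build_ranges <- function(bundle, overrides = NULL) {
  rng <- list()
  add <- function(label, baseline, dist, low = NULL, high = NULL) {
    r <- if (is.null(low)) expand_range(baseline, 0.2, dist) else
      param_range(baseline, low, high, dist)
    rng[[label]] <<- r
  }
  for (cl in names(bundle$countries)) {
    cc <- bundle$countries[[cl]]
    add(paste0(cl, ".drug_cost_per_cycle"), cc$drug_cost_per_cycle, "gamma")
    add(paste0(cl, ".ae_cost_osimertinib"),
        cc$ae_cost_oneoff[["osimertinib"]], "gamma")
    add(paste0(cl, ".ae_cost_placebo"), cc$ae_cost_oneoff[["placebo"]],
        "fixed", 0, 0)
    add(paste0(cl, ".lab_cost_per_cycle"), cc$lab_cost_per_cycle, "gamma")
    add(paste0(cl, ".radiology_cost_per_cycle"),
        cc$radiology_cost_per_cycle, "gamma")
    add(paste0(cl, ".bsc_cost_per_cycle"), cc$bsc_cost_per_cycle, "gamma")
    add(paste0(cl, ".palliative_cost_oneoff"), cc$palliative_cost_oneoff,
        "gamma")
    add(paste0(cl, ".discount_rate_annual"), cc$discount_rate_annual,
        "uniform", 0, if (cl == "china") 0.08 else 0.05)
  }
  add("utilities.u_pfs", bundle$utilities$u_pfs, "beta")
  add("utilities.u_pd", bundle$utilities$u_pd, "beta")
  aed <- bundle$utilities$ae_disutilities
  for (i in seq_len(nrow(aed))) {
    add(paste0("ae.disutility.", aed$event[i]), aed$disutility[i], "beta")
    add(paste0("ae.incidence.", aed$event[i]), aed$incidence[i], "beta")
  }
  rates <- bundle$countries[[1L]]$subsequent_therapy_rate
  add("subsequent_therapy_rate.osimertinib", rates[["osimertinib"]], "beta")
  add("subsequent_therapy_rate.placebo", rates[["placebo"]], "beta")
  if (!is.null(overrides)) {
    for (label in names(overrides)) {
      o <- overrides[[label]]
      rng[[label]] <- param_range(o$baseline, o$low, o$high, o$distribution)
    }
  }
  rng
}

#' Set one bundle parameter by label
#'
#' Injects a value into a copy of the bundle, addressing parameters by the
#' same labels used in `bundle$ranges` (e.g. `"usa.drug_cost_per_cycle"`,
#' `"utilities.u_pfs"`, `"ae.incidence.diarrhea"`).
#'
#' @param bundle A `cea_bundle`.
#' @param label Parameter label.
#' @param value Replacement value.
#' @return The modified bundle.
#' @export
set_param <- function(bundle, label, value) {
  parts <- strsplit(label, ".", fixed = TRUE)[[1L]]
  head <- parts[1L]
  if (head %in% names(bundle$countries)) {
    field <- paste(parts[-1L], collapse = ".")
    if (field == "ae_cost_osimertinib") {
      bundle$countries[[head]]$ae_cost_oneoff[["osimertinib"]] <- value
    } else if (field == "ae_cost_placebo") {
      bundle$countries[[head]]$ae_cost_oneoff[["placebo"]] <- value
    } else if (field %in% names(bundle$countries[[head]])) {
      bundle$countries[[head]][[field]] <- value
    } else {
      stop(sprintf("unknown parameter label '%s'", label), call. = FALSE)
    }
  } else if (head == "utilities") {
    bundle$utilities[[parts[2L]]] <- value
  } else if (head == "ae") {
    aed <- bundle$utilities$ae_disutilities
    i <- match(paste(parts[-(1:2)], collapse = "."), aed$event)
    if (is.na(i)) stop(sprintf("unknown AE '%s'", label), call. = FALSE)
    aed[[if (parts[2L] == "disutility") "disutility" else "incidence"]][i] <-
      value
    bundle$utilities$ae_disutilities <- aed
  } else if (head == "subsequent_therapy_rate") {
    for (cl in names(bundle$countries))
      bundle$countries[[cl]]$subsequent_therapy_rate[[parts[2L]]] <- value
  } else {
    stop(sprintf("unknown parameter label '%s'", label), call. = FALSE)
  }
  bundle
}

#' Built-in parameter presets
#'
#' The published model inputs: Weibull OS/PFS parameters per arm, US and
#' China per-cycle costs, utilities and adverse-event disutilities,
#' discount rates, WTP thresholds and subgroup PFS hazard ratios.
#'
#' @inheritParams load_parameters
#' @return A `cea_bundle` with both country presets.
#' @examples
#' b <- default_parameters()
#' b$countries$usa$drug_cost_per_cycle   # 18034
#' b$countries$china$wtp_per_qaly        # 39632
#' @export
default_parameters <- function(conventions = model_conventions()) {
  path <- system.file("extdata", "laura_inputs.yaml", package = "osimcea",
                      mustWork = TRUE)
  load_parameters(path, conventions)
}

#' Write a parameter bundle back to YAML
#'
#' Inverse of [load_parameters()]: a written bundle reloads to the same
#' values (bit-exact for decimals representable in YAML).
#'
#' @param bundle A `cea_bundle`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(bundle, path) {
  pr <- bundle$printed_survival
  wbl <- function(w) list(scale = w$scale, shape = w$shape)
  cfg <- list(
    survival = list(
      osimertinib = list(os = wbl(pr$osimertinib$os),
                         pfs = wbl(pr$osimertinib$pfs)),
      placebo = list(os = wbl(pr$placebo$os), pfs = wbl(pr$placebo$pfs))),
    subsequent_therapy_rate =
      as.list(bundle$countries[[1L]]$subsequent_therapy_rate),
    countries = lapply(bundle$countries, function(cc)
      list(drug_cost_per_cycle = cc$drug_cost_per_cycle,
           ae_cost_oneoff = as.list(cc$ae_cost_oneoff),
           lab_cost_per_cycle = cc$lab_cost_per_cycle,
           radiology_cost_per_cycle = cc$radiology_cost_per_cycle,
           bsc_cost_per_cycle = cc$bsc_cost_per_cycle,
           palliative_cost_oneoff = cc$palliative_cost_oneoff,
           discount_rate_annual = cc$discount_rate_annual,
           wtp_per_qaly = cc$wtp_per_qaly)),
    utilities = list(u_pfs = bundle$utilities$u_pfs,
                     u_pd = bundle$utilities$u_pd),
    adverse_events = unname(apply(bundle$utilities$ae_disutilities, 1L,
      function(r) list(event = unname(r[["event"]]),
                       disutility = as.numeric(r[["disutility"]]),
                       incidence = as.numeric(r[["incidence"]])))),
    settings = list(
      cycle_length_days = bundle$settings$cycle_length_days,
      horizon_years = bundle$settings$horizon_years,
      n_cycles = bundle$settings$n_cycles,
      half_cycle_correction = bundle$settings$half_cycle_correction),
    subgroups = lapply(bundle$subgroups, function(s)
      list(label = s$subgroup_label, pfs_hr = s$pfs_hr,
           ci_low = s$hr_ci_low, ci_high = s$hr_ci_high)))
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}

#' @export
print.cea_bundle <- function(x, ...) {
  cat("Cost-utility parameter bundle\n")
  cat("  countries:", paste(names(x$countries), collapse = ", "), "\n")
  cat(sprintf("  cycles: %d x %.4f months (%g-year horizon)\n",
              x$settings$n_cycles, x$settings$months_per_cycle,
              x$settings$horizon_years))
  cat(sprintf("  structure: %s, OS assignment: %s\n",
              x$conventions$structure, x$conventions$os_assignment))
  cat(sprintf("  subgroups: %d, sensitivity ranges: %d\n",
              length(x$subgroups), length(x$ranges)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
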