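# Model inputs for osimertinib vs placebo consolidation after
# chemoradiotherapy in unresectable stage III EGFR-mutated NSCLC.
# Weibull laws: S(t) = exp(-scale * t^shape), t in months.
# OS rows are stored under their published arm labels; the loader's
# "corrected" assignment (the default) swaps them so the treated arm
# carries the longer-survival law (see package documentation).
survival:
  osimertinib:
    os:  {scale: 0.000005603, shape: 2.931}
    pfs: {scale: 0.033281, shape: 0.849111}
  placebo:
    os:  {scale: 0.0001721, shape: 2.050}
    pfs: {scale: 0.12138, shape: 0.96416}

# Share of progressing patients receiving subsequent systemic therapy
# (mostly osimertinib); the remainder receive best supportive care.
subsequent_therapy_rate:
  osimertinib: 0.294
  placebo: 0.781

countries:
  usa:
    drug_cost_per_cycle: 18034
    ae_cost_oneoff: {osimertinib: 351, placebo: 0}
    lab_cost_per_cycle: 609
    radiology_cost_per_cycle: 1765
    bsc_cost_per_cycle: 3728
    palliative_cost_oneoff: 14532
    discount_rate_annual: 0.03
    wtp_per_qaly: 150000
  china:
    drug_cost_per_cycle: 685
    ae_cost_oneoff: {osimertinib: 48, placebo: 0}
    lab_cost_per_cycle: 609
    radiology_cost_per_cycle: 1765
    bsc_cost_per_cycle: 467
    palliative_cost_oneoff: 2349
    discount_rate_annual: 0.05
    wtp_per_qaly: 39632

utilities:
  u_pfs: 0.791
  u_pd: 0.653

# Grade >= 3 treatment-related adverse events with frequency >= 1%
# (treated arm only; the placebo row of the source table is "NA").
adverse_events:
  - {event: diarrhea, disutility: 0.050, incidence: 0.014}
  - {event: radiation_pneumonitis, disutility: 0.090, incidence: 0.014}
  - {event: pneumonitis, disutility: 0.090, incidence: 0.014}

settings:
  cycle_length_days: 28
  horizon_years: 15
  n_cycles: 195
  half_cycle_correction: true

# Subgroup PFS hazard ratios (osimertinib vs placebo); null = not reported.
subgroups:
  - {label: "Male", pfs_hr: 0.26, ci_low: 0.15, ci_high: 0.46}
  - {label: "Female", pfs_hr: 0.21, ci_low: 0.13, ci_high: 0.34}
  - {label: "< 65 years", pfs_hr: 0.16, ci_low: 0.10, ci_high: 0.26}
  - {label: ">= 65 years", pfs_hr: 0.33, ci_low: 0.19, ci_high: 0.57}
  - {label: "Current or former smoker", pfs_hr: 0.26, ci_low: 0.14, ci_high: 0.48}
  - {label: "Never smoker", pfs_hr: 0.22, ci_low: 0.14, ci_high: 0.34}
  - {label: "Stage IIIA", pfs_hr: 0.28, ci_low: 0.15, ci_high: 0.52}
  - {label: "Stage IIIB or IIIC", pfs_hr: 0.21, ci_low: 0.13, ci_high: 0.33}
  - {label: "Exon 19 deletion", pfs_hr: 0.17, ci_low: 0.10, ci_high: 0.29}
  - {label: "L858R mutation", pfs_hr: 0.32, ci_low: 0.19, ci_high: 0.56}
  - {label: "Concurrent chemoradiotherapy", pfs_hr: 0.25, ci_low: 0.17, ci_high: 0.36}
  - {label: "Sequential chemoradiotherapy", pfs_hr: null}
  - {label: "Complete response to CRT", pfs_hr: null}
  - {label: "Partial response to CRT", pfs_hr: 0.20, ci_low: 0.11, ci_high: 0.34}
  - {label: "Stable disease after CRT", pfs_hr: 0.18, ci_low: 0.10, ci_high: 0.30}
  - {label: "Response not evaluable", pfs_hr: null}
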