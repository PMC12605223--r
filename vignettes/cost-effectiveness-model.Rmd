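---
title: "A three-state cost-utility model of osimertinib consolidation in stage III EGFR-mutated NSCLC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-state cost-utility model of osimertinib consolidation in stage III EGFR-mutated NSCLC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osimcea)
```

## The decision problem

Patients with unresectable stage III non-small-cell lung cancer carrying a
sensitising EGFR mutation who have not progressed after chemoradiotherapy
can receive consolidation therapy with osimertinib, an EGFR tyrosine-kinase
inhibitor, instead of observation (placebo). Consolidation roughly
quintuples median progression-free survival, but the drug is expensive and
taken until progression, so the value question differs sharply between a
high-price payer (the United States) and a low-price, lower-threshold payer
(China). `osimcea` implements the full decision model: survival
extrapolation, a three-state cohort engine, incremental cost-effectiveness
accounting, deterministic and probabilistic sensitivity analyses, and
hazard-ratio-driven subgroup analyses.

## Model structure

The cohort occupies three health states: progression free (PFS), progressed
disease (PD), and dead. Time advances in 4-week cycles
(`28 * 12 / 365.25 = 0.92` months per cycle) over a 15-year horizon (195
cycles), by which point more than 99% of the cohort has died under either
strategy; both numbers are configurable through `model_settings()`.

State membership is *partitioned survival*: with `S_OS` and `S_PFS` the
arm's overall-survival and progression-free-survival laws,

    death(t) = 1 - S_OS(t)
    pfs(t)   = min(S_PFS(t), S_OS(t))
    pd(t)    = 1 - death(t) - pfs(t)

Occupancy is therefore read directly off the two curves rather than chained
through a transition matrix. A transition-probability chain
(`compute_trace(..., structure = "markov_chain")`, built on
`cycle_transition_prob()`) is retained as a structural variant; the two
agree to numerical precision wherever the curves have not crossed, and the
chain clamps PFS to the survivors after a crossing.

## Survival inputs and their interpretation

Each endpoint follows a cumulative-hazard Weibull,
`S(t) = exp(-scale * t^shape)` with `t` in months. The built-in presets
carry the published fitted parameters. Two interpretation questions were
genuinely open and are resolved as follows:

* **Time unit.** The parameters only reproduce the trial's reported median
  PFS values (38.9 and 7.3 months) on a month scale: the fitted medians are
  35.7 and 6.09 months (`weibull_median()`). A week or cycle scale puts
  them far off, so months it is.

* **OS arm assignment.** Taken at their printed arm labels, the two OS
  parameter rows give the *placebo* arm about 0.46 more undiscounted
  life-years than the treated arm. That contradicts the trial's interim OS
  hazard ratio of 0.81 favouring osimertinib and the source analysis's own
  life-year totals, which show the treated arm ahead by 0.45 LYs. We treat
  this as a transposition in the input table: the default
  `os_assignment = "corrected"` gives the treated arm the longer-survival
  law, and `"as_printed"` is available as a switch. With the correction the
  incremental life-years (+0.46 undiscounted) and all four life-year totals
  line up with the published base case to within ~1% (undiscounted) —
  without it the sign of the incremental effect is wrong.

Five parametric families (exponential, Weibull, log-normal, log-logistic,
Gompertz) can be fitted to reconstructed patient-level data by maximum
likelihood under right censoring (`fit_parametric()`), and
`select_best_family()` ranks them by AIC, breaking ties by BIC and then by
parameter count. A purely numeric rule replaces visual curve inspection for
reproducibility. The Gompertz is parameterised as
`S(t) = exp(-(b/c)(exp(ct) - 1))` with `c` allowed negative but bounded in
`[-1, 1]`; the log-logistic as `1/(1 + (t/alpha)^beta)`. Optimisation runs
on log-transformed positive parameters (Nelder–Mead, Brent for the
one-parameter exponential) from three starting points to guard against
local optima.

## Accrual rules and calibrated conventions

Per cycle, with half-cycle (trapezoid) correction by default:

* PFS members accrue the drug acquisition cost (treated arm only) and the
  PFS utility (0.791).
* PD members accrue subsequent-therapy drug cost — drug price times the
  arm-specific subsequent-therapy rate (0.294 treated / 0.781 placebo;
  most progressing patients in both arms receive osimertinib) — plus
  best-supportive-care cost for the non-recipients, and the PD utility
  (0.653).
* Each cycle's death increment accrues the one-off palliative/terminal
  cost.
* The treated arm takes a one-off adverse-event cost and an
  incidence-weighted utility decrement (three grade ≥ 3 events, each at
  1.4% incidence) at model entry; no duration is specified for these
  events, so a single hit is the least-assumption choice.
* All flows are discounted at `(1 + r)^(-t)` with the country's annual rate
  (3% US, 5% China) applied to costs and QALYs.

Several accounting conventions are not pinned down by the published
description. Each is an explicit switch in `model_conventions()`, and the
defaults were chosen — by grid search over the switch space only, never
over the input values — to maximise agreement with the published base-case
table:

| Switch | Options | Default | Note |
|---|---|---|---|
| `structure` | partitioned / markov_chain | partitioned | standard realisation |
| `os_assignment` | corrected / as_printed | corrected | see above |
| `monitoring_in` | none / pfs / pd / both | none | see below |
| `bsc_for_nonrecipients` | on / off | on | stated accrual rule |
| `palliative_at_death` | on / off | on | per-patient one-off |
| `half_cycle_correction` | on / off | on | trapezoid occupancy |
| `discount_ly` | on / off | off | see below |

Two defaults deserve comment. *Monitoring costs*: the input table prices
laboratory and radiology monitoring identically for both countries
(609 + 1765 USD per cycle). Accruing them in any state is irreconcilable
with the published China totals — a single cycle of monitoring at that
price is about 7% of the entire published China placebo budget — so the
default accrues none; the costs remain in the presets and the switch
restores any accrual. *Life-year discounting*: the published US life-year
totals exceed the discounted area under either OS curve but match the
undiscounted areas to about 1%, and the source description of which
benefit stream is discounted at which rate is ambiguous; headline
life-years are therefore reported undiscounted (the discounted twin is
always computed, and QALYs and costs are always discounted).

Even at the calibrated defaults the published table is not fully
reproducible: the published China osimertinib total cost requires a
progressed-disease phase far longer than the published QALY increments
allow, and the published incremental cost in the US implies roughly 0.35
discounted years less drug exposure than the published PFS/OS curves
produce. The package reports what the published inputs imply; the
acceptance checks quantify the residual gaps rather than paper over them.
At the defaults, 11 of the 12 published base-case cells agree within 10%,
and the sign of the incremental net health benefit matches in both
countries (negative in the US, positive in China).

## Economic outputs

For increments `dC`, `dE` (comparator minus reference, full precision):

* `ICER = dC / dE` per QALY and per LY, with dominance flags when the
  signs disagree;
* `INHB = dE - dC / WTP` in QALYs — positive exactly when the ICER is
  below the willingness-to-pay threshold;
* `NMB = WTP * dE - dC = WTP * INHB` in dollars.

Thresholds: 150,000 USD/QALY (US) and 39,632 USD/QALY (China, three times
2024 per-capita GDP). Display rounding (dollars to integers, effects to
two decimals) is applied only in `base_case_report()`; every computation
uses full precision.

## Sensitivity analyses

**One-way (tornado).** Every parameter with a range is set to its low and
high bound with everything else at baseline; ranges are ±20% of baseline
except the discount rates, whose published ranges are 0–0.05 (US) and
0–0.08 (China). Entries are sorted by ICER spread; the PFS utility
dominates both countries' tornados, consistent with the published finding.

**Scenario analysis.** `scenario_analysis()` reruns the pipeline under
arbitrary utility overrides; no specific alternative utility sets ship as
presets because their values are not published in the main text.

**Probabilistic.** `run_psa()` jointly resamples all distributed
parameters: costs from gamma, utilities, adverse-event incidences and
subsequent-therapy rates from beta, discount rate uniform on its published
range. Distributions are method-of-moments with mean equal to the baseline
and `SE = (high - low)/(2 * 1.96)` — the published description states the
families but not their dispersion, so this conventional choice is exposed
in the config. Infeasible beta variances fall back to uniform with a
warning. The Weibull survival parameters carry no published distribution or
covariance matrix and are **held fixed** in the PSA; an exploratory
lognormal-on-scale toggle (`survival_uncertainty = TRUE`) exists but is off
by default. The CEAC reports, per WTP value, the fraction of draws with
positive incremental net monetary benefit. Because survival uncertainty is
excluded by necessity, the PSA spread is narrower than the published one;
the acceptance probability at the US threshold is correspondingly lower
than the published 21.1%.

**Subgroups.** The published subgroup table varies only the PFS hazard
ratio, so `analyze_subgroup()` replaces the treated arm's PFS curve with
the placebo baseline raised to the power `hr` (proportional hazards keep
the Weibull shape), holding OS curves and costs at base case. The
alternative reading — rescaling the treated arm's fitted curve by
`hr / 0.19` (the trial-wide hazard ratio) — is available via
`method = "treated_rescale"`; both weaken the treated PFS curve similarly.
Under the calibrated conventions the subgroup ICER *falls* as the hazard
ratio rises: less time progression free means proportionally less drug
spending than QALY loss. Per-subgroup cost-effectiveness probabilities come
from a reduced-size PSA (1000 draws by default).

## The synthetic-data generator

The survival inputs were originally obtained by digitizing published
Kaplan–Meier figures and reconstructing pseudo individual-patient data.
The package emulates that pipeline end to end so the fitting machinery is
testable without any external data:

1. `generate_ipd()` draws event times from a Weibull law by inverse CDF,
   with independent uniform censoring (probability `censor_rate`) and
   administrative censoring at end of follow-up. Default cohort sizes
   mirroring the trial arms are 143 treated / 73 placebo (back-computed
   from the published subsequent-therapy counts 42/0.294 and 57/0.781).
2. `km_estimate()` computes the product-limit curve (via the survival
   package) with numbers at risk at landmark times.
3. `digitize_emulate()` resamples the curve on a uniform grid and adds
   truncated Gaussian survival-axis noise, re-monotonised by running
   minimum — emulating manual figure extraction.
4. `ipd_reconstruct()` performs Guyot-style interval accounting: per
   landmark interval, the censoring count is chosen iteratively so the
   implied risk set matches the published number at risk, events are read
   off the product-limit drops (with fractional-event carry to conserve
   totals, and event times placed at the midpoint of the gap between
   digitized points), and one record is emitted per inferred patient.
   Interval accounting was preferred over least-squares curve matching
   because it yields genuine record-level output.

What this emulation does *not* capture: the real trial's non-uniform
censoring pattern (driven by staggered accrual and data cut-offs),
informative censoring, and reading errors correlated along the time axis.
Passing the round-trip test (generate → KM → digitize → reconstruct → fit
recovering parameters within 10% median error at n = 500 over 20 seeds)
therefore validates the machinery, not the fidelity of any specific
published digitization.

## Numerical choices and degenerate inputs

* Occupancy conservation is asserted to 1e-9 at every cycle; the
  telescoping identity between chained transition probabilities and the
  survival curve holds to 1e-12.
* An exhausted risk set in `cycle_transition_prob()` returns probability 1
  (absorbing exhaustion) rather than 0/0.
* `icer()` flags a zero effect difference as undefined instead of
  dividing; INHB remains defined.
* Degenerate parameter ranges (`low == high`) sample as point masses.
* MLE convergence failures return `converged = FALSE` with diagnostics
  rather than throwing; `select_best_family()` errors only if every family
  fails, listing per-family diagnostics.
* Problem sizes used by the test suite — 10,000 PSA draws for the headline
  probabilities, 2000 observations × 20 seeds for parameter recovery, 500
  × 20 for the digitization round trip — were chosen to make Monte-Carlo
  noise small relative to the tolerances being checked.

## Known limitations

* OS extrapolation rests on immature interim trial data; both OS curves
  are fitted Weibulls over a horizon several times the observed follow-up.
* The monitoring-cost and life-year-discounting conventions were selected
  by calibration against the published base case because the published
  description underdetermines them; the residual disagreements documented
  above persist under every convention set searched and appear to reflect
  inconsistencies in the published figures themselves.
* No efficiency frontier (only two strategies), no EVPI/EVPPI, no
  correlated parameter sampling (no published correlations), and no
  subgroup-specific costs or utilities (none published).
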