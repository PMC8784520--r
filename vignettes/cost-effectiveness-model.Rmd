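---
title: "A partitioned-survival cost-effectiveness model for first-line NSCLC immunotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A partitioned-survival cost-effectiveness model for first-line NSCLC immunotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmcea)
```

## The decision problem

For metastatic NSCLC with PD-L1 expression of at least 50%, two first-line
standards coexist: pembrolizumab monotherapy and pembrolizumab combined with
platinum-based chemotherapy. No head-to-head trial compares them, so the
comparison must be indirect, and the economic question — does the
combination's extra survival justify its extra cost? — must be answered by
modelling. `psmcea` implements that model as a partitioned-survival cohort
simulation with explicit, testable components, for non-squamous and squamous
histologies separately.

## Model structure

Four states: progression-free on first-line therapy, progression-free off
therapy (discontinued for toxicity), progressive disease, and death. The
cohort runs over 240 one-month cycles (20 years). Occupancy is derived from
the survival curves rather than from a hand-built transition matrix:
`PFS(t) = S_PFS(t)`, `dead(t) = 1 − S_OS(t)`, `PD(t)` the difference,
clipped at zero with a warning where the independently fitted curves cross
(they genuinely do at early times for these inputs, an artefact of fitting
OS and PFS separately). This partitioned-survival arithmetic is the only
construction consistent with driving the model directly from published OS
and PFS curves.

Within PFS, the fraction still on each drug decays by that drug's per-cycle
probability of discontinuation due to adverse events, and a drug stops
contributing when its maximum number of administrations is exhausted. The
cohort-level on-treatment fraction is the largest per-drug on-drug fraction
(the backbone drug outlasts its partners in every regimen considered).

Deaths are apportioned between PFS and PD in proportion to the occupancy of
the preceding cycle; new progressions are the PD inflow implied by the
partition plus those deaths. These increments only drive one-off costs
(subsequent therapy, death-associated care), so the apportionment rule has a
small, bounded effect.

## Survival inputs

The combination arm uses log-logistic curves `S(t) = 1/(1 + θ t^κ)` (time in
months), the family selected for these trials by AIC/BIC among exponential,
Weibull, log-logistic, log-normal and Gompertz candidates. The monotherapy
arm applies indirect-comparison hazard ratios. Two conventions deserve
comment:

* **Hazard-ratio scale.** The HR acts on the cumulative hazard,
  `S(t)^HR`. The log-logistic family is not proportional-hazards, and the
  source HRs come from a proportional-hazards-style indirect comparison;
  applying them on the cumulative-hazard scale is the dominant convention in
  published cost-effectiveness models and is a one-line change
  (`apply_hazard_ratio()`) if a different scale is preferred.
* **Independent endpoints.** OS and PFS hazard ratios are applied
  independently to their own curves; any induced crossing is clipped in the
  trace.

Three long-term extrapolation strategies:

1. **Pure parametric** (`scenario1`): the fitted curves run the whole
   horizon.
2. **Registry splice** (`base`): parametric for the first five years, then
   annual conditional survival probabilities from a cancer-registry-style
   table, interpolated within years at constant hazard and continuous at the
   splice. The bundled table is a synthetic stand-in (0.84 rising to a 0.95
   plateau per year, the magnitude typical of distant-stage NSCLC
   conditional survival); users with registry access should supply their own
   via `read_registry_table()`.
3. **Background mortality** (`scenario2`): overall survival built from an
   age-indexed life table (constant-hazard conversion of annual
   probabilities) with the probability of a fatal treatment-related adverse
   event applied once in the first cycle. The bundled life table is a
   synthetic Gompertz schedule `q(age) = 0.012·e^{0.09(age−64)}` from age 64,
   the magnitude of US general-population mortality at those ages. This
   strategy deliberately ignores disease-specific mortality beyond fatal
   AEs; it answers "what if mortality reverted to background?" and, as the
   model shows, it inverts the QALY ordering of the arms — the reason such
   constructions should be used with caution.

## Costs, utilities, discounting

Drug quantities follow the dose rules (flat, per-m² with BSA 1.79 m²,
Calvert AUC with CrCl 70 mL/min) and are rounded up to whole single-use
vials — the smallest total covering the dose, ties broken by fewest vials —
so wastage is billed. Administration fees bill the first infusion hour at
the 1-hour rate and each additional hour at the add-on rate. Three-weekly
regimens accrue 30.44/21 administrations per monthly cycle as a continuous
rate; pembrolizumab is capped at 35 administrations (two years), induction
chemotherapy at 4, pemetrexed maintenance runs until progression. Routine
follow-up is a monthly physician visit plus an imaging examination every
third cycle; the progressed fraction not on subsequent therapy receives best
supportive care monthly. One-off events: adverse-event management cost and
QALY decrement at entry (the published aggregates are frequency-weighted
over grade ≥3 events with incidence ≥1%; `ae_burden()` regenerates them from
an incidence table when one is available), subsequent-anticancer-therapy
cost times an uptake parameter at each new progression, and a
death-associated cost at each death.

The proportion of progressing patients receiving subsequent therapy is not
derivable from the published inputs; it is a transparent knob
(`subsq_uptake`, default 0.5, range 0.25–0.75) rather than a buried
assumption.

Utilities follow a time-to-death approach: a patient alive at `t` receives
the mixture of window utilities weighted by the conditional probability of
dying within 1, 1–6, 6–12, or beyond 12 months, computed from the arm's OS
curve. Setting all windows equal reduces QALYs to utility-weighted
life-years exactly, a tested identity. Costs and QALYs discount at 3%/year
as `(1+r)^{−t/12}`; no half-cycle correction is applied by default (a
`half_cycle` switch exists).

## Uncertainty analysis

One-way DSA sweeps each parameter across its published range (or ±50% when
no interval is published) and ranks by ICER spread; where dominance makes an
ICER undefined at a bound, ordering falls back to net monetary benefit at
$100,000/QALY. PSA draws: log-normal for hazard ratios (baseline as median,
log-SD from the CI), beta for probabilities and utilities and gamma for
costs (moment-matched to the baseline and the CI-implied SD, with a uniform
fallback and warning if beta moments are infeasible), truncated normal for
the remaining quantities. The acceptability curve reports, per
willingness-to-pay value on a $0–$300,000 grid, the fraction of draws with
positive net monetary benefit for the combination.

## Synthetic data and what the tests do (and do not) show

No external data ship with the package. `simulate_km()` draws censored
individual-patient data from a stated law (defaults: n = 400, 30-month
administrative cutoff, light random censoring — a modern first-line trial
arm) and digitizes the resulting Kaplan-Meier curve at one-month resolution
with its number-at-risk table. `reconstruct_ipd()` inverts such
digitizations with the standard iterative risk-table-matching algorithm;
`fit_distribution()`/`select_best()` refit and choose among candidate
families.

Two honest caveats. First, the one-month digitization grid places
reconstructed events on month boundaries, so refitted shape parameters carry
a resolution floor (a few percent on κ, amplified on θ = scale^−κ) that
does not vanish with sample size; fitting the individual-patient data
directly is unbiased, and real digitizations with dense click points sit in
between. Second, the synthetic registry and life tables are illustrative
schedules, not transcriptions; base-case results under them are qualitative.
Passing tests therefore demonstrate the machinery is correct under the
stated generating laws, not that the bundled fixtures equal any particular
registry's experience.

For the background-mortality scenario, the bundled fatal treatment-related
AE probabilities used in testing are 0.006 for monotherapy and 0.045
(non-squamous) / 0.036 (squamous) for the combination — the magnitude of
treatment-related deaths reported in the first-line trials; the shipped
configurations default them to 0 so that scenario-2 users must opt into a
value deliberately.

## Numerical choices and degenerate inputs

* Vial rounding uses a bounded dynamic programme on the mg-grid implied by
  the vial sizes; ties in overage resolve to fewer vials.
* Spliced curves are continuous at the switch by construction (anchored at
  the parametric value) and error on registry gaps rather than
  extrapolating.
* `S(t) = 0` states raise degenerate-state errors in conditional quantities
  (per-cycle probabilities, time-to-death utilities) instead of dividing by
  zero; the trace handles fully-dead tails by zeroing their accruals.
* Equal-effect comparisons (|ΔQALY| < 1e−9) are flagged rather than turned
  into unstable ratios; opposite-sign increments produce `dominated` /
  `dominant` flags.
* The reconstruction adjusts interval censoring counts for up to 60
  iterations and accepts the closest feasible allocation if the published
  risk table is internally inconsistent.

## Problem sizes

The deterministic model is vectorized over cycles and runs both arms in
well under 0.1 s, so the full DSA (~30 parameters × 2 bounds) takes a few
seconds. Test-suite PSAs use 20–300 iterations and the selection-consistency
study uses 100 replicates of n = 1,000 fits; production PSAs at 10,000
iterations complete in a few minutes.

## Known limitations

* The regimen details (doses, vial presentations, maximum durations) are
  standard-of-care reconstructions, config-editable, not transcriptions of
  any trial protocol appendix; headline ICERs for the squamous comparison
  are sensitive to these at the $1,000 scale because its incremental cost is
  small.
* Indirect hazard ratios are treated as fixed inputs; the package's
  `bucher_indirect_hr()` covers the two-trial single-comparator case, not a
  full network meta-analysis. Published posterior intervals need not be
  log-symmetric around the point estimate, which a ratio-of-ratios interval
  always is.
* No treatment-effect waning, dose reductions, or relative dose intensity;
  costs are not re-inflated across years.
* Comparison against traditional chemotherapy is out of scope: ICI-based
  regimens are the standard of care in this population.
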