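---
title: "The HS2 recurrent-hypoglycaemia economic model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The HS2 recurrent-hypoglycaemia economic model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hs2cea)
```

## The decision problem

After an ambulance crew resolves a hypoglycaemic attack at scene, the
patient is discharged without conveyance and faces an elevated risk of a
recurrent attack in the following fortnight. The HS2 intervention is a
booklet issued at scene: the crew records vitals in it, encourages the
patient to read it, and — during business hours — books a next-day GP
appointment. `hs2cea` models whether adding this referral activity to
standard care is good value for the NHS, on three questions: cost per
recurrence avoided (cost-effectiveness), cost per QALY (cost-utility), and
the chance that HS2 ends up cheaper overall once GP consultation eventually
happens under either arm (cost-minimisation).

## Model structure and assumptions

The model is a cohort decision tree in three stages; the full tree is the
composition of stage 3 onto every non-terminating stage-2 node, mapped onto
every stage-1 branch, giving 30 terminal pathways for the HS2 arm and 20
for standard care (`build_arm()` enumerates them; `write_pathways()` exports
the audit table).

Key structural assumptions:

* **Perfect triage, severe-only attendance.** The 999 and 111 triage desks
  classify severity correctly and EMS attends only severe recurrences. A
  severe call to 111 is redirected to 999 (an extra call cost) before
  attendance. Consequently a pathway's outcome is severe exactly when it
  contains an EMS-attendance node.
* **Exponential time to recurrence.** Recurrence within the fortnight has
  probability `1 − exp(−r)` for a per-fortnight incident rate `r`. The rate
  cap 1.65 derives from the top of the published incidence range
  (42,890 episodes per 1,000 person-years; `annual_rate_to_fortnight()`).
* **Constant severity probability per arm.** A single `p4` (HS2) and `q4`
  (standard care) applies at every 999 and 111 severity node. This is what
  makes calibration a one-liner: the arm's attendance probability is
  `p4 × Σᵢ Pᵢ` with `Σᵢ Pᵢ = Σ stage1 × p2 × (p31 + p32)`, so
  `calibrate_severity_probability()` divides the observed repeat-attendance
  rate by that sum, and re-evaluating the arm recovers the observed rate to
  machine precision (a tested invariant).
* **Cost composition.** A pathway's cost is the sum of its state costs
  (e.g. a severe 111 pathway costs 111-call + redirect-999-call + stage-3
  states), each state carrying one provider tag (EMS, IUC, primary,
  secondary care).

## Parameters

All parameters live in one configuration (`default_config()`, or the
YAML serialisation shipped at `inst/extdata/hs2_baseline.yaml`); every
analysis is a pure function of it.

| Parameter | Default | Units | Notes |
|---|---|---|---|
| stage-1 split (HS2) | 0.4125 / 0.3375 / 0.25 | probability | read+action / read-only / no actions |
| stage-1 split (SC) | 0.25 / 0.75 | probability | action / no action |
| incident rates | 0.75 / 0.9 / 1.0 | per fortnight | full / partial / no success; `r_max = 1.65` |
| call probabilities | 0.3625+0.2375 (read+action), 0.4+0.35 (others) | probability | residual self-manages |
| observed repeat rates | 0.045 / 0.055 | proportion | calibration targets (trial primary outcome) |
| conveyance, admission | 0.6, 1/3 | probability | shared across arms |
| intervention cost | £9.95 | GBP | booklet £1.60 + crew time £2.55/min |
| utility decrements | 0.004/0.007 (NS), 0.062/0.057 (S) | utility | day/night; averaged at day share 0.28 |
| annualisation factor | 9/182 | 1/year | see below |
| PSA | triangular(0, 1.65; modes 0.75/0.9/1), BN(707, 4.5%), BN(1674, 5.5%) | — | 10,000 draws |
| cost-min | pGP ∈ {0.3, 0.4, 0.5}, ≤ 6 cycles, stop at 95% absorption | — | fortnight cycles within 90 days |

The baseline intervention cost is carried as the constant £9.95. Its own
components imply `1.60 + 2.55 × (0.28 × 6.6 + 0.72 × 2) ≈ £10.02`
(`intervention_cost(weighted_admin_time(0.28, 6.6, 2))`), a small
discrepancy in the source material; both values are exposed and neither is
silently substituted for the other. The out-of-hours (£6.70) and in-hours
(£18.43) variants are the shipped one-way sensitivity scenarios.

## Cost-utility

The utility pathway is flat at `U0` unless recurrence happens at time `T`,
after which it drops by a severity-specific decrement for the rest of the
fortnight (no recovery inside the window), so `U0` cancels in the
between-arm difference. `T` is triangular on (0, 14) days with mode 2;
`E[14 − T] = 26/3` days in closed form (`expected_decrement_days()`). The
annualised QALY difference is
`factor × (Δ_NS (pNS_sc − pNS_hs2) + Δ_S (pS_sc − pS_hs2))`.

The annualisation factor defaults to `9/182 ≈ 0.0495`. Its provenance is
not derivable from first principles here (it is not `E[14 − T]/365`), so it
is a plain configuration parameter; the default is the value under which
the published cost-per-QALY arithmetic is internally consistent.
`qaly_difference(method = "mc")` integrates over `T` by Monte Carlo,
weighting each draw by `(14 − T)/E[14 − T]`, and is tested to converge to
the closed form — this checks the triangular expectation without asserting
any particular reading of the factor.

## Probabilistic sensitivity analysis

Each draw samples the three incident rates independently from triangular
distributions (support (0, 1.65), modes at baseline) and the two
repeat-attendance rates as binomial proportions at the trial arm sizes,
then recalibrates `p4`/`q4` inside the draw; all other parameters stay at
baseline. Draws are kept even when they violate the deterministic ordering
`r_HS2 < r_HS2e < r_NA` (the rates are sampled independently);
`psa$enforce_rate_ordering = TRUE` switches to rejection sampling. Draws
with infeasible calibration (`p4 > 1`) would be excluded and counted; at
the shipped settings none occur. Axes are scaled per 100 patients.
Evaluation uses a vectorised closed-form evaluator that the test suite
pins against the pathway enumeration and an independent recursive tree
evaluator at 1e-9.

## Cost-minimisation

Both arms are extended to fortnightly cycles with GP consultation as the
absorbing event. The GP-engaged stage-1 types start absorbed; in each later
cycle the remaining types absorb with common probability `pGP`, paying the
GP fee once, while unabsorbed mass re-incurs its type's first-cycle
recurrence-management expectation (one-off stage-1 costs excluded). The
recorded statistic is the first cycle at which HS2's cumulative cost falls
strictly below standard care's; recording stops once absorption exceeds 95%
in both arms, or after 6 cycles (the number of fortnights within the
90-day secondary horizon).

Two genuinely open choices were resolved as follows:

* **Post-absorption accrual.** The source material states only that
  absorption attracts a once-only GP cost. The default here is therefore
  *no* further accrual for absorbed patients (`absorbed_accrual = "none"`).
  The alternative — absorbed mass keeps accruing its arm's GP-engaged
  type's recurrence expectation (`"gp_type"`) — is available, but it
  reverses the model's expected qualitative behaviour: because the HS2
  GP-engaged type's continuation cost is far below standard care's, that
  accrual rule makes a *higher* GP consultation rate favour HS2, whereas
  under `"none"` a higher `pGP` weakly lowers the crossing probability at
  every cycle, as one expects when absorption erodes the arms' differences.
  Exact cross-arm cancellation of any common accrual is impossible anyway
  since the arms' absorbed masses differ from cycle 1.
* **Continuation costs** replicate the first-cycle draw (stochasticity
  enters only through the first-cycle parameters), so each simulation is a
  deterministic cohort chain given its draw.

## Synthetic trial data

`simulate_trial()` generates episode-level tables with the aggregates the
model consumes: per-arm Bernoulli repeat flags (707 episodes at 4.5%, 1674
at 5.5% by default), a 28%/72% day/night split, 60% conveyance, and
at-scene durations from a common log-normal base (median ≈ 30 min, a
typical at-scene time for a resolved hypoglycaemia) with deterministic
intervention-arm shifts of 6.6 min (day) and 2 min (night), so the median
differences per stratum are exact in expectation. Only median differences
are anchored by the source data; the log-normal shape is a modelling choice
(any right-skewed positive family with controlled medians would do).
`estimate_model_inputs()` + `config_from_trial()` close the loop from raw
table to full pipeline; tests check parameter recovery tightens at 10× the
sample size and that the efficacy test holds its 5% size on null data. The
generator does **not** emulate calendar structure, operational ambulance
fields, or within-patient correlation, so passing tests demonstrate
estimator correctness, not robustness to real-world messiness.

## Reproduction of previously published values, and deviations

The outcome side of the model reproduces the published derivations exactly:
calibrated severity probabilities 0.113/0.121, no-recurrence probabilities
42.4%/39.4%, relative-risk reduction 7.6%, efficacy p = 0.33, the
intervention-cost variants and the self-manage weighted costs (these are
what `scripts/acceptance.R` recomputes).

The cost side cannot be reproduced from the stated structure alone: the
published provider attribution of composite states is under-specified (and
the published baseline ICER arithmetic is inconsistent at the penny level —
its own formula evaluates to 309.67 against a stated 309.36). This package
computes costs strictly from the stated tree and per-state assignments,
which yields higher arm totals than the published table, dominated by the
ED-plus-admission and 111-disposition states. `compare_reference()`
recomputes every published headline quantity (arm and provider costs, all
ICERs, PSA quadrant shares, cost-minimisation averages) and tabulates the
deviations; nothing is tuned toward the published numbers. The
`attribution$pathways_111` switch ("iuc" vs "split") exposes the one
attribution the source motivates but does not fix.

## Numerical choices

* Calibration, pathway probabilities and costs are exact arithmetic; the
  law of total probability and the enumeration-vs-recursive-evaluator
  agreement are asserted at 1e-9 on random parameter sets.
* Probabilities are validated to [0, 1] with 1e-9 slack on sum constraints;
  mixes must sum to 1 at 1e-9.
* Degenerate inputs: zero incident rates give the point distribution
  (1, 0, 0) and calibration returns 0 for a zero observed rate; a zero
  effect difference yields an *undefined-ICER* signal rather than a number;
  dominance is flagged when cost and effect differences have opposite
  signs.
* The triangular sampler is inverse-CDF; reproducibility is by explicit
  seeds recorded in outputs.
* YAML round-trips are written at 12 significant digits — exact for every
  tabulated constant, ~1e-13 for derived fractions such as 1/3.

## Problem sizes

The shipped probabilistic analyses use 10,000 draws (each completing in
under a second via the vectorised evaluator). The test suite uses 200–2,000
draws for distributional checks, 1e5 draws for sampler moments, 2e5 for the
QALY Monte-Carlo cross-check, and 5 replicate synthetic trials at 1× and
10× the trial size for consistency checks; the full suite runs in well
under a minute.

## Limitations

* Cohort expectations only — no microsimulation, so no patient-level
  heterogeneity beyond the discrete types.
* One fortnight horizon for the incremental analyses; no discounting or
  half-cycle correction in the ≤ 6-cycle extension.
* No acceptability curves; no confidence interval on the baseline ICER
  beyond the PSA cloud.
* Unit costs are taken as given 2018–19 constants; their derivation from
  NHS reference-cost schedules is out of scope.
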