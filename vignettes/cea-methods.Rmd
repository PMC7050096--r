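---
title: "Methods: a Markov cohort cost-effectiveness model for PD-L1-guided pembrolizumab combination therapy in NSCLC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Markov cohort CEA for PD-L1-guided therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdl1cea)
```

This vignette records the model, its assumptions, the numerical choices,
and the places where the design was genuinely open — the information a
maintainer or reviewer needs to judge what a green test does and does
not establish.

## The decision problem

First-line treatment of metastatic nonsquamous non-small-cell lung
cancer without EGFR/ALK alterations. Pembrolizumab added to
pemetrexed-platinum chemotherapy prolongs progression-free and overall
survival but is expensive, and its benefit concentrates in patients
whose tumors express PD-L1. Three strategies are compared from a
public-payer perspective in the United States and China: chemotherapy
for all, combination for all, and PD-L1-test-guided therapy at a 1% or
50% tumor-proportion-score cutoff (prevalences 32.87% / 32.18% / 34.95%
for <1% / 1–49% / ≥50%). Decision statistics are the ICER against the
willingness-to-pay thresholds $100 000/QALY (US) and $27 351/QALY
(China, three times 2017 per-capita GDP), and net monetary benefit for
the acceptability curves.

## Survival model

Two parametric families, in the explicitly declared parameterization

* Weibull: \(S(t) = \exp(-(t/\sigma)^k)\)
* log-logistic: \(S(t) = 1/(1 + (t/\sigma)^k)\)

with shape \(k > 0\) dimensionless and scale \(\sigma > 0\) in months.
Months are mean Gregorian months (30.4375 days), so one 3-week model
cycle is \(21/30.4375 \approx 0.690\) months. The parameterization is
stated because rival conventions (rate vs scale, log-scale intercepts)
are a classic source of silent error; `survreg` fits are converted
explicitly in the tests.

Per-cycle transition probabilities are conditional survival ratios
\(p_j = 1 - S((j{+}1)\Delta)/S(j\Delta)\); when \(S\) has reached zero
the state absorbs (\(p = 1\)). Chained products of \(1-p_j\) reconstruct
\(S\) to 1e-9, which the tests assert.

## Digitized-curve reconstruction

Published Kaplan-Meier figures are the only survival evidence, so
curve preparation follows the pseudo-IPD approach: digitized
(time, survival) coordinates plus the numbers-at-risk row are converted
to interval event/censoring counts. Within each at-risk interval the
total censoring is assumed uniform over the digitized sub-intervals (the
standard assumption of this method family) and is solved in closed form
so that the implied number at risk matches the published count at the
interval end; event counts are chosen so the implied product-limit
curve matches the digitized probabilities at every sub-interval boundary
exactly (the self-consistency oracle in the tests). Counts are
fractional and the procedure is deterministic. Subjects still at risk at
the end of follow-up are carried as administrative tail censoring, so
events + censorings + tail = arm size.

Fitting maximizes the interval-censored likelihood — events contribute
\(S(t_j) - S(t_{j+1})\), censorings \(S(t_{j+1})\), the tail
\(S(t_{end})\) — over \((\log k, \log\sigma)\) by Nelder-Mead
(`reltol` 1e-12, 2000 iterations; non-convergence is an error carrying
the optimizer trace). This is deliberately a maximum-likelihood variant
rather than the least-squares regression sometimes used with this
reconstruction: it is the more standard estimator and is directly
checkable against `survival::survreg` on the same weighted
interval-censored rows, which the test suite does (agreement to 1e-3).
The r² between fitted and digitized survival is still reported for
validation parity, and family selection takes the higher r², with exact
ties broken toward Weibull (documented, tested). Arms and endpoints are
fitted independently; no shared-shape mode is imposed.

Two boundary conventions matter and are documented choices:

* digitized probabilities that rise slightly with time (digitization
  jitter) are clipped to a running minimum with a warning;
* the risk-set count at the very last observed time includes the
  subjects failing at that instant, which the survival probability has
  already removed, so the synthetic exporter does not place an at-risk
  time there; small negative implied censoring (< 0.5 subjects) from
  grid snapping is clamped silently, larger amounts warn.

## Cohort model

Three states (progression-free, progressed, dead) on 3-week cycles.
Occupancies come directly from the two curves:
\(occ_{PFS}(t) = S_{PFS}(t)\), \(occ_{Death}(t) = 1 - S_{OS}(t)\),
\(occ_{PD}(t)\) the remainder, clamped at zero with a logged count if
the curves cross. This partitioned-survival-consistent construction
reproduces the trial curves exactly by definition, which is the point of
fitting them; a transition-matrix formulation would add assumptions the
source figures cannot identify.

* **Horizon**: 20 years (348 cycles) by default — "lifetime" for this
  population; a convergence check warns if more than 0.5% of the cohort
  is still alive at the horizon (the illustrative ≥50% subgroup curve
  triggers it deliberately).
* **Discounting**: 3%/year, applied per cycle at cycle start,
  \((1.03)^{-t/12}\). Continuous vs per-cycle discounting was an open
  choice; per-cycle is used and flagged.
* **Accrual**: state-at-cycle-start (TreeAge-style), no half-cycle
  correction by default; a `half_cycle` flag averages adjacent
  occupancies for users who want it. QALYs accrue occupancy × utility ×
  cycle length in years; death accrues nothing.

## Costs

Per-cycle, per-state schedules assembled from the published input table
(China prices already converted at 6.7 CNY/USD):

* **Induction (cycles 1–4)**: pemetrexed 500 mg/m² plus platinum
  (50/50 carboplatin/cisplatin by default; the arm split was not
  published), plus pembrolizumab 200 mg flat in the combination arm.
  Carboplatin's AUC-5 dose needs a GFR the source never states; a fixed
  750 mg (Calvert with GFR 125 mL/min) is the default, configurable,
  and worth at most ~$50/cycle in the US.
* **Maintenance (cycle 5+)**: pemetrexed until progression, plus
  pembrolizumab up to 35 cycles (~24 months) in the combination arm.
* **China donation program**: eligible patients pay cycles 1–5, receive
  6–10 free, then alternate 3 paid / 3 donated until the 24-month stop;
  implemented as a 0/1 payable fraction on the pembrolizumab
  acquisition cost and kept active (stacking) in the −50% price
  scenario, with a flag to disable.
* **Adverse events**: grade ≥3 anemia, neutropenia, thrombocytopenia.
  The source prints management costs but not incidences; the trial
  publication's safety rates are shipped as clearly-non-source
  placeholders, and the incidence-weighted expected cost is spread
  uniformly over the four induction cycles.
* **Monitoring** accrues in on-treatment (PFS) cycles only. The PD-L1
  test is charged once per patient, at entry, in test strategies only.
* **Progressed disease**: the published proportions 54.2% (combination
  arm) / 56.5% (chemotherapy arm) receive subsequent therapy, the rest
  supportive care. Compositions are configurable mixtures; defaults are
  100% pembrolizumab crossover after chemotherapy (crossover was
  permitted) and 100% docetaxel after the combination. Checkpoint
  inhibitor subsequent therapy is capped at 35 cycles; because the
  cohort model has deliberately no tunnel states, the cap is applied on
  the overall model cycle index — an approximation that slightly
  front-loads eligibility and is the price of the three-state
  structure.
* **Premedication** enters as a single optional per-cycle add-on,
  default 0, since unit prices live outside the main source table.

Costs are homogeneous of degree one in prices (tested), and scenario
multipliers reproduce the base case bit-identically at 1.0.

One input-table inconsistency is preserved deliberately: the China
nivolumab subsequent-therapy row prints 2689 with range 21 518–32 278
(likely a misprinted 26 890). The printed point value ships; any
inconsistent range is replaced by ±20% when sensitivity specs are built,
with a warning.

## Strategies and economics

Arm evaluation composes the trace with the arm's cost schedule.
Test-guided strategies are prevalence-weighted mixtures of per-stratum
arm evaluations plus the one-time test cost; the test is assumed
perfectly accurate, matching the source's silence on operating
characteristics. Stratum-specific curves are used when supplied and fall
back to the overall arm curves otherwise.

The frontier implementation sorts by cost, removes strictly dominated
strategies (no cheaper-and-no-less-effective rival), then extendedly
dominated ones (sequential ICER exceeding the next step's; exact ties
are retained — the documented tie rule), and reports sequential ICERs,
which are then strictly non-decreasing by construction (tested, along
with a brute-force check that the max-NMB strategy at any threshold is
on the frontier). "Weak dominance" in the source's results tables shows
negative incremental cost with positive incremental QALYs, i.e. strict
dominance; both labels exist here and are reported separately.
Publication-style pairwise rows against chemotherapy and against the
combination are emitted alongside, with ICERs unrounded: the source's
printed ICERs divide unrounded internals, so printed-table comparisons
in the tests assert increments at printing precision, not ratios.

## Sensitivity analysis

* **One-way DSA** sets each parameter to its published range ends
  (95% CIs where given, else ±20%) with the rest at base; entries are
  ordered by ICER swing. At base values the DSA reproduces the base
  ICER bit-identically (tested). The qualitative finding that the
  progressed-disease utility is the dominant lever, with more
  cost-effectiveness as it rises, is asserted as a direction, not a
  magnitude.
* **PSA** draws all parameters independently per replicate:
  beta for utilities and proportions, gamma for costs and prices, by
  moment matching with the range read as a 95% interval
  (\(sd = (high-low)/3.92\); beta \(\alpha = m(m(1-m)/v - 1)\) etc.,
  infeasible beta variance clipped with a warning; degenerate ranges
  become point masses). Survival-curve shape/scale parameters enter as
  log-normals with ±20% ranges — the source says only that "transition
  probabilities" were beta-distributed without defining the map from
  curve parameters to probabilities, so this is an interpretation,
  stated as such. No correlation structure is imposed (none was given).
  1000 draws by default; a run is fully reproducible from its seed, and
  failing draws are excluded with a count. Sampled curve uncertainty
  applies to the overall arm curves; the illustrative subgroup curves
  are held fixed, a documented limitation.
* **CEAC**: at each WTP on a 0–200 000 grid (step 2 000), the
  probability each strategy maximizes NMB, ties split equally, rows
  summing to one (tested).

## Synthetic data

The generator exists so the whole pipeline runs and is testable without
any external data. Per arm it draws event times from stated PFS and OS
distributions using a **comonotone coupling** (one shared uniform
through both quantile functions). This was chosen over the additive
"OS = PFS + post-progression" construction because it preserves *both*
stated marginals exactly — the properties tested (KM median against the
OS closed form, round-trip parameter recovery) are statements about
marginals — while still guaranteeing per-subject PFS ≤ OS whenever the
OS curve dominates the PFS curve, which is validated on a grid at
construction. The price is perfect rank correlation between progression
and death times, which real trials do not show; nothing downstream uses
the joint ranks, so this does not affect what the tests establish.

Censoring emulates trial logistics: uniform enrolment over a window
(default 12 months), administrative cut at a fixed calendar time
(default 30–40 months in the tests), and with probability
`censor_prob` (default 0.1) an additional independent censoring time
uniform on the subject's follow-up — the "10% uniform censoring" style
of dropout. Trial-sized defaults follow the source trial's arms
(410 combination, 206 chemotherapy) in the acceptance script.

The exporter computes the Kaplan-Meier estimate (via `survival`), reads
it on an evenly spaced grid (default 30 points, like a manual
digitization), optionally jitters it, and tabulates numbers at risk at
grid-aligned times. What a green round-trip test establishes: the
reconstruction-plus-fit chain recovers known generating parameters
within 10% median relative error at n = 500. What it does not: accuracy
on real digitizations with plot-reading bias, non-uniform within-interval
censoring, or informative dropout.

### Example curves and subgroup calibration

The source's fitted parameters live in an unavailable supplement, so the
shipped curves match only its printed trial statistics: chemotherapy PFS
Weibull(1.2, σ from median 4.9 months), combination PFS Weibull(1.2,
σ from median 8.8), OS Weibull(1.1, σ from 12-month survival 49.4% /
69.2%). Shapes 1.1–1.2 encode the mildly increasing hazard typical of
metastatic NSCLC cohorts; they are stated once and not tuned.

Subgroup curves multiply the combination arm's scale parameters by
PFS factors (0.80, 0.80, 1.00) and OS factors (0.70, 1.00, 3.00) for
<1% / 1–49% / ≥50%. These are calibration devices, labelled
illustrative, chosen once so the configuration reproduces the published
*sign pattern* — each test-guided strategy costs less **and** yields
more QALYs than combination-for-all in both countries. The shape of the
calibration is informative about the economics: because maintenance
pemetrexed and monitoring accrue for every progression-free cycle,
costs grow steeply with PFS extension, so a benefit expressed mainly
through post-progression survival (cheap PD-state cycles, utility-
weighted QALY gains) is what lets a test strategy beat
combination-for-all on both axes, and China's thinner combination-vs-
chemotherapy cost gap additionally requires the 1–49% stratum to be no
costlier than the trial-average combination arm. Magnitude claims about
subgroups are therefore out of scope of every test; only orderings and
dominance labels are asserted.

## Numerical conventions

* Time unit months everywhere; cycle = 21/30.4375 months.
* Survival values clipped to [0, 1] against floating spill; S = 0 tails
  absorb.
* Fractional event/censor counts, no rounding anywhere in
  reconstruction.
* Optimizer: Nelder-Mead on log-parameters, median-based starting
  values.
* All randomness flows through explicit integer seeds; identical seeds
  give byte-identical PSA artifacts (tested).

## Known limitations

* No tunnel states: time-in-state-dependent costs (the subsequent-
  therapy cap) are approximated on model time.
* No vial rounding/wastage, indirect costs, or inflation adjustment.
* Perfect PD-L1 test accuracy; exactly three strata.
* PSA treats parameters as independent; curve uncertainty excludes the
  subgroup multipliers.
* The source's headline ICERs and CEAC probabilities are not
  reproducible without its unpublished fitted survival parameters; the
  package reproduces its arithmetic (incremental tables, dosing costs)
  exactly and its structure (dominance, monotonicities, scenario
  behaviour) as properties.
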