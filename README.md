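# pdl1cea

Cost-effectiveness analysis of first-line pembrolizumab plus chemotherapy
for metastatic nonsquamous non-small-cell lung cancer (NSCLC), with and
without PD-L1 testing to select who receives the combination — from the
United States and China public-payer perspectives.

The package is aimed at health-economics and HTA analysts who want the
whole modelling chain as tested, scriptable R functions rather than a
spreadsheet or a TreeAge file: survival-curve preparation, the cohort
model, the economics, and the uncertainty analyses.

## The model

Three first-line strategies are compared:

1. **Chemotherapy for all** (pemetrexed + carboplatin/cisplatin);
2. **Pembrolizumab + chemotherapy for all**;
3. **PD-L1 test-guided**: patients with tumor proportion score at or
   above a cutoff (1% or 50%) receive the combination, the rest
   chemotherapy. Stratum prevalences are 32.87% (<1%), 32.18% (1–49%)
   and 34.95% (≥50%).

Each arm is a three-state Markov cohort (progression-free `PFS`,
progressed `PD`, dead) on 3-week cycles over a 20-year lifetime horizon.
Occupancies are driven by parametric survival curves in the
partitioned-survival-consistent form

    occ_PFS(t) = S_PFS(t),  occ_Death(t) = 1 − S_OS(t),
    occ_PD(t)  = max(0, S_OS(t) − S_PFS(t)),

with Weibull `S(t) = exp(−(t/σ)^k)` or log-logistic
`S(t) = 1/(1+(t/σ)^k)` curves. Curves can be fitted from digitized
Kaplan-Meier coordinates plus numbers-at-risk via interval event-count
reconstruction (Hoyle–Henley style pseudo-IPD) and interval-censored
maximum likelihood, validated by an r² against the digitized points.

Costs cover drug acquisition with body-size dosing (BSA 1.84 m² / 71.4 kg
US; 1.72 m² / 65 kg China), 4 induction cycles then maintenance with a
35-cycle pembrolizumab cap, the Chinese charity donation schedule
(5 paid + 5 donated, then 3+3 until 24 months), monitoring, grade ≥3
adverse events, the PD-L1 test, and post-progression subsequent therapy
vs supportive care. Costs and QALYs are discounted at 3%/year. Outputs
are incremental cost-effectiveness ratios (ICER = ΔCost/ΔQALY) on a
strict/extended dominance frontier, net monetary benefit
(NMB = λ·QALY − Cost), one-way deterministic sensitivity analysis
(tornado), and probabilistic sensitivity analysis (beta-distributed
utilities/proportions, gamma-distributed costs, ~1000 draws) with
cost-effectiveness acceptability curves at willingness-to-pay thresholds
of $100 000/QALY (US) and $27 351/QALY (China).

The KEYNOTE-189 fitted curve parameters were never published, so the
shipped example curves are calibrated only to the trial's printed
summary statistics (median PFS 8.8 vs 4.9 months; 12-month OS 69.2% vs
49.4%) and the PD-L1-subgroup effects are illustrative; every cost,
utility, proportion and price is the published input table value.

## Worked example

```r
library(pdl1cea)
us  <- default_inputs("US")       # published Table-1 inputs, US payer
res <- run_cea(us)                # four strategies, frontier, scenarios
summary(res)
```

```
Cost-effectiveness analysis: US payer perspective
  horizon 20 years, discount 3%/yr, WTP $100 000/QALY

Strategy means and frontier:
                strategy   cost  qaly              comparator delta_cost delta_qaly   icer    status
            Chemotherapy 146004 0.714                    <NA>         NA         NA     NA  frontier
 PD-L1 test (50% cutoff) 238598 1.492            Chemotherapy      92594      0.778 119048  frontier
  PD-L1 test (1% cutoff) 276606 1.651 PD-L1 test (50% cutoff)      38007      0.159 238602  frontier
   Pembro + Chemotherapy 304539 1.242                    <NA>         NA         NA     NA dominated

Pairwise comparisons:
                strategy            comparator delta_cost delta_qaly   icer     label
   Pembro + Chemotherapy          Chemotherapy     158535      0.528 300440      <NA>
  PD-L1 test (1% cutoff)          Chemotherapy     130602      0.937 139370      <NA>
  PD-L1 test (1% cutoff) Pembro + Chemotherapy     -27933      0.409     NA Dominated
 PD-L1 test (50% cutoff)          Chemotherapy      92594      0.778 119048      <NA>
 PD-L1 test (50% cutoff) Pembro + Chemotherapy     -65940      0.250     NA Dominated

Price scenarios (combination vs chemotherapy):
  base case              dCost $  158535  dQALY 0.528  ICER $300440/QALY
  pembrolizumab -15%     dCost $  143747  dQALY 0.528  ICER $272416/QALY
  pembrolizumab -40%     dCost $  119101  dQALY 0.528  ICER $225710/QALY
```

Reading the output: giving everyone the combination costs $158 535 more
than chemotherapy per patient for 0.53 extra QALYs (ICER $300 440/QALY,
far above the $100 000 threshold), while both test-guided strategies
deliver more QALYs for less money than treating everyone — the
combination-for-all strategy is dominated. Pembrolizumab price cuts
shrink the incremental cost but never change the QALYs. These numbers
describe the illustrative curve set, not the trial; the structure
(dominance pattern, directions, scenario behaviour) is the tested
content.

Other entry points: `fit_parametric()` / `select_best_family()` on
reconstructed counts from `reconstruct_interval_counts()`;
`simulate_trial()` + `export_digitized()` for synthetic digitized
inputs; `run_cea(..., dsa = TRUE, psa_n = 1000)` for the sensitivity
analyses; `plot(res, "ceac")`, `plot(res, "tornado")`;
`write_cea_artifacts()` for CSV reports.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the whole pipeline from scratch: it simulates a two-arm trial
from the example curves, digitizes and reconstructs the Kaplan-Meier
inputs, refits both parametric families per endpoint, then runs the full
analysis (base case, dominance frontier, price-reduction scenarios,
one-way DSA, PSA with n = 1000 and acceptability curves) for both
countries, writing CSV artifacts under `results/runs/` and the JSON
manifest to `--out`.
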