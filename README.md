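# screencea

Cost-effectiveness analysis of annual screening mammography in a
low-income setting, implemented as a decision tree feeding a five-state
multistate Markov cohort model.

Breast cancer in Ethiopia is mostly diagnosed at late stage; screening
mammography shifts diagnoses toward earlier stages, where treatment is
cheaper and survival longer — but screening itself costs money at every
visit, and Ethiopia's willingness-to-pay ceiling (3 × GDP per capita,
≈2808.5 USD per life-year) is very low. This package asks whether annual
screening for women aged 40–49 and 50–59 can be cost-effective under four
provider-mix policies: screening delivered at government prices (4.5
USD/exam), private prices (42 USD/exam), or 50/50 and 90/10
government/private mixes. It is written for health economists and
epidemiologists who want a fully inspectable, testable implementation of
this class of model.

## The model

Per annual cycle, among `N_t` women still at risk with incidence `p`:

```
new cancers        = N_t · p
screen-detected    = N_t · p · Se          → favourable stage distribution
clinically detected= N_t · p · (1 − Se)    → clinical stage distribution
false positives    = N_t · (1 − p) · (1 − Sp)
```

Each diagnosed cohort then advances through a row-stochastic 5×5 Markov
chain over {remission, local recurrence, distant recurrence, cancer death,
other-cause death}, stage IV entering in the distant-recurrence state.
Costs (screening visits, FNAC work-up, one-time stage-specific treatment)
are discounted at 5%/year, life-years at 3%/year, over a 10-year horizon
for 100,000 women. Outputs are the standard decision metrics:

```
ICER = ΔC / ΔE          INMB = λ·ΔE − ΔC
NNS  = cohort / deaths averted        cost per death averted = ΔC / deaths averted
```

with one-way (tornado) sensitivity analysis (±20%, discount rates 0–6%)
and second-order Monte Carlo probabilistic sensitivity analysis
(Beta/Gamma/Dirichlet parameter distributions). An individual-level
microsimulation with the identical structure serves as a brute-force
oracle for the deterministic engine. See
`vignettes/screening-cea-methods.Rmd` for the full methods account.

## Worked example

```r
library(screencea)
cfg <- load_scenario(baseline_scenario_path())   # packaged baseline inputs
policy_table(cfg)
```

```
            policy age_group incremental_cost_usd     lyg icer_usd_per_lyg   inmb_usd            verdict
        government     40-49             10777076 2510.69          4292.48   -3725810 not_cost_effective
           private     40-49             41072226 2510.69         16358.96  -34020960 not_cost_effective
 mixed_50%_private     40-49             25924651 2510.69         10325.72  -18873385 not_cost_effective
 mixed_10%_private     40-49             13806591 2510.69          5499.13   -6755325 not_cost_effective
        government     50-59             10781397 3089.17          3490.06   -2105468 not_cost_effective
           private     50-59             41087468 3089.17         13300.50  -32411539 not_cost_effective
 mixed_50%_private     50-59             25934432 3089.17          8395.28  -17258503 not_cost_effective
 mixed_10%_private     50-59             13812004 3089.17          4471.11   -5136075 not_cost_effective
```

Reading the first row: screening 100,000 women aged 40–49 at government
prices for 10 years costs 10.78M USD more than no screening, buys 2,511
discounted life-years (80 breast-cancer deaths averted, ≈1,250 women
screened per death averted, ≈135k USD per death averted), i.e. 4,292 USD
per life-year gained — above the 2,808.5 USD threshold, so the incremental
net monetary benefit is negative (−3.73M USD) and the policy is not
cost-effective. The government-only policy is the cheapest per life-year
in both age bands; private-sector pricing roughly quadruples the ICER.

The numbered drivers under `analysis/` run the complete study:

```sh
Rscript analysis/01_baseline_policy_table.R   # Table: 4 policies × 2 age bands
Rscript analysis/02_tornado.R                 # one-way sensitivity (tornado) CSVs
Rscript analysis/03_psa.R                     # probabilistic sensitivity analysis
Rscript analysis/04_oracle_check.R            # cohort engine vs microsimulation
```

Each writes its tables under `results/`.

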