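---
title: "Methods: a Markov cohort model for mammography screening cost-effectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort model for mammography screening cost-effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screencea)
```

## The question and the model

`screencea` evaluates whether annual screening mammography is cost-effective
for Ethiopian women aged 40–49 and 50–59, under four provider-mix policies
(screening delivered at government prices, private prices, or 50/50 and
90/10 mixes). The structure is the standard two-part design of screening
cost-effectiveness analyses:

1. **A decision tree per annual cycle.** Among `N_t` women still at risk,
   `N_t × incidence` develop breast cancer. Mammography splits them into
   screen-detected true positives (probability = sensitivity) and false
   negatives, who present clinically in the same cycle; cancer-free women
   yield false positives at rate `1 − specificity`. Screen-detected cancers
   draw their stage at diagnosis from a favourable distribution
   (52/38/6/4% across stages I–IV, renormalized), clinically detected
   cancers from the much less favourable Ethiopian clinical distribution
   (10/19/57/14%). This *stage shift* is the model's only mechanism of
   screening benefit.
2. **A five-state Markov chain per diagnosed cohort.** States: remission,
   local recurrence, distant recurrence, breast-cancer death, other-cause
   death. Stages I–III enter in remission; stage IV disease is metastatic at
   diagnosis and enters in distant recurrence (the only state for which
   stage-IV rates exist). The chain is progression-only — no recurrence
   state returns to remission — and both death states are absorbing. Stages
   II and III share one published rate set but are tracked separately
   because their treatment prices differ.

Everything is expected-value (deterministic cohort) arithmetic: fractional
women are allowed, and outputs such as "78.55 deaths averted" are
expectations, not realisations. The comparator arm is the same cohort with
no screening: every case presents clinically, with the clinical stage
distribution, and incurs diagnosis (doctor visit + FNAC) and stage-specific
treatment costs. Incremental cost is the screened arm's discounted total
minus the comparator's.

## Parameters that matter

All inputs ship in `inst/extdata/ethiopia_baseline.yaml` with a provenance
table mapping each value to its upstream source. The load path validates
every invariant (probability ranges, row-sum feasibility, simplex stage
distributions, non-negative costs) and rejects unknown keys — a silent typo
in a transition-probability name would be catastrophic.

| parameter | default | units | note |
|---|---|---|---|
| annual incidence | 0.000878 / 0.00079 | per woman-year | 40–49 / 50–59 |
| sensitivity | 0.821 / 0.921 | probability | age-specific |
| specificity | 0.859 | probability | both bands |
| mammography price | 4.5 (gov) / 42 (private) | USD/exam | policy lever |
| doctor visit | 6 | USD | attaches per screen by default |
| FNAC | 22 | USD | diagnostic confirmation |
| treatment (I–IV) | 160 / 458.48 / 850.45 / 668.7 | USD/case | one-time at diagnosis |
| discounting | 5% costs, 3% life-years | annual | begin-of-cycle |
| WTP threshold | 2808.5 | USD/LY | 3 × GDP per capita |
| cohort, horizon | 100,000 women, 10 cycles | | 1-year cycles |

The printed stage distributions sum to 1.001 in both arms;
`normalize_stage_distribution()` rescales proportionally (the minimal
correction) and treats deviations beyond 5% as data errors rather than
rounding. Threshold variants 2808.9 and 2808 also circulate; the WTP is a
free parameter and 2808.5 is the default because it reproduces the
reference INMB values exactly.

## Design choices where the source material is silent

Several quantities any implementation needs are not published. Each has a
configurable flag, and the default is stated here as this package's choice:

* **Other-cause mortality** is structural (the state exists) but no rate is
  published; default 0 over the 10-year horizon (`other_cause_mortality`).
  For 40–59-year-old women over ten years this underestimates all-cause
  attrition slightly but affects both arms nearly symmetrically.
* **False-positive work-up** (`flags$include_fp_workup`, default `TRUE`):
  all suspected cases are charged FNAC, including the ~14,100 false
  positives per cycle at 85.9% specificity. This is the clinically coherent
  reading ("all women suspected incur the diagnostic cost"), and it is the
  single most consequential open choice: it adds ≈2.5M USD discounted to
  the government-policy incremental cost and makes *specificity* the
  dominant tornado bar. The alternative (`FALSE`) reproduces a
  price/sensitivity-led tornado and an incremental cost much closer to the
  reference government-policy total, which suggests the reference analysis
  did not charge it — but that cannot be established from the text, so the
  conservative default stands.
* **Doctor-visit attachment** (`flags$doctor_visit_per`): per screening
  encounter (default) or per positive only.
* **Discount timing** (`flags$discount_timing`): begin-of-cycle (default;
  the first screening round is paid at t = 0), no half-cycle correction.
* **At-risk depletion** (`flags$deplete_at_risk`): the pool shrinks by
  cumulative diagnoses (default); a fixed-pool variant reapplies incidence
  to the full cohort each year.
* **Life-years per death averted** (`flags$lyg_mode`): the published
  remaining-life expectancies (36.10 and 31.72 years for the 40–44 and
  45–49 sub-bands; nothing for 50–59) do not determine how life-years
  gained were computed — the implied ≈31.4 years per death averted for ages
  40–49 matches the *undiscounted* 45–49 expectancy despite the stated 3%
  effect discounting. The default is therefore a calibrated multiplier
  (31.3958 and 23.9052 years per death averted, the reference
  LYG-to-deaths-averted ratios), which makes every downstream ratio
  identity exact; `life_table` mode is the principled alternative, valuing
  each death averted at the discounted annuity of the band's mean remaining
  expectancy, `sum(min(1, L - t) / (1 + r)^t)`. Neither is asserted to be
  the reference method. `life_table` mode errors for 50–59, whose
  expectancy is unpublished, rather than inventing one.

## Policy blending

Provider mix only changes the mammography unit price, and every cost is
linear in unit prices, so a mixed policy's incremental cost is exactly the
share-weighted blend of the two pure policies, with life-years and deaths
averted unchanged. `blend_policies()` exploits this identity;
`run_policy_cea()` with an intermediate `private_share` runs the engine at
the blended unit price and agrees to floating precision (tested). The
reference 90/10 ICERs are reproduced by this blend arithmetic; the
reference 50/50 totals are internally inconsistent with it (they exceed the
mean of the pure policies by ≈0.2M USD) and are documented as such rather
than targeted.

## Sensitivity analyses

**One-way (tornado).** Every scalar parameter is swept to ±20% of base
(probabilities capped at 1.0 — a +20% perturbation of 92.1% sensitivity is
read as a perfect test), discount rates over the conventional 0–6% policy
range, with all else held at base; the output is the ICER span, reported
for *all* parameters (the plot, not the table, filters). One composite bar
varies the mammography price and doctor-visit fee jointly, since they form
a single out-of-pocket price per screening visit and move together under
any realistic price policy.

**Probabilistic (second-order Monte Carlo).** Per draw: probabilities from
Beta and costs/life-year multipliers from Gamma distributions, both
moment-matched to (base mean, CV); stage distributions from a Dirichlet
centred on the base simplex. The dispersion is *not* published; the default
CV is 0.1 per parameter (a common convention when no uncertainty intervals
are reported) and the Dirichlet total concentration is slaved to the same
dial as `100 × (0.1/CV)²`, so one parameter controls all families and the
CV → 0 limit degenerates every distribution onto the base case (verified to
0.1% at CV = 1e-4). Because the dispersion is an assumption, the PSA's
standard errors are illustrative, not reproductions of any published value.
Draws are reproducible from `(seed, draw_index)` alone; infeasible draws
(row sums exceeding 1) are rejected and redrawn with a reported count.
Default 10,000 iterations; the analysis driver uses 2,000 to stay
interactive, and the convergence test uses 100, which suffices at CV = 1e-4.

## Validation strategy

Three independent lines of evidence back the cohort engine:

* **Closed forms.** A deliberately tiny scenario (`toy_fixture()`: point
  mass on stage I, incidence 0.1, sensitivity 0.5, a two-step
  remission → distant → death path, two cycles, zero costs) has hand-computed
  expectations that the engine must hit exactly — e.g. 5 screen-detected
  cases in cycle 0 and half the cycle-0 cohort dead after two transitions.
* **Invariants.** Row-stochastic matrices to 1e-12; cohort mass conservation
  (occupancy = cumulative enrollment per stage) to 1e-9; monotonicity of
  deaths in death probabilities; discounting bounds; ICER×LYG and
  NNS×deaths identities; blend affinity; verdict monotonicity in the
  threshold — each property-tested over seeded random scenarios drawn
  ±50% around the baseline (probabilities truncated, simplex renormalized,
  infeasible draws rejected).
* **A brute-force oracle.** `microsim_cohort()` simulates individual women
  with Bernoulli/categorical draws through the *same* tree, stage
  distributions, costing rules and transition ordering, so any divergence
  beyond Monte Carlo noise isolates an engine bug. The suite compares 20
  random scenarios at n = 20,000 women on per-state person-cycle totals,
  cumulative cancer deaths, and undiscounted cost. Each comparison uses the
  mean of three independent replicates against the cohort expectation, with
  the pooled standard error `sqrt(mean(se²)/3)`: a single-replicate
  z-statistic is left-tail-inflated for states visited by few women,
  because an unlucky low draw drags its own empirical SE down with it.
  (This comparison caught a real bug during development: in-place state
  updates let a woman take two transitions in one cycle.)

The microsim emulates what the cohort engine models — it deliberately does
*not* add features of real screening data (detection delays and sojourn
times, age progression across bands, recall imaging, non-participation
clustering, overdiagnosis). Agreement therefore shows the deterministic
engine computes its stated expectations correctly, not that the model is an
accurate description of Ethiopian screening outcomes.

## Numerical notes

* Matrices are built with the residual on the diagonal so rows sum to
  exactly 1; a negative residual (rates + other-cause mortality > 1) is an
  error naming the offending row, not a silent clamp.
* ICER dominance cases are flags (`dominant`, `dominated`, `undefined`),
  never exceptions; `classify()` uses strict inequality ("less than 3 ×
  GDP per capita"), so an ICER exactly at the threshold is not
  cost-effective.
* Beta moment-matching near mean 0 or 1 can demand an infeasible variance;
  the CV is clamped to the moment bound with a warning. Parameters with
  base 0 (structurally absent transitions) stay 0 in every draw.
* Problem sizes used by the shipped tests and drivers: 20 oracle scenarios
  × 3 replicates × 20,000 women; 2,000 PSA iterations in the driver and 100
  in the convergence check. These sizes give Monte Carlo errors well inside
  the tolerances they are tested against.

## Worked example

```{r example, eval = FALSE}
cfg <- load_scenario(baseline_scenario_path())
policy_table(cfg)[, c("policy", "age_group", "icer_usd_per_lyg", "verdict")]
```

With the baseline inputs the government-only policy yields the lowest ICER
(≈4292 USD/LYG for ages 40–49, ≈3490 for 50–59 under the default flags) and
every policy exceeds the 2808.5 USD threshold — screening is not
cost-effective at Ethiopian prices and GDP, and the INMB is negative
throughout. The qualitative conclusion is robust across every flag
combination; the exact incremental cost moves by up to ≈25% with the
false-positive work-up flag, which is why that flag is the headline
limitation.

## Known limitations

* No tunnel states, no time-varying rates, no age progression mid-run, no
  half-cycle correction, no overdiagnosis, no QALY weighting, and no
  CEAC/EVPI machinery beyond the probability of cost-effectiveness at a
  configurable threshold.
* Other-cause mortality defaults to zero; over a 10-year horizon in this
  age range the bias is small and nearly symmetric across arms, but
  absolute occupancy figures should not be read as survival projections.
* The calibrated LYG multipliers tie life-year outputs to the reference
  ratios by construction; use `life_table` mode for an independent (and
  more conservative, discounted) valuation.
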