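# nutricea

Trial-based cost-effectiveness analysis of a maternal nutrition education
intervention for early-childhood cognitive development.

## What this package is for

A cluster-randomized controlled trial in rural Uganda taught mothers of
6–8-month-old children about nutrition, hygiene and child stimulation, and
measured child development with the Bayley Scales of Infant and Toddler
Development (BSID-III) up to age 20–24 months. The intervention raised the
cognitive composite score substantially; the question for policymakers is
whether that gain is worth the cost of delivering the program at scale.

`nutricea` implements the full economic evaluation of that question from a
healthcare-provider perspective, for analysts who want to reproduce,
stress-test or adapt a trial-based cost-effectiveness analysis:

- **Cost ledger** — load an itemized intervention cost table (2014 USD),
  aggregate it into the four expenditure categories (personnel, materials
  and other, capacity building, capital) and into per-child costs.
- **Incremental effect** — estimate the intervention effect on the
  cognitive composite score as a difference-in-differences (DiD) linear
  mixed model, or adopt a published estimate directly.
- **Deterministic cost-effectiveness** — incremental cost-effectiveness
  ratio (ICER), net monetary benefit, cost-effectiveness-plane quadrants,
  and DALY-weight break-even thresholds.
- **Uncertainty** — one-way (tornado) sensitivity analysis, Monte Carlo
  probabilistic sensitivity analysis (PSA) and the cost-effectiveness
  acceptability curve (CEAC).
- **Synthetic trial generator** — cluster-randomized longitudinal data
  with village-level clustering and missing-completely-at-random
  attrition, so the statistical machinery is testable end to end without
  the (undeposited) raw trial data.

## The model

With incremental cost per child ΔC (intervention cost averaged over the
intervention-arm completers; the comparator, current practice, is assumed
to add zero cost) and incremental effect ΔE (the group×time interaction
coefficient of a linear mixed model with random intercepts for village and
for child nested in village):

    ICER = ΔC / ΔE                    (USD per cognitive composite score unit)
    NMB(λ) = λ·ΔE − ΔC                (net monetary benefit at willingness-to-pay λ)
    CEAC(λ) = Pr( NMB(λ) > 0 )        (over Monte Carlo parameter draws)

The PSA draws ΔE from Normal(point estimate, SE) and scales each per-child
cost category by an independent uniform multiplier matching the one-way
sensitivity ranges (personnel 0.5–1.2; the others 0.8–1.2).

## Worked example

```r
library(nutricea)

ledger <- read_cost_ledger(
  system.file("extdata", "chnudev_costs.csv", package = "nutricea")
)
costs <- summarize_costs(ledger, n_children = 227, total_override = 60335)
costs
#> Intervention cost summary (2014 USD)
#>            category total share_pct per_child
#> 1         personnel 46485      77.0    204.78
#> 2   materials_other 11496      19.1     50.64
#> 3 capacity_building  1822       3.0      8.03
#> 4           capital   533       0.9      2.35
#> Total: $60335.00 over 227 children -> $265.79 per child

effect <- effect_estimate(16.11, ci_low = 11.72, ci_high = 20.50)
icer(costs$per_child_total, effect$point)
#> Incremental cost $265.79, incremental effect 16.11 (quadrant NE)
#> ICER: $16.50 per cognitive composite score unit

psa <- run_psa(costs, effect, n_samples = 1000, seed = 20140101)
psa
#> Probabilistic sensitivity analysis: 1000 draws (seed 20140101)
#> Mean ICER (per-sample ratios): $14.82 (95% interval $9.20 to $21.90)
#> Ratio of means: $14.52
#> Quadrant counts: NE 1000, SE 0, NW 0, SW 0

ceac(psa, c(8, 16.5, 24))
#>    wtp probability
#> 1  8.0       0.005
#> 2 16.5       0.695
#> 3 24.0       0.996
```

Reading the output: the program cost $265.79 per child and bought 16.11
cognitive composite score units per child, i.e. $16.50 per unit gained. At
a willingness to pay of $8 per unit the intervention is almost never
cost-effective, at $16.50 it is cost-effective in about 70% of parameter
draws, and at $24 almost always. Every draw lands in the north-east
quadrant: more costly and more effective than current practice.

The full pipeline (costs → effect → deterministic CEA → tornado → PSA →
CEAC → CSV/JSON reports) runs from a YAML configuration:

```r
bundle <- run_pipeline(
  system.file("extdata", "base_case.yaml", package = "nutricea"),
  output_dir = "results"
)
```

A synthetic trial with the design's sample sizes, clustering and attrition,
and the DiD mixed-model fit on it:

```r
d <- simulate_trial(synthetic_config(seed = 7))
fit_did_model(d)
```

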