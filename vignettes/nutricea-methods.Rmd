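---
title: "Methods: trial-based cost-effectiveness of a nutrition education intervention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based cost-effectiveness of a nutrition education intervention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutricea)
```

## The evaluation in one paragraph

A maternal nutrition education program delivered in a two-arm
cluster-randomized trial improved the BSID-III cognitive composite score
of children followed from age 6–8 to 20–24 months. `nutricea` evaluates
whether that gain justifies the program's cost, from a healthcare-provider
perspective over the 18-month trial horizon: the incremental cost per
child ΔC comes from an itemized cost ledger, the incremental effect ΔE
from a difference-in-differences (DiD) linear mixed model, and their ratio
is the incremental cost-effectiveness ratio (ICER). Parameter uncertainty
is propagated by one-way sensitivity analysis and by Monte Carlo
simulation, summarized as a cost-effectiveness plane and an acceptability
curve. No discounting is applied at this horizon, and exactly two
strategies are compared (intervention vs current practice).

## Cost model

Costs are recorded in 2014 USD (a fixed display rate of 2,523 Uganda
shillings per dollar is exported as `UGX_PER_USD`) in four categories:
personnel, materials and other variable costs, capacity building
(training), and capital/facilities. Each ledger row carries either a
direct amount or a unit cost and quantity whose product is the amount; an
optional `attributable_fraction` column scales items shared with the
comparator arm (default 1 — the packaged ledger already holds
intervention-attributable amounts). Monetary arithmetic is done at full
floating precision; rounding to cents happens only in reports.

The incremental cost per child is the category total divided by the number
of intervention-arm completers, under the assumption that current practice
adds no cost of its own — so the comparator's trial costs are never
micro-costed.

Two reporting conventions deserve a note:

- **The pinned total.** The four category subtotals in the packaged ledger
  sum to $60,336, while the published grand total is $60,335 — an artifact
  of independently rounded subtotals. The ledger is authoritative for
  category-level arithmetic; `summarize_costs(..., total_override =)`
  lets an analysis pin the published total so both printed figures are
  reproduced exactly. Either convention yields the same ICER at two
  decimals.
- **Multipliers on a pinned total.** `apply_multipliers()` adjusts the
  stored total by each category's change (rather than recomputing it as
  the category sum), so an all-ones multiplier map is an exact identity
  even on a summary with an overridden total, and scaling stays linear per
  category.

## Incremental effect: the DiD mixed model

The effect of the intervention is the coefficient of the group×time
interaction (group: control = 0, intervention = 1; time: baseline = 0,
final follow-up = 1) in

```
cognitive_score ~ group * time + covariates
                  + (1 | village) + (1 | village:child)
```

fitted by REML via `lme4::lmer`, with the normal-theory (Wald) interval on
the interaction coefficient. Design choices, each of which the package
exposes rather than hard-codes:

- **Nesting.** Children belong to villages, so the child intercept is
  nested within the village intercept. Villages are the randomization
  unit; the fit refuses designs with fewer than two villages per arm.
- **Waves.** Only baseline and final waves enter the fit; the middle wave
  (child age 12–16 months) is descriptive. The analysis is restricted to
  completers — children observed at both waves — matching how the trial's
  effectiveness figures were computed.
- **Covariates.** Baseline covariates may be added as fixed effects
  (character columns become factor indicator contrasts). The default is
  none: in the trial analysis no baseline characteristic was a significant
  predictor, and on synthetic data (where covariates are generated
  independently of the score) adjustment only widens the design matrix.
- **REML vs ML.** REML is the default; at this design size (about 850
  observations, 20 clusters) the two agree to well under a tenth of a
  score unit, and a test asserts that insensitivity.
- **Degenerate data.** With zero residual noise the mixed model is
  unidentified. The fit detects this through the OLS residual scale
  (σ < 1e-6) and returns the exact OLS interaction coefficient with zero
  SE — the only setting in which a zero SE is produced.
- **Optimizer.** `bobyqa`, with the convergence-gradient check relaxed to
  a tolerance of 0.02. The default check flags spurious non-convergence on
  a small share of replicate fits whose estimates are numerically
  indistinguishable from converged ones; genuine failures still error.

When raw trial records are unavailable, a published estimate can stand in:
`effect_estimate(point, ci_low =, ci_high =)` reconstructs the SE from the
interval as `(ci_high − ci_low) / (2 z)`, and the economics half of the
pipeline runs unchanged.

Baseline balance is summarized the way trial reports do: chi-square tests
for categorical covariates (without continuity correction, which matches
the printed p-values for 2×2 tables at these sample sizes) and two-sample
t-tests for numerical ones, flagged at p < 0.05; a categorical table with
a zero expected cell reports "not applicable" rather than a p-value.

## Deterministic cost-effectiveness

`icer()` classifies (ΔE, ΔC) on the cost-effectiveness plane and reports
the ratio only where it is decision-relevant: in the north-east quadrant
(more costly, more effective) and the south-west (cheaper, less
effective, read as savings per unit forgone). Cheaper-and-better is
flagged *dominant*, costlier-and-worse *dominated*; ΔE = 0 with positive
cost is dominated with an infinite ICER. The base case never leaves the
NE quadrant, but Monte Carlo draws could, so the conventions matter for
the PSA bookkeeping.

`nmb(ΔC, ΔE, λ) = λ·ΔE − ΔC` is the decision rule behind the
acceptability curve, and `nmb(ΔC, ΔE, icer(ΔC, ΔE)) = 0` holds as an
algebraic identity for NE pairs.

`daly_weight_threshold()` translates the score-based result into generic
health units: the smallest avoided-disability weight w at which cost per
DALY averted stays under a willingness-to-pay threshold is
`w* = ΔC / (wtp_per_daly × duration)`. Both the per-DALY threshold
(e.g. 1× or 3× GDP per capita) and the duration of the cognitive benefit
are explicit parameters, because neither is knowable from the trial; the
function is exact in its inputs and deliberately refuses to guess them.

## Uncertainty analysis

**One-way (tornado).** Each parameter moves to its low and high bound with
the others at reference: personnel costs from −50% to +20% (personnel is
the dominant category and its unit cost is expected to fall as delivery
scales), the other three categories ±20%, and the effect to its 95%
confidence bounds. Entries are sorted by ICER span, ties broken
alphabetically, and a parameter held at reference reproduces the base ICER
exactly.

**Probabilistic (PSA).** 1000 independent draws by default: the effect
from Normal(point, SE) and each per-child cost category scaled by an
independent Uniform over its one-way range. Per draw the incremental cost
is the sum of sampled categories and the pair is classified by quadrant.
Because the effect distribution sits more than seven SEs above zero,
draws with non-positive effect are essentially impossible at the base
case; when they do occur (wider inputs), they are excluded from ICER
summaries — a ratio across quadrants is meaningless — but retained in the
samples, the quadrant counts and the acceptability curve, and their count
is reported.

**Which "mean ICER"?** The mean of per-sample ratios and the ratio of mean
increments differ by roughly 2% here (the ratio is convex in ΔE), and
simulation reports rarely say which they used. `run_psa` reports both
(`mean_icer`, `icer_ratio_of_means`), with the 2.5–97.5 percentile
interval of per-sample ratios as the simulation interval.

**CEAC.** At each willingness-to-pay λ the curve is the share of draws
with strictly positive net monetary benefit. The strict inequality makes
the boundary well defined: under degenerate (zero-width) distributions the
curve evaluated exactly at the ICER is 0, and an infinitesimal step above
it is 1. When every sampled effect is positive the curve is non-decreasing
in λ and tends to 1. The default grid is $0–30 in steps of $0.50.

The test suite checks the Monte Carlo curve against an independent
analytic oracle — `P(λE − C > 0)` computed by numerical convolution of the
four uniform cost densities against the normal effect — at λ ∈ {8, 16.50,
24}, within three Monte Carlo standard errors.

## The synthetic trial generator

Because the trial's raw records are not deposited, the generator produces
data with the statistical structure the analysis assumes, so that every
downstream stage is testable and the mixed model's parameter recovery can
be demonstrated:

```
score(child, wave) = mean(arm, wave) + u_village + u_child + e
u_village ~ N(0, sd_village²), u_child ~ N(0, sd_individual²), e ~ N(0, sd_residual²)
```

Defaults mirror the trial design: 263/248 dyads enrolled across 20
villages (10 per arm), 227/196 retained; baseline means 102.37/103.42
with overall SD 13; control-arm drift −4.05 between baseline and the
final wave; and a true DiD contrast of 16.11, so the final-wave
intervention mean is fixed at whatever makes the four-cell contrast equal
the true effect exactly. The mid wave (means 110.50/103.31) exists for
descriptive plots only. Covariates are drawn independently from the
published baseline marginals and, by default, do not enter the score
model — consistent with the trial's finding that no baseline covariate
was a significant predictor. Attrition is completely at random within
arm: dropped children keep only their baseline record.

Calibration choices, made once:

- **Cluster count.** The trial does not report its number of villages; 20
  (10 per arm) is a plausible size for a two-district pragmatic cluster
  trial and is configurable. The DiD interaction is a within-child
  contrast in which village intercepts cancel, so its SE is driven by the
  residual component rather than the cluster count.
- **Variance decomposition.** The components must satisfy
  `sd_village² + sd_individual² + sd_residual² = 13²` to reproduce the
  observed cross-sectional SD; the defaults (3, 8.5, √87.75) put a modest
  intra-cluster correlation (~0.05) at the village level and about half
  the variance in the stable child intercept. Under this constraint the
  implied interaction SE — `sd_residual · √(2(1/227 + 1/196))` ≈ 0.14 ×
  sd_residual — cannot exceed about 1.8 and sits near 1.3 at the
  defaults, below the trial's published SE of ≈2.24. The two cannot be
  matched simultaneously: the trial's larger SE reflects features the
  generator deliberately omits (covariate adjustment on real data,
  possibly greater follow-up variance or informative dropout). The
  generator privileges the observable quantity (the cross-sectional SD);
  recovery and coverage tests are unaffected because the model estimates
  its own SE.
- **What passing tests do and do not show.** Unbiased recovery and
  nominal coverage on this generator validate the estimation machinery
  under the assumed structure — normal components, MCAR dropout,
  covariates independent of outcome. They do not validate those
  assumptions for the real trial, where dropout may be informative and
  score distributions are bounded and discretized.

## Problem sizes and numerical conventions

The replication loops use 200 synthetic datasets for recovery/coverage
and 1000 Monte Carlo draws for the PSA — the same sizes the analysis
itself uses — and each loop derives its seeds deterministically from a
single user seed; identical configurations are byte-identical in their
tabular outputs. The convolution oracle uses a grid step of $0.01, small
relative to every cost width. ICERs are computed at full precision and
rounded to two decimals only in reports (`report_rounding`).

## Limitations

- The cost ledger ships as category subtotals plus item-level structure,
  not the full internal item list of the original costing exercise.
- Healthcare-provider perspective only; no societal costs, no
  inflation adjustment, and no discounting (18-month horizon).
- No multiple imputation or inverse-probability weighting for dropout,
  and no small-sample (Kenward–Roger) corrections; the Wald interval is
  adequate at this size but would be optimistic with few clusters and a
  cluster-level estimand.
- No EVPI, correlated parameter sampling, or multi-comparator frontier.
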