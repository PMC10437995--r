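# Base-case configuration for the trial-based cost-effectiveness analysis.
# Costs: the packaged category-subtotal ledger, averaged over the 227
# intervention-arm completers, with the published grand total pinned.
# Effect: the published incremental cognitive composite score estimate.
ledger_path: chnudev_costs.csv
n_children_denominator: 227
total_override: 60335
effect:
  point: 16.11
  ci_low: 11.72
  ci_high: 20.50
  ci_level: 0.95
psa:
  n_samples: 1000
  seed: 20140101
wtp_grid:
  from: 0
  to: 30
  by: 0.5
report_rounding: 2
figures: false
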