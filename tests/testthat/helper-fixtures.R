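# Shared fixtures, built in code.

# Published category subtotals (2014 USD) and analysis constants.
published <- list(
  personnel = 46485, materials_other = 11496,
  capacity_building = 1822, capital = 533,
  total = 60335, n_children = 227,
  effect_point = 16.11, effect_ci = c(11.72, 20.50)
)

packaged_ledger_path <- function() {
  system.file("extdata", "chnudev_costs.csv", package = "nutricea")
}

base_cost_summary <- function(total_override = NULL) {
  summarize_costs(
    read_cost_ledger(packaged_ledger_path()),
    n_children = published$n_children,
    total_override = total_override
  )
}

published_effect <- function() {
  effect_estimate(
    published$effect_point,
    ci_low = published$effect_ci[1], ci_high = published$effect_ci[2]
  )
}

# Write a ledger CSV from a data frame of rows and return its path.
write_ledger <- function(rows) {
  path <- tempfile(fileext = ".csv")
  write.csv(rows, path, row.names = FALSE, na = "")
  path
}

# Minimal long-format trial records from vectors.
make_records <- function(child_id, village_id, arm, wave, score, ...) {
  data.frame(
    child_id = child_id, village_id = village_id, arm = arm, wave = wave,
    cognitive_score = score, ..., stringsAsFactors = FALSE
  )
}

# A small two-arm, two-wave, multi-village dataset with exact cell means
# and no noise: each arm has two villages with two children each.
noise_free_records <- function(mean_int_base = 102.37, mean_ctl_base = 103.42,
                               mean_int_final = 114.43, mean_ctl_final = 99.37) {
  grid <- expand.grid(
    child = 1:4, arm = c("intervention", "control"),
    wave = c("baseline", "final"),
    stringsAsFactors = FALSE
  )
  grid$child_id <- paste0(substr(grid$arm, 1, 3), grid$child)
  grid$village_id <- paste0(substr(grid$arm, 1, 3), "_v", (grid$child - 1) %/% 2 + 1)
  means <- list(
    intervention = c(baseline = mean_int_base, final = mean_int_final),
    control = c(baseline = mean_ctl_base, final = mean_ctl_final)
  )
  grid$cognitive_score <- mapply(
    function(a, w) means[[a]][w], grid$arm, grid$wave
  )
  make_records(grid$child_id, grid$village_id, grid$arm, grid$wave,
               grid$cognitive_score)
}
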