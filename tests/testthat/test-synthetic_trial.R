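test_that("config validation rejects impossible designs", {
  expect_error(synthetic_config(retained_intervention = 300), "retained")
  expect_error(synthetic_config(n_villages = 1), "villages")
  expect_error(synthetic_config(sd_village = -1), "non-negative")
  cfg <- synthetic_config()
  expect_equal(
    cfg$sd_village^2 + cfg$sd_individual^2 + cfg$sd_residual^2,
    cfg$baseline_sd^2,
    tolerance = 0.01
  )
})

test_that("the enrolled cohort matches the trial design", {
  d <- generate_trial(synthetic_config(seed = 42))
  expect_equal(length(unique(d$child_id)), 511)
  expect_equal(length(unique(d$child_id[d$arm == "intervention"])), 263)
  expect_equal(length(unique(d$child_id[d$arm == "control"])), 248)
  expect_equal(length(unique(d$village_id)), 20)
  # structural invariants
  expect_false(any(duplicated(d[, c("child_id", "wave")])))
  expect_true(all(tapply(d$village_id, d$child_id,
                         function(v) length(unique(v))) == 1))
  expect_true(all(tapply(d$arm, d$village_id,
                         function(a) length(unique(a))) == 1))
  for (v in c("child_sex", "dietary_diversity", "maternal_age_years")) {
    expect_true(all(tapply(d[[v]], d$child_id,
                           function(x) length(unique(x))) == 1))
  }
  expect_true(all(is.finite(d$cognitive_score)))
})

test_that("attrition keeps the published completer counts, MCAR", {
  cfg <- synthetic_config(seed = 9)
  d <- apply_attrition(generate_trial(cfg), cfg)
  finals <- d[d$wave == "final", ]
  expect_equal(nrow(finals), 423)
  expect_equal(sum(finals$arm == "intervention"), 227)
  expect_equal(sum(finals$arm == "control"), 196)
  # dropped children keep only their baseline record
  dropped <- setdiff(unique(d$child_id), finals$child_id)
  expect_true(all(d$wave[d$child_id %in% dropped] == "baseline"))

  none <- synthetic_config(
    retained_intervention = 263, retained_control = 248, seed = 9
  )
  full <- apply_attrition(generate_trial(none), none)
  expect_equal(nrow(full), 511 * 3)

  one <- synthetic_config(retained_intervention = 1, seed = 9)
  d1 <- apply_attrition(generate_trial(one), one)
  expect_equal(sum(d1$wave == "final" & d1$arm == "intervention"), 1)
})

test_that("generation is deterministic given the config and seed", {
  a <- simulate_trial(synthetic_config(seed = 123))
  b <- simulate_trial(synthetic_config(seed = 123))
  expect_identical(a, b)
  c <- simulate_trial(synthetic_config(seed = 124))
  expect_false(identical(a, c))
  # and leaves the caller's RNG stream untouched
  set.seed(77); before <- rnorm(1)
  set.seed(77); invisible(simulate_trial(synthetic_config(seed = 5)))
  expect_identical(rnorm(1), before)
})

test_that("noise-free generation hits the cell means exactly", {
  cfg <- synthetic_config(
    sd_village = 0, sd_individual = 0, sd_residual = 0, seed = 1
  )
  d <- generate_trial(cfg)
  m <- group_wave_means(d, completers_only = FALSE)
  get <- function(a, w) m$mean_score[m$arm == a & m$wave == w]
  expect_equal(get("intervention", "baseline"), 102.37)
  expect_equal(get("control", "baseline"), 103.42)
  expect_equal(get("control", "final"), 103.42 - 4.05)
  did <- (get("intervention", "final") - get("intervention", "baseline")) -
    (get("control", "final") - get("control", "baseline"))
  expect_equal(did, 16.11, tolerance = 1e-12)
})

test_that("baseline means land near their targets over seeds", {
  # the SD of an arm's baseline mean under clustering:
  # village variance shrinks with the number of villages, the rest with n
  cfg <- synthetic_config()
  sd_mean <- function(n) sqrt(
    cfg$sd_village^2 / 10 + (cfg$sd_individual^2 + cfg$sd_residual^2) / n
  )
  for (seed in c(2, 31, 57)) {
    d <- generate_trial(synthetic_config(seed = seed))
    ctl <- d$cognitive_score[d$arm == "control" & d$wave == "baseline"]
    expect_lt(abs(mean(ctl) - 103.42), 3 * sd_mean(248))
    int <- d$cognitive_score[d$arm == "intervention" & d$wave == "baseline"]
    expect_lt(abs(mean(int) - 102.37), 3 * sd_mean(263))
  }
})

test_that("village intercepts induce intra-cluster correlation", {
  icc_hat <- function(sd_village) {
    cfg <- synthetic_config(
      seed = 8, sd_village = sd_village,
      sd_individual = 6, sd_residual = 6
    )
    d <- generate_trial(cfg)
    b <- d[d$wave == "baseline", ]
    fit <- suppressMessages(lme4::lmer(
      cognitive_score ~ arm + (1 | village_id), data = b,
      control = lme4::lmerControl(optimizer = "bobyqa")
    ))
    vc <- as.data.frame(lme4::VarCorr(fit))
    v_village <- vc$vcov[vc$grp == "village_id"]
    v_village / sum(vc$vcov)
  }
  expect_gt(icc_hat(6), 0.1)
  expect_lt(icc_hat(0), 0.05)
})

test_that("covariate marginals follow the published baseline table", {
  d <- generate_trial(synthetic_config(seed = 14))
  b <- d[d$wave == "baseline" & d$arm == "intervention", ]
  expect_lt(abs(mean(b$child_sex == "male") - 0.529), 3 * 0.5 / sqrt(263))
  expect_lt(abs(mean(b$dietary_diversity == "low") - 0.567),
            3 * 0.5 / sqrt(263))
  expect_lt(abs(mean(b$maternal_education_years) - 4.85),
            3 * 2.82 / sqrt(263))
})
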