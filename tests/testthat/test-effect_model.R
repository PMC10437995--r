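test_that("se_from_ci inverts the normal-theory interval", {
  expect_equal(se_from_ci(11.72, 20.50, 0.95), 2.2398, tolerance = 1e-4)
  expect_equal(se_from_ci(-1.96, 1.96, 0.95), 1.0, tolerance = 1e-3)
  expect_error(se_from_ci(0, 0, 0.95), "exceed")
  expect_error(se_from_ci(0, 1, 1.5), "level")
  # round trip: building a CI from (point, se, level) and inverting it
  # recovers the se
  set.seed(3)
  for (i in 1:20) {
    point <- rnorm(1, 10, 5); se <- runif(1, 0.1, 4)
    level <- runif(1, 0.5, 0.99)
    z <- qnorm((1 + level) / 2)
    expect_equal(
      se_from_ci(point - z * se, point + z * se, level), se,
      tolerance = 1e-10
    )
  }
})

test_that("effect_estimate derives missing pieces and validates", {
  e <- effect_estimate(16.11, ci_low = 11.72, ci_high = 20.50)
  expect_equal(e$se, 2.2398, tolerance = 1e-4)
  e2 <- effect_estimate(16.11, se = 2.2398)
  expect_equal(e2$ci_low, 11.72, tolerance = 1e-3)
  expect_equal(e2$ci_high, 20.50, tolerance = 1e-3)
  expect_error(effect_estimate(30, ci_low = 11.72, ci_high = 20.50), "inside")
  expect_error(effect_estimate(1, se = 1, ci_level = 2), "ci_level")
})

test_that("noise-free data recover the generating contrast exactly", {
  cfg <- synthetic_config(
    sd_village = 0, sd_individual = 0, sd_residual = 0, seed = 1
  )
  est <- fit_did_model(simulate_trial(cfg))
  expect_equal(est$point, 16.11, tolerance = 1e-9)
  expect_equal(est$se, 0)
  expect_equal(est$n_intervention, 227)
  expect_equal(est$n_control, 196)

  flat <- noise_free_records(100, 100, 100, 100)
  expect_equal(fit_did_model(flat)$point, 0, tolerance = 1e-9)
})

test_that("the DiD coefficient ignores level and arm shifts", {
  d <- simulate_trial(synthetic_config(seed = 21))
  ref <- fit_did_model(d)$point
  shifted <- d
  shifted$cognitive_score <- shifted$cognitive_score + 50
  expect_equal(fit_did_model(shifted)$point, ref, tolerance = 1e-6)
  armshift <- d
  armshift$cognitive_score <- armshift$cognitive_score +
    ifelse(armshift$arm == "intervention", 12, 0)
  expect_equal(fit_did_model(armshift)$point, ref, tolerance = 1e-6)
})

test_that("REML and ML estimates agree at this design size", {
  d <- simulate_trial(synthetic_config(seed = 33))
  a <- fit_did_model(d, reml = TRUE)
  b <- fit_did_model(d, reml = FALSE)
  expect_equal(a$point, b$point, tolerance = 0.05)
  expect_equal(a$se, b$se, tolerance = 0.05)
})

test_that("covariate adjustment leaves the estimate essentially unchanged", {
  d <- simulate_trial(synthetic_config(seed = 44))
  plain <- fit_did_model(d)
  adj <- fit_did_model(d, covariates = c(
    "child_sex", "breastfeeding", "dietary_diversity", "child_age_months",
    "maternal_education_years", "maternal_age_years", "household_size",
    "poverty_score"
  ))
  expect_equal(adj$point, plain$point, tolerance = 0.5)
  expect_error(fit_did_model(d, covariates = "no_such_column"), "no_such")
})

test_that("design errors are reported for unusable inputs", {
  d <- simulate_trial(synthetic_config(seed = 2))
  one_village <- d[d$village_id %in% c("int_v01", "ctl_v01"), ]
  expect_error(fit_did_model(one_village), "2 villages")
  expect_error(fit_did_model(d[0, ]), "missing column|completer|villages")
  expect_error(fit_did_model(data.frame(x = 1)), "missing column")
})

test_that("group means restrict to completers and report empty cells", {
  rec <- noise_free_records()
  m <- group_wave_means(rec)
  expect_equal(
    m$mean_score[m$arm == "intervention" & m$wave == "final"], 114.43
  )
  single <- make_records("c1", "v1", "intervention", "final", 88)
  ms <- group_wave_means(single)
  expect_equal(ms$mean_score[ms$arm == "intervention" & ms$wave == "final"], 88)
  expect_true(is.na(ms$mean_score[ms$arm == "control" & ms$wave == "final"]))
  # non-completers are excluded from the wave means
  extra <- rbind(rec, make_records("drop1", "int_v1", "intervention",
                                   "baseline", 1000))
  expect_equal(group_wave_means(extra), m)
  expect_error(group_wave_means(rec[0, ]), "no records")
})

test_that("baseline balance applies the test matching the variable kind", {
  # child sex counts from the published baseline table
  sex <- c(rep("male", 139), rep("female", 124), rep("male", 123),
           rep("female", 125))
  arm <- c(rep("intervention", 263), rep("control", 248))
  rec <- make_records(
    child_id = paste0("c", 1:511), village_id = "v1", arm = arm,
    wave = "baseline", score = 100, child_sex = sex
  )
  bal <- baseline_balance(rec, variables = "child_sex")
  expect_equal(bal$test, "chi_square")
  expect_equal(bal$p_value, 0.462, tolerance = 0.005)
  expect_false(bal$significant)

  # identical numeric distributions give t-test p-value 1
  rec$maternal_age_years <- rep(c(20, 25, 30), length.out = 511)
  rec$maternal_age_years[rec$arm == "control"] <-
    rep(c(20, 25, 30), length.out = 248)
  ident <- make_records(
    child_id = paste0("c", 1:40), village_id = "v1",
    arm = rep(c("intervention", "control"), each = 20),
    wave = "baseline", score = 100,
    age = rep(seq(20, 39), 2)
  )
  bal2 <- baseline_balance(ident, variables = "age")
  expect_equal(bal2$test, "t_test")
  expect_equal(bal2$p_value, 1, tolerance = 1e-9)

  # a level absent from both arms collapses the table: not applicable
  degen <- make_records(
    child_id = paste0("c", 1:10), village_id = "v1",
    arm = rep(c("intervention", "control"), each = 5),
    wave = "baseline", score = 100,
    cat = factor(rep("only_level", 10), levels = c("only_level", "unused"))
  )
  bal3 <- baseline_balance(degen, variables = "cat")
  expect_equal(bal3$test, "not_applicable")
  expect_true(is.na(bal3$p_value))

  expect_error(
    baseline_balance(rec[rec$arm == "control", ]), "both arms"
  )
})
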