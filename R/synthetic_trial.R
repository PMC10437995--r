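# Synthetic cluster-randomized trial generator.
#
# Emulates a two-arm pragmatic cluster trial of maternal nutrition
# education: mother/child dyads nested in villages, cognitive composite
# scores measured at three child-age waves, and completely-at-random
# attrition between enrollment and the final assessment.

#' Configuration for the synthetic cluster trial
#'
#' Defaults reproduce the design of the source trial: 263 vs 248 dyads
#' enrolled, 227 vs 196 retained through the final wave, arm-level baseline
#' means 102.37 / 103.42 with an overall score SD of 13, a true
#' difference-in-differences effect of 16.11 score units, and a control-arm
#' drift of -4.05 units between baseline and the final wave. The score
#' variance is decomposed into village, individual and residual components
#' that sum to the baseline variance; the cluster count (20 villages, 10 per
#' arm) and the decomposition are stand-ins, as neither is reported for the
#' original trial.
#'
#' @param n_intervention,n_control Dyads enrolled per arm.
#' @param n_villages Total number of village clusters, split evenly across
#'   arms (intervention gets the first half, rounded up).
#' @param retained_intervention,retained_control Children per arm retained
#'   through the final wave.
#' @param baseline_mean_intervention,baseline_mean_control Arm means of the
#'   cognitive composite score at baseline (child age 6-8 months).
#' @param baseline_sd Total SD of the score at any one wave.
#' @param true_effect Generating difference-in-differences contrast
#'   (score units).
#' @param control_followup_drift Change in the control-arm mean from
#'   baseline to the final wave (score units).
#' @param mid_mean_intervention,mid_mean_control Arm means at the middle
#'   wave (child age 12-16 months); descriptive only, excluded from the
#'   difference-in-differences fit.
#' @param sd_village,sd_individual,sd_residual SDs of the village random
#'   intercept, the child random intercept, and the occasion-level residual.
#'   The defaults satisfy
#'   `sd_village^2 + sd_individual^2 + sd_residual^2 == baseline_sd^2`.
#' @param seed Integer seed; generation is deterministic given the config.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_intervention = 263,
                             n_control = 248,
                             n_villages = 20,
                             retained_intervention = 227,
                             retained_control = 196,
                             baseline_mean_intervention = 102.37,
                             baseline_mean_control = 103.42,
                             baseline_sd = 13,
                             true_effect = 16.11,
                             control_followup_drift = -4.05,
                             mid_mean_intervention = 110.50,
                             mid_mean_control = 103.31,
                             sd_village = 3,
                             sd_individual = 8.5,
                             sd_residual = sqrt(13^2 - 3^2 - 8.5^2),
                             seed = 1L) {
  cfg <- list(
    n_intervention = n_intervention, n_control = n_control,
    n_villages = n_villages,
    retained_intervention = retained_intervention,
    retained_control = retained_control,
    baseline_mean_intervention = baseline_mean_intervention,
    baseline_mean_control = baseline_mean_control,
    baseline_sd = baseline_sd, true_effect = true_effect,
    control_followup_drift = control_followup_drift,
    mid_mean_intervention = mid_mean_intervention,
    mid_mean_control = mid_mean_control,
    sd_village = sd_village, sd_individual = sd_individual,
    sd_residual = sd_residual, seed = as.integer(seed)
  )
  if (cfg$retained_intervention > cfg$n_intervention ||
      cfg$retained_control > cfg$n_control) {
    stop("retained counts cannot exceed enrolled counts", call. = FALSE)
  }
  if (cfg$n_villages < 2) stop("need at least 2 villages", call. = FALSE)
  if (any(c(cfg$sd_village, cfg$sd_individual, cfg$sd_residual) < 0)) {
    stop("variance component SDs must be non-negative", call. = FALSE)
  }
  if (min(cfg$n_intervention, cfg$n_control, cfg$retained_intervention,
          cfg$retained_control) < 1) {
    stop("arm sizes must be positive", call. = FALSE)
  }
  class(cfg) <- "synthetic_config"
  cfg
}

# Baseline covariate marginals per arm (intervention, control), matching the
# published baseline characteristics table. Categorical probabilities are
# renormalized; numeric entries are mean and SD.
covariate_marginals <- function() {
  list(
    child_sex = list(
      levels = c("male", "female"),
      p_intervention = c(52.9, 47.2), p_control = c(49.6, 50.4)
    ),
    breastfeeding = list(
      levels = c("on_demand", "le_8_per_day"),
      p_intervention = c(64.9, 35.1), p_control = c(73.8, 26.2)
    ),
    dietary_diversity = list(
      levels = c("low", "medium", "high"),
      p_intervention = c(56.7, 31.6, 11.8), p_control = c(67.7, 26.2, 6.0)
    ),
    child_age_months = list(
      mean = c(intervention = 7.39, control = 7.26),
      sd = c(intervention = 0.83, control = 0.91)
    ),
    maternal_education_years = list(
      mean = c(intervention = 4.85, control = 4.92),
      sd = c(intervention = 2.82, control = 2.75)
    ),
    maternal_age_years = list(
      mean = c(intervention = 26.17, control = 26.98),
      sd = c(intervention = 5.92, control = 6.5)
    ),
    household_size = list(
      mean = c(intervention = 5.47, control = 5.48),
      sd = c(intervention = 2.08, control = 2.09)
    ),
    poverty_score = list(
      mean = c(intervention = 47.84, control = 47.61),
      sd = c(intervention = 11.65, control = 11.38)
    )
  )
}

# Arm-by-wave score means implied by the config. The final-wave
# intervention mean is chosen so the difference-in-differences contrast of
# the four cell means equals true_effect exactly.
wave_means <- function(config) {
  ctrl_final <- config$baseline_mean_control + config$control_followup_drift
  int_final <- config$baseline_mean_intervention +
    config$control_followup_drift + config$true_effect
  list(
    intervention = c(
      baseline = config$baseline_mean_intervention,
      mid = config$mid_mean_intervention,
      final = int_final
    ),
    control = c(
      baseline = config$baseline_mean_control,
      mid = config$mid_mean_control,
      final = ctrl_final
    )
  )
}

#' Generate the enrolled cohort of a synthetic cluster trial
#'
#' Draws one record per child per wave (baseline, mid, final) under the
#' model
#' `score = arm-by-wave mean + village intercept + child intercept + residual`
#' with independent normal components, and draws baseline covariates
#' independently from their published marginals (covariates are constant
#' across waves and, by default, do not affect the score). Deterministic
#' given `config$seed`; the caller's RNG state is left untouched.
#'
#' @param config A `synthetic_config`.
#' @return A long-format data frame with one row per child-wave:
#'   `child_id`, `village_id`, `arm`, `wave`, `age_months`,
#'   `cognitive_score`, and the covariate columns.
#' @export
#' @examples
#' trial <- generate_trial(synthetic_config(seed = 42))
#' length(unique(trial$child_id))
generate_trial <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_preserved_rng({
    set.seed(config$seed)
    means <- wave_means(config)
    marg <- covariate_marginals()
    waves <- c("baseline", "mid", "final")
    wave_age_offset <- c(baseline = 0, mid = 7, final = 14)

    n_vil_int <- ceiling(config$n_villages / 2)
    n_vil_ctl <- config$n_villages - n_vil_int
    arms <- list(
      intervention = list(
        n = config$n_intervention,
        villages = sprintf("int_v%02d", seq_len(n_vil_int))
      ),
      control = list(
        n = config$n_control,
        villages = sprintf("ctl_v%02d", seq_len(n_vil_ctl))
      )
    )

    pieces <- list()
    child_counter <- 0L
    for (arm in names(arms)) {
      n <- arms[[arm]]$n
      villages <- arms[[arm]]$villages
      village_of <- sample(rep(villages, length.out = n))
      vil_eff <- stats::setNames(
        stats::rnorm(length(villages), 0, config$sd_village), villages
      )
      child_eff <- stats::rnorm(n, 0, config$sd_individual)
      ids <- sprintf("c%04d", child_counter + seq_len(n))
      child_counter <- child_counter + n

      cov <- data.frame(
        child_sex = draw_categorical(n, marg$child_sex, arm),
        child_age_months = round(
          stats::rnorm(n, marg$child_age_months$mean[arm],
                       marg$child_age_months$sd[arm]), 1
        ),
        breastfeeding = draw_categorical(n, marg$breastfeeding, arm),
        dietary_diversity = draw_categorical(n, marg$dietary_diversity, arm),
        maternal_education_years = pmax(0, round(
          stats::rnorm(n, marg$maternal_education_years$mean[arm],
                       marg$maternal_education_years$sd[arm]), 1
        )),
        maternal_age_years = round(
          stats::rnorm(n, marg$maternal_age_years$mean[arm],
                       marg$maternal_age_years$sd[arm]), 1
        ),
        household_size = pmax(1, round(
          stats::rnorm(n, marg$household_size$mean[arm],
                       marg$household_size$sd[arm])
        )),
        poverty_score = round(
          stats::rnorm(n, marg$poverty_score$mean[arm],
                       marg$poverty_score$sd[arm]), 1
        ),
        stringsAsFactors = FALSE
      )

      for (w in waves) {
        score <- means[[arm]][w] + vil_eff[village_of] + child_eff +
          stats::rnorm(n, 0, config$sd_residual)
        pieces[[length(pieces) + 1L]] <- data.frame(
          child_id = ids,
          village_id = village_of,
          arm = arm,
          wave = w,
          age_months = cov$child_age_months + wave_age_offset[w],
          cognitive_score = as.numeric(score),
          cov,
          stringsAsFactors = FALSE
        )
      }
    }
    out <- do.call(rbind, pieces)
    out <- out[order(out$child_id, match(out$wave, waves)), ]
    rownames(out) <- NULL
    out
  })
}

draw_categorical <- function(n, spec, arm) {
  p <- if (arm == "intervention") spec$p_intervention else spec$p_control
  sample(spec$levels, n, replace = TRUE, prob = p / sum(p))
}

#' Apply completely-at-random attrition to a generated cohort
#'
#' Randomly selects which children are retained through the final wave so
#' that exactly `retained_intervention` and `retained_control` children per
#' arm keep their post-baseline records; dropped children keep only their
#' baseline record (missing completely at random). Deterministic given
#' `config$seed`.
#'
#' @param records Output of [generate_trial()] for the enrolled cohort.
#' @param config The same `synthetic_config`.
#' @return The records with post-baseline rows of dropped children removed.
#' @export
apply_attrition <- function(records, config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_preserved_rng({
    # offset so attrition is not correlated with the generation stream
    set.seed(config$seed + 1000003L)
    keep <- character(0)
    for (arm in c("intervention", "control")) {
      ids <- unique(records$child_id[records$arm == arm])
      n_keep <- if (arm == "intervention") {
        config$retained_intervention
      } else {
        config$retained_control
      }
      if (n_keep > length(ids)) {
        stop("retained count exceeds available children in the ", arm,
             " arm", call. = FALSE)
      }
      keep <- c(keep, sample(ids, n_keep))
    }
    drop <- records$wave != "baseline" & !(records$child_id %in% keep)
    out <- records[!drop, ]
    rownames(out) <- NULL
    out
  })
}

#' Generate a synthetic trial dataset with attrition applied
#'
#' Convenience wrapper: [generate_trial()] followed by [apply_attrition()].
#'
#' @inheritParams generate_trial
#' @return Long-format trial records for the observed (post-attrition) data.
#' @export
#' @examples
#' d <- simulate_trial(synthetic_config(seed = 7))
#' table(d$arm[d$wave == "final"])
simulate_trial <- function(config = synthetic_config()) {
  apply_attrition(generate_trial(config), config)
}

# Run code with the global RNG state restored afterwards.
with_preserved_rng <- function(expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    )
  }
  expr
}
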