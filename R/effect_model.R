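# Difference-in-differences estimation of the incremental cognitive score,
# descriptive arm-by-wave means, and baseline balance tests.

#' Construct an incremental-effect estimate
#'
#' Holds the incremental cognitive composite score (the
#' difference-in-differences effect of the intervention), its standard
#' error and normal-theory confidence interval. Either `se` or both CI
#' bounds may be supplied; the missing pieces are derived under normal
#' theory, so published estimates (point and CI) can stand in for a fitted
#' model.
#'
#' @param point Effect point estimate (score units).
#' @param se Standard error; derived from the CI when omitted.
#' @param ci_low,ci_high Confidence bounds; derived from `se` when omitted.
#' @param ci_level Confidence level (default 0.95).
#' @param n_intervention,n_control Optional analysis sample sizes.
#' @return An object of class `effect_estimate`.
#' @export
#' @examples
#' effect_estimate(16.11, ci_low = 11.72, ci_high = 20.50)
effect_estimate <- function(point, se = NULL, ci_low = NULL, ci_high = NULL,
                            ci_level = 0.95,
                            n_intervention = NA_integer_,
                            n_control = NA_integer_) {
  if (ci_level <= 0 || ci_level >= 1) {
    stop("ci_level must be strictly between 0 and 1", call. = FALSE)
  }
  z <- stats::qnorm((1 + ci_level) / 2)
  if (is.null(se)) {
    if (is.null(ci_low) || is.null(ci_high)) {
      stop("supply either se or both ci bounds", call. = FALSE)
    }
    se <- se_from_ci(ci_low, ci_high, ci_level)
  }
  if (is.null(ci_low)) ci_low <- point - z * se
  if (is.null(ci_high)) ci_high <- point + z * se
  if (ci_low > point || point > ci_high) {
    stop("point estimate must lie inside its confidence interval",
         call. = FALSE)
  }
  structure(
    list(
      point = point, se = se, ci_low = ci_low, ci_high = ci_high,
      ci_level = ci_level,
      n_intervention = n_intervention, n_control = n_control
    ),
    class = "effect_estimate"
  )
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf(
    "Incremental cognitive composite score: %.2f (SE %.3f, %d%% CI %.2f to %.2f)\n",
    x$point, x$se, round(100 * x$ci_level), x$ci_low, x$ci_high
  ))
  invisible(x)
}

#' Reconstruct a standard error from a confidence interval
#'
#' Inverts the normal-theory interval: `(ci_high - ci_low) / (2 * z)` with
#' `z` the standard normal quantile at `(1 + level) / 2`. Used to recover
#' the regression SE from a published interval when raw data are absent.
#'
#' @param ci_low,ci_high Interval bounds (`ci_high > ci_low`).
#' @param level Confidence level in (0, 1).
#' @return The implied standard error.
#' @export
#' @examples
#' se_from_ci(11.72, 20.50, 0.95)
se_from_ci <- function(ci_low, ci_high, level = 0.95) {
  if (level <= 0 || level >= 1) {
    stop("level must be strictly between 0 and 1", call. = FALSE)
  }
  if (ci_high <= ci_low) {
    stop("ci_high must exceed ci_low", call. = FALSE)
  }
  (ci_high - ci_low) / (2 * stats::qnorm((1 + level) / 2))
}

#' Fit the difference-in-differences linear mixed model
#'
#' Estimates the incremental cognitive composite score as the coefficient
#' of the group-by-time interaction (group: control = 0, intervention = 1;
#' time: baseline = 0, final follow-up = 1) in a linear mixed model with a
#' random intercept for village and a random intercept for child nested in
#' village. Only baseline and final waves enter the fit, restricted to
#' completers (children observed at both), mirroring the trial analysis.
#' Estimation is by REML through `lme4::lmer`; the CI is the normal
#' (Wald) interval on the interaction coefficient.
#'
#' Noise-free inputs (all within-cell residuals zero) make the mixed model
#' degenerate; they are detected via the OLS residual scale and resolved by
#' returning the exact OLS interaction coefficient with zero SE.
#'
#' @param records Long-format trial records as produced by
#'   [simulate_trial()]: columns `child_id`, `village_id`, `arm`, `wave`,
#'   `cognitive_score` plus any covariates.
#' @param covariates Character vector of baseline covariate columns to
#'   adjust for (entered as fixed effects; character columns become factor
#'   indicator contrasts). Default none.
#' @param ci_level Confidence level for the interval.
#' @param reml Use REML (default) or ML.
#' @return An `effect_estimate` with the interaction coefficient, its SE
#'   and CI, plus the fitted model in attribute `"model"`.
#' @export
#' @examples
#' d <- simulate_trial(synthetic_config(seed = 3))
#' fit_did_model(d)
fit_did_model <- function(records, covariates = NULL, ci_level = 0.95,
                          reml = TRUE) {
  needed <- c("child_id", "village_id", "arm", "wave", "cognitive_score")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    stop("records are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d <- records[records$wave %in% c("baseline", "final"), , drop = FALSE]
  # completers: children observed at both waves
  both <- intersect(
    d$child_id[d$wave == "baseline"], d$child_id[d$wave == "final"]
  )
  d <- d[d$child_id %in% both, , drop = FALSE]
  if (nrow(d) == 0) stop("no completer records to fit", call. = FALSE)
  for (arm in c("intervention", "control")) {
    if (length(unique(d$village_id[d$arm == arm])) < 2) {
      stop("need at least 2 villages per arm to fit the mixed model",
           call. = FALSE)
    }
  }
  d$group <- as.integer(d$arm == "intervention")
  d$time <- as.integer(d$wave == "final")
  for (v in covariates) {
    if (!v %in% names(d)) {
      stop("covariate column not found: ", v, call. = FALSE)
    }
    if (is.character(d[[v]])) d[[v]] <- factor(d[[v]])
  }
  rhs <- c("group * time", covariates)
  fixed <- stats::reformulate(rhs, response = "cognitive_score")

  # degenerate (noise-free) data: mixed model is unidentified, OLS is exact
  ols <- stats::lm(fixed, data = d)
  if (stats::sigma(ols) < 1e-6) {
    point <- unname(stats::coef(ols)["group:time"])
    return(effect_estimate(
      point = point, se = 0, ci_low = point, ci_high = point,
      ci_level = ci_level,
      n_intervention = length(unique(d$child_id[d$group == 1])),
      n_control = length(unique(d$child_id[d$group == 0]))
    ))
  }

  mixed <- stats::as.formula(
    paste(
      paste(deparse(fixed), collapse = " "),
      "+ (1 | village_id) + (1 | village_id:child_id)"
    )
  )
  fit <- tryCatch(
    lme4::lmer(
      mixed, data = d, REML = reml,
      control = lme4::lmerControl(
        optimizer = "bobyqa",
        check.conv.grad = lme4::.makeCC("warning", tol = 0.02, relTol = NULL)
      )
    ),
    error = function(e) {
      stop("mixed model estimation failed: ", conditionMessage(e),
           call. = FALSE)
    }
  )
  point <- unname(lme4::fixef(fit)["group:time"])
  se <- sqrt(stats::vcov(fit)["group:time", "group:time"])
  z <- stats::qnorm((1 + ci_level) / 2)
  out <- effect_estimate(
    point = point, se = se,
    ci_low = point - z * se, ci_high = point + z * se,
    ci_level = ci_level,
    n_intervention = length(unique(d$child_id[d$group == 1])),
    n_control = length(unique(d$child_id[d$group == 0]))
  )
  attr(out, "model") <- fit
  out
}

#' Arm-by-wave mean cognitive scores
#'
#' Arithmetic means of the cognitive composite score per arm and wave,
#' restricted (by default) to children retained through the final wave, as
#' in the trial's descriptive figure. Cells with no observations are
#' reported as missing.
#'
#' @param records Long-format trial records.
#' @param completers_only Restrict to children with a final-wave record.
#' @return Data frame with `arm`, `wave`, `n`, `mean_score`.
#' @export
group_wave_means <- function(records, completers_only = TRUE) {
  if (nrow(records) == 0) stop("no records", call. = FALSE)
  d <- records
  if (completers_only) {
    finals <- unique(d$child_id[d$wave == "final"])
    d <- d[d$child_id %in% finals, , drop = FALSE]
  }
  waves <- intersect(c("baseline", "mid", "final"), unique(records$wave))
  grid <- expand.grid(
    arm = c("intervention", "control"), wave = waves,
    stringsAsFactors = FALSE
  )
  grid$n <- mapply(function(a, w) sum(d$arm == a & d$wave == w),
                   grid$arm, grid$wave)
  grid$mean_score <- mapply(function(a, w) {
    x <- d$cognitive_score[d$arm == a & d$wave == w]
    if (length(x) == 0) NA_real_ else mean(x)
  }, grid$arm, grid$wave)
  grid
}

#' Baseline balance table
#'
#' Per-covariate arm summaries and balance tests on the baseline wave:
#' chi-square tests (without continuity correction) for categorical
#' variables, two-sample t-tests for numerical variables, flagged at
#' p < 0.05. A categorical test with a zero expected cell count is reported
#' as not applicable (`NA` p-value).
#'
#' @param records Trial records; only the baseline wave is used.
#' @param variables Covariate columns to test; defaults to every column
#'   other than the identifiers, `wave`, `age_months` and the score.
#' @return Data frame of class `balance_table` with one row per variable:
#'   `variable`, `type`, `summary_intervention`, `summary_control`, `test`,
#'   `p_value`, `significant`.
#' @export
baseline_balance <- function(records, variables = NULL) {
  d <- records[records$wave == "baseline", , drop = FALSE]
  if (length(unique(d$arm)) < 2) {
    stop("baseline balance needs both arms", call. = FALSE)
  }
  if (is.null(variables)) {
    variables <- setdiff(
      names(d),
      c("child_id", "village_id", "arm", "wave", "age_months",
        "cognitive_score")
    )
  }
  rows <- lapply(variables, function(v) {
    x <- d[[v]]
    int <- x[d$arm == "intervention"]
    ctl <- x[d$arm == "control"]
    if (is.numeric(x)) {
      ht <- stats::t.test(int, ctl)
      data.frame(
        variable = v, type = "numerical",
        summary_intervention = sprintf("%.2f (%.2f)", mean(int), stats::sd(int)),
        summary_control = sprintf("%.2f (%.2f)", mean(ctl), stats::sd(ctl)),
        test = "t_test", p_value = ht$p.value,
        stringsAsFactors = FALSE
      )
    } else {
      tab <- table(factor(d$arm, c("intervention", "control")), x)
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      p <- if (any(expected == 0)) {
        NA_real_
      } else {
        suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
      }
      summarize_arm <- function(arm) {
        cnt <- tab[arm, ]
        paste(sprintf("%s %d (%.1f%%)", colnames(tab), cnt,
                      100 * cnt / sum(cnt)), collapse = "; ")
      }
      data.frame(
        variable = v, type = "categorical",
        summary_intervention = summarize_arm("intervention"),
        summary_control = summarize_arm("control"),
        test = if (is.na(p)) "not_applicable" else "chi_square",
        p_value = p,
        stringsAsFactors = FALSE
      )
    }
  })
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p_value) & out$p_value < 0.05
  class(out) <- c("balance_table", class(out))
  out
}
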