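# Configuration, pipeline orchestration and report rendering.

#' Read and validate an analysis configuration
#'
#' Reads a YAML configuration describing a full cost-effectiveness run:
#' cost ledger location, the source of the incremental effect (a published
#' estimate, a trial-records file, or a synthetic-trial block), sensitivity
#' ranges, PSA settings and output options. Relative paths are resolved
#' against the configuration file's directory, falling back to the
#' package's `extdata` folder for packaged fixtures.
#'
#' @param path Path to a YAML file. Recognized keys: `ledger_path`
#'   (required), `n_children_denominator` (default 227), `total_override`,
#'   `effect` (`point`, `ci_low`, `ci_high`, optional `ci_level`),
#'   `trial_data_path`, `synthetic` (arguments to [synthetic_config()]),
#'   `covariates`, `psa` (`n_samples`, `seed`), `cost_ranges`, `wtp_grid`
#'   (`from`, `to`, `by` or a list of values), `output_dir`,
#'   `report_rounding`, `figures`.
#' @return A validated list of class `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  cfg$.dir <- dirname(normalizePath(path))
  if (is.null(cfg$ledger_path)) {
    stop("config is missing required field 'ledger_path'", call. = FALSE)
  }
  cfg$ledger_path <- resolve_path(cfg$ledger_path, cfg$.dir)
  if (is.null(cfg$ledger_path)) {
    stop("config field 'ledger_path' does not point to an existing file",
         call. = FALSE)
  }
  if (!is.null(cfg$trial_data_path)) {
    cfg$trial_data_path <- resolve_path(cfg$trial_data_path, cfg$.dir)
    if (is.null(cfg$trial_data_path)) {
      stop("config field 'trial_data_path' does not point to an existing file",
           call. = FALSE)
    }
  }
  if (is.null(cfg$effect) && is.null(cfg$trial_data_path) &&
      is.null(cfg$synthetic)) {
    stop("config must provide one of: effect, trial_data_path, synthetic",
         call. = FALSE)
  }
  if (!is.null(cfg$psa) && is.null(cfg$psa$seed)) {
    stop("config field 'psa' must carry an explicit seed", call. = FALSE)
  }
  if (is.null(cfg$n_children_denominator)) cfg$n_children_denominator <- 227
  if (is.null(cfg$report_rounding)) cfg$report_rounding <- 2
  class(cfg) <- "analysis_config"
  cfg
}

resolve_path <- function(p, dir) {
  candidates <- c(
    p, file.path(dir, p),
    system.file("extdata", p, package = "nutricea")
  )
  candidates <- candidates[nzchar(candidates)]
  hit <- candidates[file.exists(candidates)]
  if (length(hit) == 0) NULL else hit[1]
}

config_wtp_grid <- function(cfg) {
  g <- cfg$wtp_grid
  if (is.null(g)) return(seq(0, 30, by = 0.5))
  if (is.list(g) && !is.null(g$from)) {
    return(seq(g$from, g$to, by = if (is.null(g$by)) 0.5 else g$by))
  }
  sort(unlist(g))
}

#' Run the full cost-effectiveness pipeline
#'
#' Executes, in order: cost-ledger aggregation, incremental-effect
#' estimation (or adoption of a supplied estimate), deterministic
#' cost-effectiveness, one-way sensitivity analysis, probabilistic
#' sensitivity analysis and the acceptability curve. Each stage failure is
#' reported with the stage name. When `output_dir` is set (in the config or
#' as an argument) the report bundle is also written to disk via
#' [render_reports()].
#'
#' @param config An `analysis_config` from [read_analysis_config()], or a
#'   path to a YAML config file.
#' @param output_dir Optional output directory overriding the config.
#' @return Invisibly, a list of class `cea_bundle`: `cost_summary`,
#'   `effect`, `deterministic`, `tornado`, `psa`, `ceac`, `group_means`
#'   (NULL unless trial records were fitted), and `config`.
#' @export
#' @examples
#' cfg <- read_analysis_config(
#'   system.file("extdata", "base_case.yaml", package = "nutricea")
#' )
#' bundle <- run_pipeline(cfg)
#' bundle$deterministic
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_analysis_config(config)
  stopifnot(inherits(config, "analysis_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  t0 <- Sys.time()
  costs <- stage("cost_summary", {
    ledger <- read_cost_ledger(config$ledger_path)
    summarize_costs(
      ledger, config$n_children_denominator,
      total_override = config$total_override
    )
  })
  group_means <- NULL
  effect <- stage("effect_estimate", {
    if (!is.null(config$effect)) {
      e <- config$effect
      effect_estimate(
        point = e$point, se = e$se, ci_low = e$ci_low, ci_high = e$ci_high,
        ci_level = if (is.null(e$ci_level)) 0.95 else e$ci_level
      )
    } else {
      records <- if (!is.null(config$trial_data_path)) {
        utils::read.csv(config$trial_data_path, stringsAsFactors = FALSE)
      } else {
        simulate_trial(do.call(synthetic_config, config$synthetic))
      }
      group_means <- group_wave_means(records)
      fit_did_model(records, covariates = unlist(config$covariates))
    }
  })
  deterministic <- stage("deterministic_cea", {
    icer(costs$per_child_total, effect$point)
  })
  tornado <- stage("one_way_dsa", one_way_dsa(costs, effect))
  psa_cfg <- config$psa
  psa <- stage("psa", {
    if (is.null(psa_cfg)) NULL else {
      run_psa(
        costs, effect,
        n_samples = if (is.null(psa_cfg$n_samples)) 1000 else psa_cfg$n_samples,
        seed = psa_cfg$seed,
        cost_ranges = if (is.null(config$cost_ranges)) {
          default_cost_ranges()
        } else {
          lapply(config$cost_ranges, unlist)
        }
      )
    }
  })
  acceptability <- stage("ceac", {
    if (is.null(psa)) NULL else ceac(psa, config_wtp_grid(config))
  })
  bundle <- structure(
    list(
      cost_summary = costs, effect = effect, deterministic = deterministic,
      tornado = tornado, psa = psa, ceac = acceptability,
      group_means = group_means, config = config,
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    ),
    class = "cea_bundle"
  )
  out_dir <- if (is.null(output_dir)) config$output_dir else output_dir
  if (!is.null(out_dir)) render_reports(bundle, out_dir)
  invisible(bundle)
}

#' Write the report bundle to disk
#'
#' Writes the tabular outputs of a pipeline run as CSV/JSON — cost summary,
#' deterministic result, tornado table, PSA samples, acceptability curve,
#' and (when available) arm-by-wave means — plus a run log with package
#' version, seed and timing. Monetary columns are rounded to
#' `report_rounding` decimals (default 2) at write time. When `ggplot2` is
#' installed and the config sets `figures: true`, PNG figures of the
#' tornado, cost-effectiveness plane, acceptability curve, and group means
#' are written as well.
#'
#' @param bundle A `cea_bundle` from [run_pipeline()].
#' @param output_dir Directory to write into (created if needed).
#' @return Invisibly, the paths written.
#' @export
render_reports <- function(bundle, output_dir) {
  stopifnot(inherits(bundle, "cea_bundle"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(output_dir)) {
    stop("cannot create output directory: ", output_dir, call. = FALSE)
  }
  nd <- bundle$config$report_rounding
  money <- function(x) sprintf(paste0("%.", nd, "f"), x)
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(output_dir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = TRUE)
    paths <<- c(paths, p)
  }

  cs <- bundle$cost_summary
  emit(data.frame(
    category = c(names(cs$category_totals), "total"),
    total_usd = money(c(cs$category_totals, cs$total)),
    share_pct = c(sprintf("%.1f", cs$category_shares), "100.0"),
    per_child_usd = money(c(cs$per_child_by_category, cs$per_child_total)),
    stringsAsFactors = FALSE
  ), "cost_summary.csv")

  det <- bundle$deterministic
  det_path <- file.path(output_dir, "cea_deterministic.json")
  jsonlite::write_json(
    list(
      delta_c = round(det$delta_c, nd), delta_e = det$delta_e,
      icer = round(det$icer, nd), quadrant = det$quadrant,
      dominance = det$dominance
    ),
    det_path, auto_unbox = TRUE, digits = NA
  )
  paths <- c(paths, det_path)

  tor <- bundle$tornado
  emit(data.frame(
    parameter = tor$parameter, low = tor$low, high = tor$high,
    icer_low = money(tor$icer_at_low), icer_high = money(tor$icer_at_high),
    span = money(tor$span), stringsAsFactors = FALSE
  ), "tornado.csv")

  if (!is.null(bundle$psa)) {
    s <- bundle$psa$samples
    emit(data.frame(
      draw = s$draw, delta_e = s$delta_e, delta_c = money(s$delta_c),
      icer = ifelse(is.na(s$icer), "", money(s$icer)),
      quadrant = s$quadrant, stringsAsFactors = FALSE
    ), "psa_samples.csv")
    emit(bundle$ceac, "ceac.csv")
  } else {
    warning("PSA not configured; psa_samples.csv and ceac.csv omitted")
  }

  if (!is.null(bundle$group_means)) emit(bundle$group_means, "group_means.csv")

  log_path <- file.path(output_dir, "run_log.txt")
  writeLines(c(
    paste("nutricea version:", as.character(utils::packageVersion("nutricea"))),
    paste("R version:", R.version.string),
    paste("PSA seed:", if (is.null(bundle$psa)) "none" else bundle$psa$seed),
    paste("PSA draws:", if (is.null(bundle$psa)) 0 else bundle$psa$n_samples),
    paste("elapsed seconds:", sprintf("%.2f", bundle$elapsed_s))
  ), log_path)
  paths <- c(paths, log_path)

  if (isTRUE(bundle$config$figures) && requireNamespace("ggplot2", quietly = TRUE)) {
    figs <- list(
      tornado = plot_tornado(bundle$tornado, det$icer),
      ce_plane = if (is.null(bundle$psa)) NULL else plot_ce_plane(bundle$psa),
      ceac = if (is.null(bundle$ceac)) NULL else plot_ceac(bundle$ceac),
      group_means = if (is.null(bundle$group_means)) NULL else
        plot_group_means(bundle$group_means)
    )
    for (nm in names(figs)) {
      if (is.null(figs[[nm]])) next
      p <- file.path(output_dir, paste0(nm, ".png"))
      ggplot2::ggsave(p, figs[[nm]], width = 7, height = 5, dpi = 150)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' @export
print.cea_bundle <- function(x, ...) {
  print(x$cost_summary)
  print(x$effect)
  print(x$deterministic)
  if (!is.null(x$psa)) print(x$psa)
  invisible(x)
}

#' Tornado diagram of the one-way sensitivity analysis
#'
#' @param tornado A `tornado` table from [one_way_dsa()].
#' @param base_icer The base-case ICER (vertical reference line).
#' @return A ggplot object (requires the `ggplot2` package).
#' @export
plot_tornado <- function(tornado, base_icer) {
  require_ggplot()
  d <- tornado
  d$parameter <- factor(d$parameter, levels = rev(d$parameter))
  long <- rbind(
    data.frame(parameter = d$parameter, icer = d$icer_at_low, bound = "low"),
    data.frame(parameter = d$parameter, icer = d$icer_at_high, bound = "high")
  )
  ggplot2::ggplot(long) +
    ggplot2::geom_segment(
      ggplot2::aes(
        x = base_icer, xend = .data_col(long, "icer"),
        y = .data_col(long, "parameter"),
        yend = .data_col(long, "parameter"),
        colour = .data_col(long, "bound")
      ),
      linewidth = 6
    ) +
    ggplot2::geom_vline(xintercept = base_icer, linetype = 2) +
    ggplot2::labs(
      x = "ICER (USD per cognitive composite score unit)", y = NULL,
      colour = "bound"
    ) +
    ggplot2::theme_minimal()
}

# aes() helper avoiding a hard ggplot2 import at build time
.data_col <- function(d, nm) d[[nm]]

#' Cost-effectiveness plane scatter plot
#'
#' @param psa A `psa_result`.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa) {
  require_ggplot()
  s <- psa$samples
  ggplot2::ggplot(s) +
    ggplot2::geom_point(
      ggplot2::aes(x = .data_col(s, "delta_e"), y = .data_col(s, "delta_c")),
      alpha = 0.4
    ) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::geom_vline(xintercept = 0) +
    ggplot2::labs(
      x = "Incremental cognitive composite score",
      y = "Incremental cost (USD per child)"
    ) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param ceac_table A `ceac` data frame.
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_table) {
  require_ggplot()
  ggplot2::ggplot(ceac_table) +
    ggplot2::geom_line(
      ggplot2::aes(x = .data_col(ceac_table, "wtp"),
                   y = .data_col(ceac_table, "probability"))
    ) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Willingness to pay (USD per score unit)",
      y = "Probability cost-effective"
    ) +
    ggplot2::theme_minimal()
}

#' Arm-by-wave mean score plot
#'
#' @param means Output of [group_wave_means()].
#' @return A ggplot object.
#' @export
plot_group_means <- function(means) {
  require_ggplot()
  means$wave <- factor(means$wave, levels = c("baseline", "mid", "final"))
  ggplot2::ggplot(means) +
    ggplot2::geom_line(
      ggplot2::aes(
        x = as.integer(.data_col(means, "wave")),
        y = .data_col(means, "mean_score"),
        colour = .data_col(means, "arm")
      )
    ) +
    ggplot2::scale_x_continuous(
      breaks = 1:3, labels = c("baseline", "mid", "final")
    ) +
    ggplot2::labs(x = "Wave", y = "Mean cognitive composite score",
                  colour = "arm") +
    ggplot2::theme_minimal()
}

require_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("the ggplot2 package is required for plotting", call. = FALSE)
  }
}
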