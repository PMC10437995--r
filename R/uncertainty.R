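# One-way (tornado) deterministic sensitivity analysis and Monte Carlo
# probabilistic sensitivity analysis, with cost-effectiveness plane and
# acceptability-curve summaries.

#' Define a one-way sensitivity parameter
#'
#' A parameter varied one at a time in the tornado analysis: either a cost
#' category scaled by a low/high multiplier, or the incremental effect set
#' to absolute low/high values (its confidence bounds).
#'
#' @param name One of the four cost categories ([cost_categories()]) or
#'   `"effect"`.
#' @param low,high Bounds (`low <= reference <= high` under the parameter's
#'   natural ordering).
#' @param kind `"multiplier"` (cost categories) or `"absolute"` (effect).
#' @param reference Base-case value (1 for multipliers; effect point
#'   estimate for the effect).
#' @return A list of class `dsa_parameter`.
#' @export
dsa_parameter <- function(name, low, high,
                          kind = c("multiplier", "absolute"),
                          reference = if (kind[1] == "multiplier") 1 else NA) {
  kind <- match.arg(kind)
  if (!name %in% c(cost_categories(), "effect")) {
    stop("unrecognized sensitivity parameter: ", name, call. = FALSE)
  }
  if (low > high) stop("low bound exceeds high bound for ", name, call. = FALSE)
  structure(
    list(name = name, low = low, high = high, kind = kind,
         reference = reference),
    class = "dsa_parameter"
  )
}

#' Default one-way sensitivity ranges
#'
#' The base-case tornado set: personnel costs from a 50% reduction to a 20%
#' increase; the other three cost categories varied by +/-20%; the
#' incremental effect set to its 95% confidence bounds.
#'
#' @param effect An `effect_estimate` supplying the effect reference and
#'   bounds.
#' @return List of `dsa_parameter` objects.
#' @export
default_dsa_parameters <- function(effect) {
  list(
    dsa_parameter("personnel", 0.5, 1.2),
    dsa_parameter("materials_other", 0.8, 1.2),
    dsa_parameter("capacity_building", 0.8, 1.2),
    dsa_parameter("capital", 0.8, 1.2),
    dsa_parameter("effect", effect$ci_low, effect$ci_high,
                  kind = "absolute", reference = effect$point)
  )
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Recomputes the ICER with each parameter at its low and then its high
#' bound, all other parameters at reference, and returns the entries sorted
#' by ICER span (largest first; ties broken alphabetically by parameter
#' name).
#'
#' @param base Base-case `cost_summary` (per-child costs at reference).
#' @param effect Base-case `effect_estimate`.
#' @param params List of [dsa_parameter()] objects; defaults to
#'   [default_dsa_parameters()].
#' @return Data frame of class `tornado` with columns `parameter`, `low`,
#'   `high`, `icer_at_low`, `icer_at_high`, `span`.
#' @export
#' @examples
#' ledger <- read_cost_ledger(
#'   system.file("extdata", "chnudev_costs.csv", package = "nutricea")
#' )
#' base <- summarize_costs(ledger, n_children = 227)
#' eff <- effect_estimate(16.11, ci_low = 11.72, ci_high = 20.50)
#' one_way_dsa(base, eff)
one_way_dsa <- function(base, effect, params = default_dsa_parameters(effect)) {
  stopifnot(inherits(base, "cost_summary"), inherits(effect, "effect_estimate"))
  icer_at <- function(p, value) {
    if (p$kind == "multiplier") {
      dc <- apply_multipliers(base, stats::setNames(value, p$name))$per_child_total
      dc / effect$point
    } else {
      base$per_child_total / value
    }
  }
  rows <- lapply(params, function(p) {
    if (!inherits(p, "dsa_parameter")) {
      stop("params must be dsa_parameter objects", call. = FALSE)
    }
    data.frame(
      parameter = p$name, low = p$low, high = p$high,
      icer_at_low = icer_at(p, p$low),
      icer_at_high = icer_at(p, p$high),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$span <- abs(out$icer_at_high - out$icer_at_low)
  out <- out[order(-out$span, out$parameter), ]
  rownames(out) <- NULL
  class(out) <- c("tornado", class(out))
  out
}

#' Default cost-multiplier ranges for the probabilistic analysis
#'
#' Mirrors the one-way ranges: personnel Uniform(0.5, 1.2); materials and
#' other, capacity building, and capital Uniform(0.8, 1.2), applied as
#' multipliers to the per-child category costs.
#'
#' @return Named list of length-2 numeric ranges.
#' @export
default_cost_ranges <- function() {
  list(
    personnel = c(0.5, 1.2),
    materials_other = c(0.8, 1.2),
    capacity_building = c(0.8, 1.2),
    capital = c(0.8, 1.2)
  )
}

#' Monte Carlo probabilistic sensitivity analysis
#'
#' Draws `n_samples` independent parameter sets: the incremental effect
#' from Normal(point, SE) and each per-child cost category scaled by an
#' independent uniform multiplier over its sensitivity range. Per draw the
#' incremental cost is the sum of the sampled categories; each
#' (incremental cost, incremental effect) pair is classified on the
#' cost-effectiveness plane. ICER summaries (mean of per-sample ratios, its
#' 2.5-97.5 percentile interval, and the ratio of means) are taken over the
#' draws with positive incremental effect; draws with non-positive effect
#' are retained in the samples and quadrant counts but excluded from the
#' ratio summaries, with the exclusion count reported.
#'
#' @param base Base-case `cost_summary`.
#' @param effect `effect_estimate` supplying the effect distribution.
#' @param n_samples Number of Monte Carlo draws (default 1000).
#' @param seed Integer seed; results are reproducible given the seed.
#' @param cost_ranges Named list of per-category multiplier ranges;
#'   defaults to [default_cost_ranges()].
#' @return Object of class `psa_result`: list with `samples` (data frame
#'   `draw`, `delta_e`, `delta_c`, `icer`, `quadrant`), `mean_icer`,
#'   `icer_interval` (2.5% and 97.5% percentiles), `icer_ratio_of_means`,
#'   `quadrant_counts`, `n_excluded_from_icer`, `n_samples`, `seed`.
#' @export
#' @examples
#' ledger <- read_cost_ledger(
#'   system.file("extdata", "chnudev_costs.csv", package = "nutricea")
#' )
#' base <- summarize_costs(ledger, n_children = 227)
#' eff <- effect_estimate(16.11, ci_low = 11.72, ci_high = 20.50)
#' psa <- run_psa(base, eff, n_samples = 1000, seed = 1)
#' psa$mean_icer
run_psa <- function(base, effect, n_samples = 1000, seed = 1L,
                    cost_ranges = default_cost_ranges()) {
  stopifnot(inherits(base, "cost_summary"), inherits(effect, "effect_estimate"))
  if (n_samples < 1) stop("n_samples must be at least 1", call. = FALSE)
  bad <- vapply(cost_ranges, function(r) length(r) != 2 || r[1] > r[2],
                logical(1))
  if (any(bad)) {
    stop("cost range for ", names(cost_ranges)[which(bad)[1]],
         " must be an ordered pair", call. = FALSE)
  }
  unknown <- setdiff(names(cost_ranges), cost_categories())
  if (length(unknown) > 0) {
    stop("unknown cost category in cost_ranges: ", unknown[1], call. = FALSE)
  }
  with_preserved_rng({
    set.seed(as.integer(seed))
    delta_e <- stats::rnorm(n_samples, effect$point, effect$se)
    per_child <- base$per_child_by_category
    delta_c <- numeric(n_samples)
    for (cat in cost_categories()) {
      r <- cost_ranges[[cat]]
      mult <- if (is.null(r)) rep(1, n_samples) else stats::runif(n_samples, r[1], r[2])
      delta_c <- delta_c + per_child[[cat]] * mult
    }
    quadrant <- ifelse(
      delta_e > 0, ifelse(delta_c > 0, "NE", "SE"),
      ifelse(delta_c > 0, "NW", "SW")
    )
    ratio <- ifelse(delta_e > 0, delta_c / delta_e, NA_real_)
    samples <- data.frame(
      draw = seq_len(n_samples), delta_e = delta_e, delta_c = delta_c,
      icer = ratio, quadrant = quadrant, stringsAsFactors = FALSE
    )
    ok <- !is.na(ratio)
    counts <- table(factor(quadrant, levels = c("NE", "SE", "NW", "SW")))
    structure(
      list(
        samples = samples,
        mean_icer = mean(ratio[ok]),
        icer_interval = stats::quantile(ratio[ok], c(0.025, 0.975),
                                        names = FALSE),
        icer_ratio_of_means = mean(delta_c) / mean(delta_e),
        quadrant_counts = counts,
        n_excluded_from_icer = sum(!ok),
        n_samples = n_samples,
        seed = as.integer(seed)
      ),
      class = "psa_result"
    )
  })
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf(
    "Probabilistic sensitivity analysis: %d draws (seed %d)\n",
    x$n_samples, x$seed
  ))
  cat(sprintf(
    "Mean ICER (per-sample ratios): $%.2f (95%% interval $%.2f to $%.2f)\n",
    x$mean_icer, x$icer_interval[1], x$icer_interval[2]
  ))
  cat(sprintf("Ratio of means: $%.2f\n", x$icer_ratio_of_means))
  cat("Quadrant counts:",
      paste(names(x$quadrant_counts), x$quadrant_counts, collapse = ", "),
      "\n")
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the share of Monte Carlo draws with
#' strictly positive net monetary benefit (`wtp * delta_e - delta_c > 0`),
#' i.e. the probability the intervention is cost-effective at that
#' threshold.
#'
#' @param result A `psa_result`.
#' @param wtp_grid Non-negative willingness-to-pay grid (USD per score
#'   unit); default 0 to 30 in steps of 0.5.
#' @return Data frame of class `ceac` with `wtp` and `probability`.
#' @export
ceac <- function(result, wtp_grid = seq(0, 30, by = 0.5)) {
  stopifnot(inherits(result, "psa_result"))
  if (length(wtp_grid) == 0) {
    return(structure(
      data.frame(wtp = numeric(0), probability = numeric(0)),
      class = c("ceac", "data.frame")
    ))
  }
  if (any(wtp_grid < 0)) stop("wtp grid must be non-negative", call. = FALSE)
  s <- result$samples
  prob <- vapply(
    wtp_grid,
    function(l) mean(l * s$delta_e - s$delta_c > 0),
    numeric(1)
  )
  structure(
    data.frame(wtp = wtp_grid, probability = prob),
    class = c("ceac", "data.frame")
  )
}

#' Cost-effectiveness plane scatter
#'
#' Emits all sampled (incremental effect, incremental cost) pairs with
#' their quadrant labels, plus per-quadrant counts, for plotting the joint
#' distribution of the Monte Carlo draws.
#'
#' @param result A `psa_result`.
#' @return List with `samples` (data frame `delta_e`, `delta_c`,
#'   `quadrant`) and `quadrant_counts`.
#' @export
ce_plane <- function(result) {
  stopifnot(inherits(result, "psa_result"))
  list(
    samples = result$samples[, c("delta_e", "delta_c", "quadrant")],
    quadrant_counts = result$quadrant_counts
  )
}
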