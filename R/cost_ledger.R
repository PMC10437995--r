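# Cost-ledger loading, validation and per-child aggregation.

#' Cost categories used by the intervention costing
#'
#' The four expenditure lines of the provider-perspective costing:
#' personnel, materials and other variable costs, capacity building
#' (training), and capital/facilities.
#'
#' @return Character vector of the four category codes.
#' @export
cost_categories <- function() {
  c("personnel", "materials_other", "capacity_building", "capital")
}

#' Read an intervention cost ledger
#'
#' Reads a delimited cost ledger with one row per cost item. Required
#' columns are `label` and `category`; each row must carry either a direct
#' `amount` (2014 USD) or both `unit_cost` and `quantity`, in which case the
#' amount is their product. An optional `attributable_fraction` column
#' (default 1) scales amounts shared with the comparator arm down to the
#' intervention-attributable part.
#'
#' @param path Path to a CSV file with header
#'   `label,category,unit_cost,quantity,amount,attributable_fraction`
#'   (the last four columns may be empty per row where not applicable).
#' @return A data frame of class `cost_ledger` with columns `label`,
#'   `category`, `unit_cost`, `quantity`, `amount` (intervention-attributable
#'   2014 USD) and `attributable_fraction`.
#' @export
#' @examples
#' ledger <- read_cost_ledger(
#'   system.file("extdata", "chnudev_costs.csv", package = "nutricea")
#' )
#' sum(ledger$amount)
read_cost_ledger <- function(path) {
  if (!file.exists(path)) {
    stop("cost ledger file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  for (col in c("label", "category")) {
    if (!col %in% names(raw)) {
      stop("cost ledger is missing required column '", col, "'", call. = FALSE)
    }
  }
  for (col in c("unit_cost", "quantity", "amount", "attributable_fraction")) {
    if (!col %in% names(raw)) raw[[col]] <- NA_real_
    raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  }
  bad_cat <- !(raw$category %in% cost_categories())
  if (any(bad_cat)) {
    stop(
      "unknown cost category '", raw$category[which(bad_cat)[1]],
      "' in row ", which(bad_cat)[1],
      " (expected one of: ", paste(cost_categories(), collapse = ", "), ")",
      call. = FALSE
    )
  }
  raw$attributable_fraction[is.na(raw$attributable_fraction)] <- 1
  has_uq <- !is.na(raw$unit_cost) & !is.na(raw$quantity)
  amount <- ifelse(has_uq, raw$unit_cost * raw$quantity, raw$amount)
  if (any(is.na(amount))) {
    stop(
      "row ", which(is.na(amount))[1],
      " has neither a direct amount nor both unit_cost and quantity",
      call. = FALSE
    )
  }
  amount <- amount * raw$attributable_fraction
  if (any(amount < 0)) {
    stop("negative amount in row ", which(amount < 0)[1], call. = FALSE)
  }
  out <- data.frame(
    label = raw$label,
    category = raw$category,
    unit_cost = raw$unit_cost,
    quantity = raw$quantity,
    amount = amount,
    attributable_fraction = raw$attributable_fraction,
    stringsAsFactors = FALSE
  )
  class(out) <- c("cost_ledger", class(out))
  out
}

#' Aggregate a cost ledger into per-category and per-child costs
#'
#' Sums item amounts within each of the four cost categories and divides by
#' the number of children in the intervention group to obtain per-child
#' figures. Under the assumption that the comparator (current practice)
#' carries zero additional cost, the per-child total is the incremental
#' cost per child.
#'
#' @param items A `cost_ledger` data frame (or any data frame with
#'   `category` and `amount` columns).
#' @param n_children Number of children over which costs are averaged
#'   (the completers of the intervention arm).
#' @param total_override Optional grand total (2014 USD) used instead of the
#'   sum of category subtotals, for reproducing published totals whose
#'   category breakdown was rounded independently.
#' @return An object of class `cost_summary`: a list with
#'   `category_totals`, `total`, `n_children`, `per_child_total`,
#'   `per_child_by_category` and `category_shares` (percent).
#' @export
#' @examples
#' ledger <- read_cost_ledger(
#'   system.file("extdata", "chnudev_costs.csv", package = "nutricea")
#' )
#' summarize_costs(ledger, n_children = 227)
summarize_costs <- function(items, n_children, total_override = NULL) {
  if (!is.numeric(n_children) || length(n_children) != 1 || n_children <= 0) {
    stop("n_children must be a single positive number", call. = FALSE)
  }
  if (nrow(items) == 0) {
    stop("cost ledger is empty", call. = FALSE)
  }
  totals <- stats::setNames(numeric(length(cost_categories())), cost_categories())
  agg <- tapply(items$amount, items$category, sum)
  totals[names(agg)] <- agg
  total <- if (is.null(total_override)) sum(totals) else total_override
  structure(
    list(
      category_totals = totals,
      total = total,
      n_children = n_children,
      per_child_total = total / n_children,
      per_child_by_category = totals / n_children,
      category_shares = 100 * totals / sum(totals)
    ),
    class = "cost_summary"
  )
}

#' Scale cost categories by multipliers
#'
#' Applies per-category scaling factors to a cost summary, as used by the
#' one-way and probabilistic sensitivity analyses (e.g. personnel cost
#' reduced by 50% or increased by 20%). Categories without a factor keep
#' factor 1. The grand total is adjusted by each category's change so that
#' an all-ones multiplier map is an exact identity even when the summary
#' carries an overridden total.
#'
#' @param summary A `cost_summary`.
#' @param multipliers Named numeric vector or list mapping category names to
#'   non-negative factors.
#' @return A new `cost_summary` with scaled categories and re-derived totals.
#' @export
#' @examples
#' ledger <- read_cost_ledger(
#'   system.file("extdata", "chnudev_costs.csv", package = "nutricea")
#' )
#' base <- summarize_costs(ledger, n_children = 227)
#' apply_multipliers(base, c(personnel = 0.5))$per_child_total
apply_multipliers <- function(summary, multipliers) {
  stopifnot(inherits(summary, "cost_summary"))
  multipliers <- unlist(multipliers)
  if (length(multipliers) > 0 && is.null(names(multipliers))) {
    stop("multipliers must be named by cost category", call. = FALSE)
  }
  unknown <- setdiff(names(multipliers), cost_categories())
  if (length(unknown) > 0) {
    stop("unknown cost category in multipliers: ", unknown[1], call. = FALSE)
  }
  if (any(multipliers < 0)) {
    stop("multipliers must be non-negative", call. = FALSE)
  }
  factors <- stats::setNames(rep(1, length(cost_categories())), cost_categories())
  factors[names(multipliers)] <- multipliers
  new_totals <- summary$category_totals * factors
  # adjust the stored total by the category deltas so an overridden total
  # survives an identity application unchanged
  new_total <- summary$total + sum(new_totals - summary$category_totals)
  structure(
    list(
      category_totals = new_totals,
      total = new_total,
      n_children = summary$n_children,
      per_child_total = new_total / summary$n_children,
      per_child_by_category = new_totals / summary$n_children,
      category_shares = 100 * new_totals / sum(new_totals)
    ),
    class = "cost_summary"
  )
}

#' @export
print.cost_summary <- function(x, digits = 2, ...) {
  cat("Intervention cost summary (2014 USD)\n")
  tab <- data.frame(
    category = names(x$category_totals),
    total = round(x$category_totals, digits),
    share_pct = round(x$category_shares, 1),
    per_child = round(x$per_child_by_category, digits),
    row.names = NULL
  )
  print(tab, ...)
  cat(
    sprintf(
      "Total: $%.2f over %d children -> $%.2f per child\n",
      x$total, x$n_children, x$per_child_total
    )
  )
  invisible(x)
}

#' Fixed 2014 exchange rate, Uganda shillings per US dollar
#'
#' Display-conversion constant for the 2014 costing year
#' (UGX per 1 USD).
#' @export
UGX_PER_USD <- 2523
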