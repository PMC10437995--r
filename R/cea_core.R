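# Deterministic cost-effectiveness algebra: ICER, net monetary benefit,
# quadrant classification, and DALY-weight thresholds.

#' Incremental cost-effectiveness ratio with quadrant classification
#'
#' Computes the ICER `delta_c / delta_e` and classifies the pair on the
#' cost-effectiveness plane. The ratio is reported only where it is
#' decision-relevant: in the NE quadrant (more costly, more effective,
#' positive finite ICER) and the SW quadrant (cheaper, less effective,
#' interpreted as savings per score unit forgone). A cheaper and more
#' effective intervention is flagged `dominant` (SE), a costlier and less
#' effective one `dominated` (NW); zero incremental effect with positive
#' incremental cost is dominated with an infinite ICER.
#'
#' @param delta_c Incremental cost per child (2014 USD).
#' @param delta_e Incremental cognitive composite score (score units).
#' @return An object of class `cea_result`: list with `delta_c`, `delta_e`,
#'   `icer` (NA where a dominance flag replaces it), `quadrant`
#'   (`"NE"`, `"SE"`, `"NW"`, `"SW"`) and `dominance`
#'   (`"none"`, `"dominant"`, `"dominated"`).
#' @export
#' @examples
#' icer(265.79, 16.11)
icer <- function(delta_c, delta_e) {
  if (!is.finite(delta_c) || !is.finite(delta_e)) {
    stop("delta_c and delta_e must be finite", call. = FALSE)
  }
  if (delta_e > 0 && delta_c > 0) {
    quadrant <- "NE"; dominance <- "none"; ratio <- delta_c / delta_e
  } else if (delta_e > 0) {
    quadrant <- "SE"; dominance <- "dominant"; ratio <- NA_real_
  } else if (delta_e < 0 && delta_c > 0) {
    quadrant <- "NW"; dominance <- "dominated"; ratio <- NA_real_
  } else if (delta_e < 0 && delta_c < 0) {
    quadrant <- "SW"; dominance <- "none"; ratio <- delta_c / delta_e
  } else if (delta_e == 0 && delta_c > 0) {
    quadrant <- "NW"; dominance <- "dominated (infinite ICER)"
    ratio <- Inf
  } else {
    # delta_e == 0 and delta_c <= 0, or both zero: nothing lost
    quadrant <- if (delta_c < 0) "SW" else "NE"
    dominance <- if (delta_c < 0) "dominant" else "none"
    ratio <- NA_real_
  }
  structure(
    list(delta_c = delta_c, delta_e = delta_e, icer = ratio,
         quadrant = quadrant, dominance = dominance),
    class = "cea_result"
  )
}

#' @export
print.cea_result <- function(x, digits = 2, ...) {
  cat(sprintf(
    "Incremental cost $%.2f, incremental effect %.2f (quadrant %s)\n",
    x$delta_c, x$delta_e, x$quadrant
  ))
  if (is.finite(x$icer)) {
    cat(sprintf("ICER: $%.*f per cognitive composite score unit\n",
                digits, x$icer))
  } else {
    cat("ICER not reported:", x$dominance, "\n")
  }
  invisible(x)
}

#' Net monetary benefit
#'
#' `nmb = wtp * delta_e - delta_c`: the monetary value of the incremental
#' effect at willingness-to-pay `wtp` minus the incremental cost. Positive
#' net monetary benefit means the intervention is cost-effective at that
#' threshold. Vectorized over `wtp`.
#'
#' @param delta_c Incremental cost (USD).
#' @param delta_e Incremental effect (score units).
#' @param wtp Willingness to pay per score unit (USD, non-negative).
#' @return Net monetary benefit in USD.
#' @export
#' @examples
#' nmb(265.79, 16.11, wtp = 8)
nmb <- function(delta_c, delta_e, wtp) {
  if (any(wtp < 0)) stop("wtp must be non-negative", call. = FALSE)
  wtp * delta_e - delta_c
}

#' Break-even DALY weight for cost-effectiveness
#'
#' The smallest avoided-disability weight `w` at which the intervention's
#' cost per DALY averted, `delta_c / (w * duration_years)`, does not exceed
#' the willingness to pay per DALY: `w* = delta_c / (wtp_per_daly *
#' duration_years)`. Links the score-based ICER to generic DALY thresholds
#' (e.g. 1x or 3x GDP per capita) under an assumed duration of the
#' cognitive benefit.
#'
#' @param delta_c Incremental cost per child (USD).
#' @param wtp_per_daly Willingness to pay per DALY averted (USD, > 0).
#' @param duration_years Assumed duration of the health effect (> 0).
#' @return The threshold disability weight (dimensionless).
#' @export
#' @examples
#' daly_weight_threshold(265.79, wtp_per_daly = 2610, duration_years = 60)
daly_weight_threshold <- function(delta_c, wtp_per_daly, duration_years) {
  if (delta_c <= 0 || wtp_per_daly <= 0 || duration_years <= 0) {
    stop("delta_c, wtp_per_daly and duration_years must be positive",
         call. = FALSE)
  }
  delta_c / (wtp_per_daly * duration_years)
}
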