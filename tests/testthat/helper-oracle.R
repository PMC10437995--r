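# Independent analytic oracle for the acceptability curve: the probability
# of positive net monetary benefit under a normal effect and a sum of
# independent uniform cost components, computed by numerical convolution
# on a grid rather than by Monte Carlo.

# Density of the sum of independent uniforms over absolute bounds
# comps = list(c(lo, hi), ...), on a grid of step h.
density_of_cost_sum <- function(comps, h = 0.01) {
  f <- NULL
  start <- 0
  for (b in comps) {
    w <- b[2] - b[1]
    m <- max(1L, round(w / h))
    g <- rep(1 / (m * h), m)
    if (is.null(f)) {
      f <- g
    } else {
      f <- stats::convolve(f, rev(g), type = "open") * h
    }
    start <- start + b[1]
  }
  list(x = start + (seq_along(f) - 0.5) * h, d = f, h = h)
}

# P(lambda * E - C > 0) with E ~ Normal(mu, se) independent of C.
ceac_analytic <- function(lambda, mu, se, comps, h = 0.01) {
  dens <- density_of_cost_sum(comps, h)
  vapply(lambda, function(l) {
    if (l == 0) return(0)
    sum(dens$d * stats::pnorm(dens$x / l, mu, se, lower.tail = FALSE)) * dens$h
  }, numeric(1))
}

# Absolute cost-component bounds for the default PSA distributions.
default_cost_components <- function(per_child_by_category,
                                    ranges = default_cost_ranges()) {
  lapply(names(ranges), function(cat) {
    per_child_by_category[[cat]] * ranges[[cat]]
  })
}
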