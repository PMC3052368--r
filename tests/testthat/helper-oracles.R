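# Independent oracles, deliberately written from first principles rather
# than through the package's code paths.

# Closed-form OLS via the normal equations.
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  se_slope <- if (n > 2) sqrt(ss_res / (n - 2) / sxx) else NA_real_
  p <- if (n > 2) 2 * stats::pt(abs(slope / se_slope), n - 2,
                                lower.tail = FALSE) else NA_real_
  list(intercept = intercept, slope = slope, r_squared = r2, p = p)
}

# Brute-force double loop over (cohort birth day, neuron age): the
# recruitment sum written with scalar arithmetic only.
brute_recruitment <- function(scale, exponent, start, intercept, slope,
                              maturation, t) {
  total <- 0
  for (tau in seq_len(t)) {
    if (tau < start) next
    age <- t - tau
    if (age < maturation) next
    p <- intercept + slope * age
    if (p < 0) p <- 0
    total <- total + scale * tau^exponent * p
  }
  total
}

brute_cumulative <- function(scale, exponent, start, t) {
  total <- 0
  for (tau in seq_len(t)) {
    if (tau >= start) total <- total + scale * tau^exponent
  }
  total
}

paper_fit <- function() fit_responsiveness(response_points())
paper_survival <- function() power_survival_model()
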