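#' Observed responsiveness of adult-born granule neurons
#'
#' The three group-mean observations of the fraction of BrdU-labelled
#' granule neurons that expressed Arc in response to spatial exploration,
#' as a function of neuron age: 5.0% at 30 days, 4.8% at 45 days and 2.8%
#' at 150 days (the 5-month point comes from an earlier study with the
#' same labelling protocol).
#'
#' @return A data frame with columns `age_days` and `fraction_responding`.
#' @examples
#' fit_responsiveness(response_points())
#' @export
response_points <- function() {
  data.frame(
    age_days = c(30, 45, 150),
    fraction_responding = c(0.050, 0.048, 0.028)
  )
}

#' Read responsiveness observations from CSV
#'
#' Expects a two-column file with header `age_days,fraction_responding`.
#' With `percent = TRUE` the second column is interpreted as percentages
#' and divided by 100; internally all proportions are fractions.
#'
#' @param path Path to a CSV file.
#' @param percent Logical; is the responding column in percent?
#' @return A validated data frame of response points.
#' @export
read_response_points <- function(path, percent = FALSE) {
  pts <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age_days", "fraction_responding")
  if (!all(need %in% names(pts))) {
    stop("response-point CSV must have columns: ", paste(need, collapse = ", "))
  }
  pts <- pts[, need]
  if (percent) pts$fraction_responding <- pts$fraction_responding / 100
  validate_response_points(pts)
  pts
}

validate_response_points <- function(points) {
  if (!is.data.frame(points) ||
      !all(c("age_days", "fraction_responding") %in% names(points))) {
    stop("`points` must be a data frame with columns age_days and fraction_responding")
  }
  if (nrow(points) < 2) stop("need at least 2 response points")
  if (any(!is.finite(points$age_days)) || any(points$age_days < 0)) {
    stop("age_days must be finite and non-negative")
  }
  fr <- points$fraction_responding
  if (any(!is.finite(fr)) || any(fr < 0 | fr > 1)) {
    stop("fraction_responding must lie in [0, 1]")
  }
  invisible(points)
}

#' Fit the linear responsiveness model
#'
#' Ordinary least squares of the fraction of neurons responding to spatial
#' exploration on neuron age (days), `fraction = a + r * age`. The fitted
#' line is parametrized by its age-0 intercept `a` and slope `r` per day;
#' for a declining line the extrapolated zero crossing `-a / r` is the
#' neuron age beyond which the model predicts no response.
#'
#' In recruitment mode (see [response_probability()]) the probability is
#' additionally floored at zero below `maturation_age_days`, reflecting
#' that the exploration-specific Arc response only develops once a neuron
#' is about 30 days old.
#'
#' @param points Data frame with columns `age_days`, `fraction_responding`.
#' @param maturation_age_days Neuron age (days) below which recruitment-mode
#'   probability is 0. Default 30.
#' @return An object of class `responsiveness_fit` with components
#'   `intercept_at_birth`, `slope_per_day`, `r_squared`, `slope_p_value`,
#'   `zero_crossing_age_days` (NA when the slope is not negative),
#'   `maturation_age_days`, `n_points` and the input `points`.
#' @examples
#' fit <- fit_responsiveness(response_points())
#' round(fit$r_squared, 4)
#' round(fit$zero_crossing_age_days)
#' @export
fit_responsiveness <- function(points, maturation_age_days = 30) {
  validate_response_points(points)
  if (maturation_age_days <= 0) stop("maturation_age_days must be positive")
  if (length(unique(points$age_days)) < 2) {
    stop("degenerate input: need at least 2 distinct ages to fit a line")
  }
  fit <- stats::lm(fraction_responding ~ age_days, data = points)
  a <- unname(stats::coef(fit)[1])
  r <- unname(stats::coef(fit)[2])
  if (stats::sd(points$fraction_responding) == 0) r <- 0  # flat data
  sm <- suppressWarnings(summary(fit))
  r2 <- sm$r.squared
  if (!is.finite(r2)) r2 <- NA_real_   # flat data: zero total variance
  pv <- if (stats::df.residual(fit) > 0 && nrow(sm$coefficients) >= 2) {
    unname(sm$coefficients[2, 4])
  } else {
    NA_real_                           # exact 2-point fit: no residual df
  }
  zc <- if (is.finite(r) && r < 0) -a / r else NA_real_
  structure(
    list(
      intercept_at_birth = a,
      slope_per_day = r,
      r_squared = r2,
      slope_p_value = pv,
      zero_crossing_age_days = zc,
      maturation_age_days = maturation_age_days,
      n_points = nrow(points),
      points = points
    ),
    class = "responsiveness_fit"
  )
}

#' @export
print.responsiveness_fit <- function(x, ...) {
  cat("Linear responsiveness model: P(age) = a + r * age\n")
  cat(sprintf("  intercept at birth (a): %.6f\n", x$intercept_at_birth))
  cat(sprintf("  slope per day (r):      %.6g\n", x$slope_per_day))
  cat(sprintf("  R-squared:              %.4f\n", x$r_squared))
  if (is.finite(x$slope_p_value)) {
    cat(sprintf("  slope p-value:          %.4f\n", x$slope_p_value))
  }
  if (is.finite(x$zero_crossing_age_days)) {
    cat(sprintf("  zero crossing:          %.2f days (~%d)\n",
                x$zero_crossing_age_days, round(x$zero_crossing_age_days)))
  } else {
    cat("  zero crossing:          undefined (slope not negative)\n")
  }
  cat(sprintf("  maturation age:         %d days; fitted on %d points\n",
              x$maturation_age_days, x$n_points))
  invisible(x)
}

#' Age at which the responsiveness line reaches zero
#'
#' Solves `a + r * age = 0` for a fitted declining line. Rounded to the
#' nearest day this gives the headline age beyond which adult-born neurons
#' are predicted to no longer respond to spatial exploration.
#'
#' @param model A `responsiveness_fit`.
#' @return Zero-crossing age in days (unrounded).
#' @export
zero_crossing_age <- function(model) {
  stopifnot(inherits(model, "responsiveness_fit"))
  r <- model$slope_per_day
  if (!is.finite(r) || r >= 0) {
    stop("no zero crossing: slope must be negative for the line to reach 0")
  }
  -model$intercept_at_birth / r
}

#' Probability that an adult-born neuron responds at a given age
#'
#' Evaluates the fitted line, clamped below at 0 (ages beyond the zero
#' crossing contribute nothing). In `"recruitment"` mode the probability is
#' additionally 0 for ages below the model's maturation age, because the
#' exploration-specific response has not yet developed; `"raw"` mode
#' returns the clamped line everywhere.
#'
#' @param model A `responsiveness_fit`.
#' @param age_days Neuron age(s) in days, non-negative. Vectorized.
#' @param mode `"recruitment"` (default) or `"raw"`.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
response_probability <- function(model, age_days,
                                 mode = c("recruitment", "raw")) {
  stopifnot(inherits(model, "responsiveness_fit"))
  mode <- match.arg(mode)
  if (any(!is.finite(age_days)) || any(age_days < 0)) {
    stop("age_days must be finite and non-negative")
  }
  p <- pmax(0, model$intercept_at_birth + model$slope_per_day * age_days)
  if (mode == "recruitment") p[age_days < model$maturation_age_days] <- 0
  p
}
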