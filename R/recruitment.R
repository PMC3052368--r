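#' Predicted recruitment of adult-born neurons across the life span
#'
#' Convolves cohort survival with age-dependent responsiveness: for each
#' animal age `t`, the predicted number of adult-born neurons responding
#' to spatial exploration is
#' \deqn{R(t) = \sum_{\tau = start}^{t - maturation} N(\tau) \, P(t - \tau)}
#' where `N` is the surviving-cohort curve and `P` the recruitment-mode
#' responsiveness probability (0 below the maturation age and beyond the
#' zero crossing). Sums are daily; cohorts are indexed by birth day.
#'
#' The first animal age with a non-zero count is
#' `start_age_days + maturation_age_days` (day 100 in the reference
#' parametrization); this onset also defines the alternative day axis used
#' by [peak_recruitment()].
#'
#' @param survival A `power_survival` model.
#' @param response A `responsiveness_fit`.
#' @param t_max Last animal age (days) to evaluate; must be at least
#'   `start_age_days + maturation_age_days`.
#' @return A data frame of class `recruitment_curve` with columns
#'   `age_days` (1..t_max) and `count`, and attributes `start_age_days`,
#'   `maturation_age_days`, `onset_age_days`.
#' @examples
#' curve <- recruitment_curve(power_survival_model(),
#'                            fit_responsiveness(response_points()), 600)
#' peak_recruitment(curve)
#' @export
recruitment_curve <- function(survival, response, t_max) {
  stopifnot(inherits(survival, "power_survival"),
            inherits(response, "responsiveness_fit"))
  start <- survival$start_age_days
  mat <- response$maturation_age_days
  if (start < 1 || mat <= 0) {
    stop("configuration error: non-positive cohort or maturation window")
  }
  if (t_max < start + mat) {
    stop("configuration error: t_max must be at least start_age_days + maturation_age_days")
  }
  ages <- seq_len(t_max)
  counts <- numeric(t_max)
  for (t in ages) {
    last <- t - mat
    if (last < start) next
    tau <- start:last
    counts[t] <- sum(cohort_size(survival, tau) *
                       response_probability(response, t - tau, "recruitment"))
  }
  structure(
    data.frame(age_days = ages, count = counts),
    start_age_days = start,
    maturation_age_days = mat,
    onset_age_days = start + mat,
    class = c("recruitment_curve", "data.frame")
  )
}

#' Locate the peak of a recruitment curve
#'
#' Returns the animal age at which the predicted number of responding
#' adult-born neurons is maximal (smallest age on ties) and the count
#' there. The peak day is also reported on the recruitment-onset axis
#' (`onset_day`), where day 1 is the first animal age at which a matured
#' adult-born cohort can respond (`start + maturation`); the published
#' headline peak day counts on this convolution-grid axis, which is how
#' the printed peak day, peak count and population share are jointly
#' consistent. An all-zero curve yields a degenerate result with `NA` age
#' rather than an error.
#'
#' @param curve A `recruitment_curve`.
#' @return A list of class `recruitment_peak` with `age_days`, `count`,
#'   `onset_day` and `degenerate`.
#' @export
peak_recruitment <- function(curve) {
  stopifnot(inherits(curve, "recruitment_curve"))
  if (nrow(curve) == 0) stop("empty curve")
  onset <- attr(curve, "onset_age_days")
  if (all(curve$count == 0)) {
    return(structure(
      list(age_days = NA_real_, count = 0, onset_day = NA_real_,
           degenerate = TRUE),
      class = "recruitment_peak"
    ))
  }
  i <- which.max(curve$count)  # first maximum: smallest age on ties
  age <- curve$age_days[i]
  structure(
    list(age_days = age, count = curve$count[i],
         onset_day = age - onset + 1, degenerate = FALSE),
    class = "recruitment_peak"
  )
}

#' @export
print.recruitment_peak <- function(x, ...) {
  if (x$degenerate) {
    cat("Recruitment peak: degenerate (all-zero curve)\n")
  } else {
    cat(sprintf(
      "Recruitment peak: %d cells at animal age %d d (day %d of recruitment)\n",
      round(x$count), round(x$age_days), round(x$onset_day)))
  }
  invisible(x)
}

#' Share of the responding population that is adult-born
#'
#' @param peak_count Predicted responding adult-born cells (e.g. at the
#'   recruitment peak).
#' @param total_responding Total granule cells responding to exploration
#'   in the same region (must be positive).
#' @return Percentage `100 * peak_count / total_responding`.
#' @examples
#' recruitment_share(2057, 3465)  # about 59.4
#' @export
recruitment_share <- function(peak_count, total_responding) {
  if (!is.finite(total_responding) || total_responding <= 0) {
    stop("total_responding must be positive")
  }
  100 * peak_count / total_responding
}

#' Two-segment model of early non-specific Arc expression
#'
#' Young granule neurons (1--30 days old) express Arc without behavioral
#' stimulation. This probability is modelled with two linear segments of
#' neuron age: segment 1 on `[1, breakpoint]`, segment 2 on
#' `(breakpoint, window_end]`; the probability is 0 outside the window.
#'
#' @param segment1,segment2 Length-2 numeric vectors `c(intercept, slope)`.
#' @param breakpoint Days, strictly between 1 and `window_end`.
#' @param window_end Last neuron age (days) of the early window. Default 30.
#' @return An object of class `early_expression_model`.
#' @seealso [calibrate_early_expression()] for the default calibration
#'   from the cage-control observations.
#' @export
early_expression_model <- function(segment1, segment2, breakpoint = 15,
                                   window_end = 30) {
  stopifnot(length(segment1) == 2, length(segment2) == 2)
  if (!(breakpoint > 1 && breakpoint < window_end)) {
    stop("breakpoint must lie strictly between 1 and window_end")
  }
  m <- structure(
    list(segment1 = as.numeric(segment1), segment2 = as.numeric(segment2),
         breakpoint = breakpoint, window_end = window_end),
    class = "early_expression_model"
  )
  p <- early_expression_probability(m, seq_len(window_end))
  if (any(p < 0 | p > 1)) {
    stop("validation error: early-expression segments leave [0, 1] in-window")
  }
  m
}

#' Calibrate the early-expression model from observed fractions
#'
#' Default calibration: segment 1 is the OLS line through the cage-control
#' (age, fraction Arc-positive among BrdU-positive) observations at 1, 7
#' and 15 days (1.3%, 2.1%, 2.3%); segment 2 is the line through the
#' 15-day observation and the 30-day one (1.5%), with the breakpoint at
#' 15 days.
#'
#' @param ages,fractions Observations for segment 1.
#' @param breakpoint Days; also the age of the last segment-1 observation.
#' @param end_age,end_fraction The observation anchoring the far end of
#'   segment 2.
#' @return An `early_expression_model`.
#' @export
calibrate_early_expression <- function(ages = c(1, 7, 15),
                                       fractions = c(0.013, 0.021, 0.023),
                                       breakpoint = 15,
                                       end_age = 30, end_fraction = 0.015) {
  stopifnot(length(ages) == length(fractions), length(ages) >= 2)
  fit <- stats::lm(fractions ~ ages)
  seg1 <- unname(stats::coef(fit))
  bp_value <- fractions[which(ages == breakpoint)]
  if (length(bp_value) != 1) {
    stop("breakpoint must coincide with one of the segment-1 ages")
  }
  slope2 <- (end_fraction - bp_value) / (end_age - breakpoint)
  seg2 <- c(bp_value - slope2 * breakpoint, slope2)
  early_expression_model(seg1, seg2, breakpoint = breakpoint,
                         window_end = end_age)
}

#' Evaluate the early non-specific expression probability
#'
#' @param model An `early_expression_model`.
#' @param age_days Neuron age(s) in days. Vectorized; 0 outside
#'   `[1, window_end]`.
#' @return Numeric vector of probabilities.
#' @export
early_expression_probability <- function(model, age_days) {
  stopifnot(inherits(model, "early_expression_model"))
  p <- ifelse(age_days <= model$breakpoint,
              model$segment1[1] + model$segment1[2] * age_days,
              model$segment2[1] + model$segment2[2] * age_days)
  p[age_days < 1 | age_days > model$window_end] <- 0
  p
}

#' Relative abundance of young cohorts before attrition completes
#'
#' About 80% of newborn granule cells die during their first month, so a
#' cohort observed at 1--30 days of age is larger than its stable
#' (30-day-survivor) size. This profile is the observed BrdU-positive
#' fraction time course (0.26%, 0.35%, 0.23%, 0.17% and 0.15% at 1, 7,
#' 15, 30 and 45 days after labelling) normalized to the stable 0.15%,
#' interpolated linearly between observation days. It converts the
#' survivor curve `N(tau)` into the number of cells actually found at a
#' young age, which is what the early-background convolution counts.
#'
#' @return A data frame with columns `age_days` and `relative_size`.
#' @export
young_attrition_profile <- function() {
  data.frame(
    age_days = c(1, 7, 15, 30, 45),
    relative_size = c(0.26, 0.35, 0.23, 0.17, 0.15) / 0.15
  )
}

#' Background curve of non-specific Arc expression in young neurons
#'
#' Convolves the cohorts currently aged 1--30 days with the two-segment
#' early-expression probability and divides by the granule population, to
#' estimate the proportion of all granule cells that express Arc with no
#' stimulation purely because they are recently born. By default each
#' cohort is weighted by [young_attrition_profile()] so that it enters at
#' its as-found size rather than its post-attrition survivor size; pass
#' `attrition = NULL` to use the survivor curve directly.
#'
#' @param early An `early_expression_model`.
#' @param survival A `power_survival` model.
#' @param granule_total Granule cells in the reference region (positive);
#'   231,000 for the whole sample region.
#' @param t_max Last animal age (days) to evaluate.
#' @param attrition Data frame with columns `age_days`, `relative_size`,
#'   or `NULL` for no weighting.
#' @return A data frame of class `background_curve` with columns
#'   `age_days`, `proportion`, and attribute `max_proportion`.
#' @examples
#' bg <- early_background_curve(calibrate_early_expression(),
#'                              power_survival_model(), 231000, 300)
#' 100 * attr(bg, "max_proportion")  # percent, about 0.17
#' @export
early_background_curve <- function(early, survival, granule_total, t_max,
                                   attrition = young_attrition_profile()) {
  stopifnot(inherits(early, "early_expression_model"),
            inherits(survival, "power_survival"))
  if (!is.finite(granule_total) || granule_total <= 0) {
    stop("granule_total must be positive")
  }
  wfun <- if (is.null(attrition)) {
    function(a) rep(1, length(a))
  } else {
    stats::approxfun(attrition$age_days, attrition$relative_size, rule = 2)
  }
  win <- seq_len(early$window_end)
  p_early <- early_expression_probability(early, win)
  w <- wfun(win)
  start <- survival$start_age_days
  ages <- seq_len(t_max)
  prop <- numeric(t_max)
  for (t in ages) {
    tau <- t - win
    keep <- tau >= start
    if (!any(keep)) next
    prop[t] <- sum(cohort_size(survival, tau[keep]) * w[keep] *
                     p_early[keep]) / granule_total
  }
  structure(
    data.frame(age_days = ages, proportion = prop),
    max_proportion = max(prop),
    start_age_days = start,
    class = c("background_curve", "data.frame")
  )
}

#' Background expression as a share of a reference Arc fraction
#'
#' Compares the maximum unstimulated background proportion with a
#' reference Arc fraction of the granule population: against the
#' cage-control fraction (0.31%) this asks what share of baseline Arc
#' expression could be young neurons; against the exploration fraction
#' (1.5%) it asks how much of the exploration response the background
#' could account for.
#'
#' @param background_max Maximum background proportion (fraction).
#' @param arc_fraction Reference Arc fraction of the granule population
#'   (fraction, positive).
#' @return Percentage `100 * background_max / arc_fraction`.
#' @export
background_share <- function(background_max, arc_fraction) {
  if (!is.finite(arc_fraction) || arc_fraction <= 0) {
    stop("arc_fraction must be positive")
  }
  100 * background_max / arc_fraction
}

#' Write a curve as a two-column CSV
#'
#' @param curve A `recruitment_curve` or `background_curve` (or any data
#'   frame whose first two columns are the day grid and the value).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve)[, 1:2], path, row.names = FALSE)
  invisible(path)
}
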