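#' Power-law cohort survival model
#'
#' Constructs the model `N(tau) = scale * tau ^ exponent` for the number of
#' granule neurons born on animal-age day `tau` that survive past the
#' 30-day maturation window (and are then assumed immortal). The curve is
#' anchored so that it passes exactly through `(anchor_age_days,
#' anchor_count)` — by default the observed 345 BrdU-positive cells of the
#' cohort counted 45 days after labelling, at animal age 150 days.
#'
#' When `exponent` is `NULL` it is solved from the scale and the anchor
#' (see [solve_exponent_from_scale()]); this is the reference
#' parametrization with `scale = 2218.2`. When `exponent` is supplied, the
#' scale is (re-)set from the anchor, so anchoring is idempotent.
#'
#' @param scale Cells; `N(1)`. Must be positive. Default 2218.2.
#' @param exponent Dimensionless power (negative for a declining curve),
#'   or `NULL` to solve it from `scale` and the anchor.
#' @param anchor_age_days,anchor_count The anchor constraint. Defaults 150
#'   days and 345 cells.
#' @param start_age_days First animal-age day whose births are counted;
#'   70 (sexual maturity) for the adult-only analysis, 1 for the postnatal
#'   variant.
#' @return An object of class `power_survival`.
#' @examples
#' m <- power_survival_model()
#' cohort_size(m, 150)  # 345, by construction
#' @export
power_survival_model <- function(scale = 2218.2, exponent = NULL,
                                 anchor_age_days = 150, anchor_count = 345,
                                 start_age_days = 70) {
  if (!is.finite(scale) || scale <= 0) stop("scale must be positive")
  if (anchor_count <= 0) stop("anchor_count must be positive")
  if (start_age_days < 1) stop("start_age_days must be >= 1")
  if (is.null(exponent)) {
    exponent <- solve_exponent_from_scale(scale, anchor_age_days, anchor_count)
  } else {
    if (anchor_age_days < 1) stop("anchor_age_days must be >= 1")
    scale <- anchor_count / anchor_age_days^exponent
  }
  structure(
    list(
      scale = scale,
      exponent = exponent,
      anchor_age_days = anchor_age_days,
      anchor_count = anchor_count,
      start_age_days = start_age_days
    ),
    class = "power_survival"
  )
}

#' @export
print.power_survival <- function(x, ...) {
  cat("Power survival model: N(tau) = scale * tau^exponent\n")
  cat(sprintf("  scale:    %.4f cells\n", x$scale))
  cat(sprintf("  exponent: %.5f\n", x$exponent))
  cat(sprintf("  anchored: N(%g) = %g; cohorts counted from day %d\n",
              x$anchor_age_days, x$anchor_count, x$start_age_days))
  invisible(x)
}

#' Solve the survival exponent from the scale and anchor
#'
#' Inverts `scale * age ^ s = count`:
#' `s = log(count / scale) / log(age)`. Used to recover the published
#' exponent from the reference scale 2218.2 and the anchor N(150) = 345.
#'
#' @param scale Cells, positive.
#' @param anchor_age Days, must exceed 1 (log(1) = 0 is degenerate).
#' @param anchor_count Cells, positive.
#' @return The exponent `s`.
#' @examples
#' solve_exponent_from_scale(2218.2, 150, 345)  # about -0.3714
#' @export
solve_exponent_from_scale <- function(scale, anchor_age, anchor_count) {
  if (!is.finite(scale) || scale <= 0) stop("scale must be positive")
  if (!is.finite(anchor_count) || anchor_count <= 0) {
    stop("anchor_count must be positive")
  }
  if (!is.finite(anchor_age) || anchor_age <= 1) {
    stop("anchor_age must be greater than 1")
  }
  log(anchor_count / scale) / log(anchor_age)
}

#' Read proliferation observations from CSV
#'
#' Two-column file with header `animal_age_days,surviving_cohort_size`:
#' each row is the number of one day's births (at that animal age) that
#' survive at least 30 days.
#'
#' @param path Path to a CSV file.
#' @return A validated data frame.
#' @export
read_proliferation <- function(path) {
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_age_days", "surviving_cohort_size")
  if (!all(need %in% names(obs))) {
    stop("proliferation CSV must have columns: ", paste(need, collapse = ", "))
  }
  obs[, need]
}

#' Fit the power survival model to proliferation data
#'
#' The exponent comes from OLS of log(count) on log(age); the scale is
#' then set so the curve passes exactly through the anchor, matching how
#' the published curve is tied to the observed 45-day cohort rather than
#' to the regression intercept. The unanchored scale `exp(intercept)` is
#' retained in the returned object for diagnostics.
#'
#' @param observations Data frame with columns `animal_age_days`,
#'   `surviving_cohort_size`, all positive.
#' @inheritParams power_survival_model
#' @return A `power_survival` model with extra fields `scale_unanchored`
#'   and `loglog_r_squared`.
#' @export
fit_power_survival <- function(observations, anchor_age_days = 150,
                               anchor_count = 345, start_age_days = 70) {
  need <- c("animal_age_days", "surviving_cohort_size")
  if (!is.data.frame(observations) || !all(need %in% names(observations))) {
    stop("`observations` must have columns ", paste(need, collapse = ", "))
  }
  age <- observations$animal_age_days
  n <- observations$surviving_cohort_size
  if (any(!is.finite(age)) || any(age <= 0) || any(!is.finite(n)) || any(n <= 0)) {
    stop("ages and counts must be positive (log-log fit is undefined otherwise)")
  }
  if (length(unique(age)) < 2) {
    stop("degenerate input: need at least 2 distinct ages")
  }
  fit <- stats::lm(log(n) ~ log(age))
  exponent <- unname(stats::coef(fit)[2])
  model <- power_survival_model(
    exponent = exponent, anchor_age_days = anchor_age_days,
    anchor_count = anchor_count, start_age_days = start_age_days
  )
  model$scale_unanchored <- exp(unname(stats::coef(fit)[1]))
  model$loglog_r_squared <- suppressWarnings(summary(fit))$r.squared
  model
}

#' Size of the surviving cohort born on a given day
#'
#' Evaluates `scale * birth_age ^ exponent` (continuous, not rounded):
#' the number of neurons born when the animal was `birth_age` days old
#' that survive their first 30 days.
#'
#' @param model A `power_survival`.
#' @param birth_age Animal age(s) at birth, in days, `>= 1`. Vectorized.
#' @return Numeric vector of cell counts.
#' @export
cohort_size <- function(model, birth_age) {
  stopifnot(inherits(model, "power_survival"))
  if (any(!is.finite(birth_age)) || any(birth_age < 1)) {
    stop("birth_age must be >= 1 day")
  }
  model$scale * birth_age^model$exponent
}

#' Cumulative adult-born survivors up to an animal age
#'
#' Daily sum of cohort sizes from the model's start age through `t`,
#' inclusive at both ends (cohorts are one-day BrdU birth cohorts, so the
#' discretization step is one day). Ages before the start age return 0.
#'
#' @param model A `power_survival`.
#' @param t Animal age(s) in days. Vectorized.
#' @return Cumulative number of surviving adult-born neurons.
#' @export
cumulative_survivors <- function(model, t) {
  stopifnot(inherits(model, "power_survival"))
  if (any(!is.finite(t))) stop("t must be finite")
  start <- model$start_age_days
  out <- numeric(length(t))
  tmax <- max(floor(t), start)
  if (any(t >= start)) {
    cs <- cumsum(cohort_size(model, start:tmax))
    idx <- t >= start
    out[idx] <- cs[floor(t[idx]) - start + 1]
  }
  out
}

#' Write fitted survival parameters as JSON
#'
#' @param model A `power_survival`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_survival_json <- function(model, path) {
  stopifnot(inherits(model, "power_survival"))
  jsonlite::write_json(
    model[c("scale", "exponent", "anchor_age_days", "anchor_count",
            "start_age_days")],
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
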