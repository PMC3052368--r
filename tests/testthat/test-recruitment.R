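test_that("recruitment curve matches single-term hand computation at onset", {
  surv <- paper_survival()
  resp <- paper_fit()
  curve <- recruitment_curve(surv, resp, 120)
  expect_equal(curve$count[99], 0)  # no cohort has matured yet
  # first non-zero term: cohort born day 70, aged exactly 30
  expect_equal(curve$count[100],
               cohort_size(surv, 70) * response_probability(resp, 30),
               tolerance = 1e-12)
  expect_equal(curve$count[100], 23.0627, tolerance = 1e-4)
  expect_true(all(curve$count[seq_len(99)] == 0))
})

test_that("convolution equals the brute-force double loop on random models", {
  set.seed(7)
  for (i in 1:20) {
    scale <- runif(1, 500, 5000)
    exponent <- runif(1, -0.9, -0.1)
    start <- sample(c(1, 30, 70), 1)
    mat <- sample(c(10, 30), 1)
    intercept <- runif(1, 0.02, 0.10)
    slope <- -runif(1, 5e-5, 5e-4)
    surv <- power_survival_model(exponent = exponent, anchor_count = scale,
                                 anchor_age_days = 100,
                                 start_age_days = start)
    pts <- data.frame(age_days = c(0, 100),
                      fraction_responding = pmin(1, pmax(0, c(
                        intercept, intercept + slope * 100))))
    resp <- fit_responsiveness(pts, maturation_age_days = mat)
    tmax <- start + mat + sample(50:250, 1)
    curve <- recruitment_curve(surv, resp, tmax)
    for (t in sample(seq_len(tmax), 5)) {
      expect_equal(
        curve$count[t],
        brute_recruitment(surv$scale, surv$exponent, start,
                          resp$intercept_at_birth, resp$slope_per_day,
                          mat, t),
        tolerance = 1e-9)
    }
  }
})

test_that("curve respects the cumulative-survivor upper bound", {
  surv <- paper_survival()
  resp <- paper_fit()
  curve <- recruitment_curve(surv, resp, 500)
  pmax_win <- response_probability(resp, resp$maturation_age_days)
  for (t in c(120, 217, 318, 500)) {
    expect_lte(curve$count[t],
               cumulative_survivors(surv, t - resp$maturation_age_days) *
                 pmax_win + 1e-9)
  }
})

test_that("constant cohorts with a linear P match the arithmetic-series sum", {
  c0 <- 100
  surv <- power_survival_model(exponent = 0, anchor_count = c0,
                               anchor_age_days = 100, start_age_days = 1)
  a <- 0.05; r <- -1e-4; mat <- 30
  resp <- fit_responsiveness(
    data.frame(age_days = c(0, 100), fraction_responding = c(a, a + 100 * r)),
    maturation_age_days = mat)
  tmax <- 300
  curve <- recruitment_curve(surv, resp, tmax)
  t <- 250  # all ages mat..(t-1) in window, none beyond the zero crossing
  ages <- mat:(t - 1)
  expect_equal(curve$count[t], c0 * sum(a + r * ages), tolerance = 1e-9)
})

test_that("curve values are invariant to extending the horizon", {
  surv <- paper_survival()
  resp <- paper_fit()
  short <- recruitment_curve(surv, resp, 250)
  long <- recruitment_curve(surv, resp, 400)
  expect_equal(short$count, long$count[1:250])
})

test_that("reference curve rises to a unique interior maximum then declines", {
  curve <- recruitment_curve(paper_survival(), paper_fit(), 600)
  pk <- peak_recruitment(curve)
  i <- which(curve$age_days == pk$age_days)
  nonzero <- which(curve$count > 0)
  expect_true(i > min(nonzero) && i < 600)
  expect_true(all(diff(curve$count[min(nonzero):i]) > 0))
  expect_true(all(diff(curve$count[i:600]) < 0))
  expect_equal(sum(curve$count == max(curve$count)), 1)
})

test_that("peak location, ties and degenerate curves behave as specified", {
  curve <- recruitment_curve(paper_survival(), paper_fit(), 600)
  pk <- peak_recruitment(curve)
  expect_false(pk$degenerate)
  expect_equal(pk$onset_day, pk$age_days - 100 + 1)
  # monotone rising curve: peak at the last age
  short <- recruitment_curve(paper_survival(), paper_fit(), 150)
  expect_equal(peak_recruitment(short)$age_days, 150)
  # tie rule: smallest age wins
  tie <- short
  tie$count[c(120, 130)] <- max(tie$count) + 1
  expect_equal(peak_recruitment(tie)$age_days, 120)
  # all-zero curve flags degenerate
  zero <- recruitment_curve(paper_survival(), paper_fit(), 120)
  zero$count[] <- 0
  dg <- peak_recruitment(zero)
  expect_true(dg$degenerate)
  expect_true(is.na(dg$age_days))
})

test_that("postnatal variant dominates the adult variant pointwise", {
  resp <- paper_fit()
  adult <- recruitment_curve(paper_survival(), resp, 400)
  postnatal <- recruitment_curve(
    power_survival_model(start_age_days = 1), resp, 400)
  expect_true(all(postnatal$count >= adult$count))
  expect_true(any(postnatal$count > adult$count))
})

test_that("recruitment share is simple percentage arithmetic", {
  expect_equal(recruitment_share(2057, 3465), 59.36508, tolerance = 1e-5)
  expect_equal(recruitment_share(0, 10), 0)
  expect_equal(recruitment_share(7, 7), 100)
  expect_error(recruitment_share(1, 0), "positive")
})

test_that("configuration errors are caught before convolving", {
  expect_error(recruitment_curve(paper_survival(), paper_fit(), 99),
               "configuration error")
})

test_that("early expression model validates its segments and window", {
  m <- calibrate_early_expression()
  expect_equal(m$breakpoint, 15)
  # segment 1 is the OLS line through the three early cage-control points
  o <- ols_oracle(c(1, 7, 15), c(0.013, 0.021, 0.023))
  expect_equal(m$segment1, c(o$intercept, o$slope), tolerance = 1e-12)
  expect_equal(early_expression_probability(m, 30), 0.015, tolerance = 1e-12)
  expect_equal(early_expression_probability(m, c(0, 31, 50)), rep(0, 3))
  expect_error(early_expression_model(c(-0.5, 0), c(0, 0)), "validation")
  expect_error(early_expression_model(c(0.1, 0), c(0.1, 0), breakpoint = 40),
               "breakpoint")
})

test_that("background curve: zero model, steady state, and reference values", {
  surv <- paper_survival()
  zero <- early_expression_model(c(0, 0), c(0, 0))
  bg0 <- early_background_curve(zero, surv, 231000, 200)
  expect_true(all(bg0$proportion == 0))

  # constant probability p, constant cohorts c: steady state 30*c*p/total
  p <- 0.02; c0 <- 50; total <- 1e5
  const <- early_expression_model(c(p, 0), c(p, 0))
  flat <- power_survival_model(exponent = 0, anchor_count = c0,
                               anchor_age_days = 100, start_age_days = 1)
  bg <- early_background_curve(const, flat, total, 100, attrition = NULL)
  expect_equal(bg$proportion[60], 30 * c0 * p / total, tolerance = 1e-12)

  ref <- early_background_curve(calibrate_early_expression(), surv,
                                231000, 400)
  m <- attr(ref, "max_proportion")
  expect_gt(100 * m, 0.11)
  expect_lt(100 * m, 0.21)
  expect_equal(background_share(0.0016, 0.0031), 51.6129, tolerance = 1e-4)
  expect_equal(background_share(0, 0.01), 0)
  expect_equal(background_share(0.0016, 0.015), 10.6667, tolerance = 1e-4)
  expect_error(background_share(0.001, 0), "positive")
})
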