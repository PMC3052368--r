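layer_names <- c("SGZ", "L1", "L2", "L3")

test_that("identical seeds give identical tables and identical CSV bytes", {
  t1 <- generate_study(seed = 123)
  t2 <- generate_study(seed = 123)
  expect_identical(t1, t2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  on.exit(unlink(c(f1, f2)))
  write_animal_counts(t1, f1)
  write_animal_counts(t2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  t3 <- generate_study(seed = 124)
  expect_false(identical(t1, t3))
})

test_that("generated tables satisfy the count-record invariants", {
  for (seed in c(1, 2, 3, 4, 5)) {
    tab <- generate_study(seed = seed)
    expect_true(all(tab$brdu_arc_double <=
                      pmin(tab$brdu_positive, tab$arc_positive)))
    expect_true(all(tab$brdu_positive >= 0 & tab$arc_positive >= 0))
    per_animal <- tapply(tab$brdu_positive + tab$arc_positive,
                         tab$animal_id, sum)
    totals <- tapply(tab$total_granule_sampled, tab$animal_id, max)
    expect_true(all(per_animal <= totals))
    # no double-labelled cells in the subgranular zone, by placement rule
    expect_true(all(tab$brdu_arc_double[tab$layer == "SGZ"] == 0))
  }
})

test_that("design shape matches the study: groups, sizes, jittered totals", {
  tab <- generate_study(seed = 5)
  s <- group_summaries(tab)
  expect_equal(nrow(s$groups), 10)  # 5 days x 2 conditions
  se_sizes <- s$groups$n_animals[s$groups$condition == "SE"]
  expect_equal(se_sizes[order(s$groups$pbi_days[s$groups$condition == "SE"])],
               c(5, 4, 4, 4, 3))
  expect_true(all(s$groups$n_animals[s$groups$condition == "CC"] == 3))
  totals <- unique(tab$total_granule_sampled)
  expect_true(all(totals >= 72000 & totals <= 88000))
  expect_gt(length(totals), 1)
})

test_that("zero double-label probability yields no double-labelled cells", {
  p <- generative_params(double_label_prob = cbind(
    CC = c(`1` = 0, `7` = 0, `15` = 0, `30` = 0, `45` = 0),
    SE = c(`1` = 0, `7` = 0, `15` = 0, `30` = 0, `45` = 0)))
  tab <- generate_study(params = p, seed = 9)
  expect_true(all(tab$brdu_arc_double == 0))
})

test_that("out-of-range probabilities are rejected", {
  expect_error(generative_params(arc_base_fraction = c(CC = -0.1, SE = 0.5)),
               "validation")
  expect_error(generative_params(
    brdu_fraction_by_day = c(`1` = 1.2, `7` = 0.1, `15` = 0.1, `30` = 0.1,
                             `45` = 0.1)), "validation")
})

test_that("empirical group means converge to the generative parameters", {
  design <- study_design(pbi_days = 30, n_se = 200, n_cc = 200)
  tab <- generate_study(design, seed = 77)
  s <- group_summaries(tab)
  g <- s$groups
  se <- g[g$condition == "SE", ]
  cc <- g[g$condition == "CC", ]
  expect_equal(se$double_frac, 0.05, tolerance = 0.05)   # relative
  expect_equal(cc$double_frac, 0.015, tolerance = 0.10)
  expect_equal(se$brdu_frac, 0.0017, tolerance = 0.02)
  expect_equal(se$arc_frac, 0.015, tolerance = 0.05)
  expect_equal(cc$arc_frac, 0.003, tolerance = 0.10)
  # layer distribution of BrdU cells follows the day-30 migration profile
  dist <- unname(unlist(se[paste0("brdu_dist_", layer_names)]))
  expect_equal(dist, c(13, 54, 24, 10) / 101, tolerance = 0.05)
  # exploration-condition doubles are L1-enriched and absent from the SGZ
  ddist <- unname(unlist(se[paste0("double_dist_", layer_names)]))
  expect_equal(ddist[1], 0)
  expect_gt(ddist[2], 0.8)
})

test_that("proliferation generator is exact at zero noise and seeded", {
  obs <- generate_proliferation_data(2218.2, -0.3713914,
                                     ages = c(70, 150, 300), noise_cv = 0)
  expect_equal(obs$surviving_cohort_size[2], 345, tolerance = 1e-3)
  expect_equal(obs$surviving_cohort_size,
               2218.2 * c(70, 150, 300)^-0.3713914)
  a <- generate_proliferation_data(1000, -0.5, noise_cv = 0.2, seed = 4)
  b <- generate_proliferation_data(1000, -0.5, noise_cv = 0.2, seed = 4)
  expect_identical(a, b)
  expect_error(generate_proliferation_data(1000, -0.5, noise_cv = -0.1),
               ">= 0")
})

test_that("noisy power-law fits recover the exponent with small bias", {
  set.seed(31)
  truth <- -0.3713914
  exps_cv20 <- replicate(500, {
    obs <- generate_proliferation_data(2218.2, truth, noise_cv = 0.2)
    fit_power_survival(obs)$exponent
  })
  expect_lt(abs(mean(exps_cv20) - truth), 0.02)
  exps_cv10 <- replicate(500, {
    obs <- generate_proliferation_data(2218.2, truth, noise_cv = 0.1)
    fit_power_survival(obs)$exponent
  })
  expect_gte(mean(abs(exps_cv10 - truth) < 0.1), 0.95)
})

test_that("recovery experiment: noiseless truth is recovered exactly", {
  # replicate with all noise off: the pipeline must return the truth
  truth_resp <- fit_responsiveness(response_points())
  rep1 <- recovery_experiment(
    replicates = 1, prolif_cv = 0,
    animals_per_day = c(50, 50, 50),   # large groups shrink binomial noise
    seed = 8)
  expect_equal(nrow(rep1$results), 1)
  expect_true(rep1$results$ok)
  # proliferation noise off: the exponent is exact
  expect_equal(rep1$results$exponent, power_survival_model()$exponent,
               tolerance = 1e-9)
  expect_lt(abs(rep1$results$slope - truth_resp$slope_per_day), 5e-5)
})

test_that("recovery report records per-replicate rows and summaries", {
  rep5 <- recovery_experiment(replicates = 5, seed = 21)
  expect_equal(nrow(rep5$results), 5)
  expect_true(all(c("slope", "exponent", "peak_age", "peak_count")
                  %in% names(rep5$results)))
  expect_equal(rep5$truth$peak_age,
               peak_recruitment(recruitment_curve(
                 power_survival_model(),
                 fit_responsiveness(response_points()), 600))$age_days)
  expect_true(is.finite(rep5$summary$negative_slope_rate))
})
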