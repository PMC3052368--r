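#' Study design for synthetic count tables
#'
#' Mirrors the pulse-chase design: animals labelled with BrdU on day 0
#' are sacrificed 1, 7, 15, 30 or 45 days later, either after a 5-minute
#' spatial exploration (SE; group sizes 5, 4, 4, 4, 3) or directly from
#' the home cage (CC; 3 per day). About 80,000 granule cells are sampled
#' per animal, jittered uniformly by +/-10% so denominators differ
#' between animals.
#'
#' @param pbi_days Sacrifice days post BrdU injection.
#' @param n_se,n_cc Animals per day in each condition.
#' @param granule_cells_mean Mean sampled granule cells per animal.
#' @param granule_jitter Half-width of the uniform relative jitter on the
#'   granule total.
#' @return A list of class `study_design`.
#' @export
study_design <- function(pbi_days = c(1, 7, 15, 30, 45),
                         n_se = c(5, 4, 4, 4, 3),
                         n_cc = rep(3, length(pbi_days)),
                         granule_cells_mean = 80000,
                         granule_jitter = 0.10) {
  stopifnot(length(pbi_days) >= 1, length(n_se) == length(pbi_days),
            length(n_cc) == length(pbi_days),
            all(n_se >= 1), all(n_cc >= 1),
            granule_cells_mean > 0, granule_jitter >= 0, granule_jitter < 1)
  structure(
    list(pbi_days = pbi_days, n_se = n_se, n_cc = n_cc,
         granule_cells_mean = granule_cells_mean,
         granule_jitter = granule_jitter),
    class = "study_design"
  )
}

#' Generative parameters for synthetic count tables
#'
#' Defaults are the published group values: BrdU-positive fractions of
#' the granule total by day (0.26%, 0.35%, 0.23%, 0.17%, 0.15%); layer
#' distributions of BrdU cells by day; baseline Arc fractions of the
#' granule population (CC 0.3%, SE 1.5%); the fraction of BrdU cells that
#' are Arc-positive per day and condition (CC 1.3, 2.1, 2.3, 1.5, 0.7%;
#' SE 1.01, 1.56, 2.9, 5.0, 4.8%); and the layer placement of the
#' double-labelled cells (SE: 89.3% in L1, 1.67% in L2, remainder in L3;
#' CC: 63.78% L1, 29.56% L2, remainder L3; none in the SGZ in either
#' condition).
#'
#' @param brdu_fraction_by_day Named fractions, names = days.
#' @param layer_distribution_by_day Matrix (day x layer) of BrdU layer
#'   distributions; rows are renormalized to sum to 1.
#' @param arc_base_fraction Named fractions `c(CC = , SE = )` of granule
#'   cells expressing Arc.
#' @param double_label_prob Matrix (day x condition) of P(Arc+ | BrdU+).
#' @param double_layer_placement Matrix (condition x layer) for placing
#'   double-labelled cells.
#' @param arc_layer_distribution Placement of Arc-only cells across
#'   layers (default: uniform over the three granule layers, none in the
#'   SGZ).
#' @return A list of class `generative_params`.
#' @export
generative_params <- function(
  brdu_fraction_by_day = c(`1` = 0.0026, `7` = 0.0035, `15` = 0.0023,
                           `30` = 0.0017, `45` = 0.0015),
  layer_distribution_by_day = rbind(
    `1`  = c(SGZ = 60, L1 = 32, L2 = 7,  L3 = 1),
    `7`  = c(SGZ = 32, L1 = 54, L2 = 11, L3 = 3),
    `15` = c(SGZ = 16, L1 = 58, L2 = 19, L3 = 6),
    `30` = c(SGZ = 13, L1 = 54, L2 = 24, L3 = 10),
    `45` = c(SGZ = 12, L1 = 51, L2 = 23, L3 = 13)
  ),
  arc_base_fraction = c(CC = 0.003, SE = 0.015),
  double_label_prob = cbind(
    CC = c(`1` = 0.013, `7` = 0.021, `15` = 0.023, `30` = 0.015,
           `45` = 0.007),
    SE = c(`1` = 0.0101, `7` = 0.0156, `15` = 0.029, `30` = 0.05,
           `45` = 0.048)
  ),
  double_layer_placement = rbind(
    CC = c(SGZ = 0, L1 = 0.6378, L2 = 0.2956, L3 = 0.0666),
    SE = c(SGZ = 0, L1 = 0.893, L2 = 0.0167, L3 = 0.0903)
  ),
  arc_layer_distribution = c(SGZ = 0, L1 = 1, L2 = 1, L3 = 1) / 3
) {
  if (any(brdu_fraction_by_day < 0 | brdu_fraction_by_day > 1) ||
      any(arc_base_fraction < 0 | arc_base_fraction > 1) ||
      any(double_label_prob < 0 | double_label_prob > 1)) {
    stop("validation error: all fractions must lie in [0, 1]")
  }
  norm_rows <- function(m) sweep(m, 1, rowSums(m), "/")
  layer_distribution_by_day <- norm_rows(layer_distribution_by_day)
  double_layer_placement <- norm_rows(double_layer_placement)
  arc_layer_distribution <- arc_layer_distribution / sum(arc_layer_distribution)
  structure(
    list(
      brdu_fraction_by_day = brdu_fraction_by_day,
      layer_distribution_by_day = layer_distribution_by_day,
      arc_base_fraction = arc_base_fraction,
      double_label_prob = double_label_prob,
      double_layer_placement = double_layer_placement,
      arc_layer_distribution = arc_layer_distribution
    ),
    class = "generative_params"
  )
}

# Place `n` double-labelled cells into layers without exceeding the
# available BrdU cells per layer, with expected shares following the
# target placement where feasible. Each BrdU cell gets weight
# placement[layer] / n_brdu[layer]; sampling cells without replacement
# then yields expected layer totals proportional to the placement.
place_doubles <- function(n, brdu_by_layer, placement) {
  layers <- names(brdu_by_layer)
  out <- stats::setNames(integer(length(layers)), layers)
  if (n == 0) return(out)
  cell_layer <- rep(seq_along(layers), brdu_by_layer)
  w <- placement[cell_layer] / brdu_by_layer[cell_layer]
  if (sum(w) <= 0) {
    # target layers hold no BrdU cells: fall back to uniform placement
    w <- rep(1, length(cell_layer))
  }
  picked <- sample(cell_layer, n, prob = w)
  tab <- tabulate(picked, nbins = length(layers))
  out[] <- tab
  out
}

#' Generate a synthetic study's per-animal count table
#'
#' Emulates the counting outputs of the pulse-chase design with the
#' minimal noise model consistent with count data: per animal, the
#' sampled granule total is jittered about its mean; the BrdU-positive
#' count is binomial in the granule total with the day's labelling
#' fraction; BrdU cells are placed multinomially across layers following
#' the day's migration profile; the double-labelled (BrdU+/Arc+) count is
#' binomial in the BrdU count with the day- and condition-specific
#' probability, placed across layers under the condition's placement
#' rule (never in the SGZ, heavily L1-enriched after exploration); and
#' Arc-only cells are binomial in the remaining granule cells with the
#' condition's baseline Arc fraction.
#'
#' @param design A `study_design`.
#' @param params A `generative_params`.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A data frame of per-animal, per-layer records with columns
#'   `animal_id, pbi_days, condition, layer, brdu_positive, arc_positive,
#'   brdu_arc_double, total_granule_sampled`.
#' @examples
#' tab <- generate_study(seed = 1)
#' head(tab)
#' @export
generate_study <- function(design = study_design(),
                           params = generative_params(), seed = NULL) {
  stopifnot(inherits(design, "study_design"),
            inherits(params, "generative_params"))
  days <- as.character(design$pbi_days)
  if (!all(days %in% names(params$brdu_fraction_by_day)) ||
      !all(days %in% rownames(params$layer_distribution_by_day)) ||
      !all(days %in% rownames(params$double_label_prob))) {
    stop("params must cover every design day: ", paste(days, collapse = ","))
  }
  if (!is.null(seed)) set.seed(seed)
  layers <- dg_layers()
  rows <- list()
  for (di in seq_along(design$pbi_days)) {
    day <- design$pbi_days[di]
    dk <- as.character(day)
    for (cond in c("CC", "SE")) {
      n_animals <- if (cond == "SE") design$n_se[di] else design$n_cc[di]
      for (i in seq_len(n_animals)) {
        total <- round(design$granule_cells_mean *
                         stats::runif(1, 1 - design$granule_jitter,
                                      1 + design$granule_jitter))
        brdu <- stats::rbinom(1, total, params$brdu_fraction_by_day[[dk]])
        brdu_l <- stats::setNames(
          as.integer(stats::rmultinom(1, brdu,
                                      params$layer_distribution_by_day[dk, layers])),
          layers)
        dbl <- stats::rbinom(1, brdu, params$double_label_prob[dk, cond])
        dbl_l <- place_doubles(dbl, brdu_l,
                               params$double_layer_placement[cond, layers])
        arc_only <- stats::rbinom(1, total - brdu,
                                  params$arc_base_fraction[[cond]])
        arc_only_l <- stats::setNames(
          as.integer(stats::rmultinom(1, arc_only,
                                      params$arc_layer_distribution[layers])),
          layers)
        rows[[length(rows) + 1]] <- data.frame(
          animal_id = sprintf("%s_d%02d_%02d", cond, day, i),
          pbi_days = day,
          condition = cond,
          layer = layers,
          brdu_positive = as.integer(brdu_l),
          arc_positive = as.integer(arc_only_l + dbl_l),
          brdu_arc_double = as.integer(dbl_l),
          total_granule_sampled = total,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_animal_counts(out)
  out
}

#' Generate synthetic proliferation-versus-age observations
#'
#' Stands in for the (unpublished) proliferation table behind the
#' survival fit: surviving-cohort sizes on a power law of animal age with
#' mean-one multiplicative log-normal noise of a given coefficient of
#' variation. Files written from this generator are synthetic, not
#' measured data. The default observation ages span weaning to
#' senescence (days 30--720), the range over which the decline of
#' dentate gyrus proliferation with age has been characterized in rats.
#'
#' @param scale,exponent Power-law parameters.
#' @param ages Animal ages (days, `>= 1`) at which to observe.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (0 for exact values).
#' @param seed Integer seed.
#' @return A data frame with columns `animal_age_days`,
#'   `surviving_cohort_size`.
#' @export
generate_proliferation_data <- function(scale, exponent,
                                        ages = c(30, 60, 120, 240, 360,
                                                 480, 600, 720),
                                        noise_cv = 0.2, seed = NULL) {
  if (!is.finite(scale) || scale <= 0) stop("scale must be positive")
  if (any(ages < 1)) stop("ages must be >= 1")
  if (!is.finite(noise_cv) || noise_cv < 0) stop("noise_cv must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  mu <- scale * ages^exponent
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    mu <- mu * stats::rlnorm(length(ages), meanlog = -sdlog^2 / 2,
                             sdlog = sdlog)
  }
  data.frame(animal_age_days = ages, surviving_cohort_size = mu)
}

#' Parameter-recovery experiment over seeded replicates
#'
#' For each replicate: simulate noisy group-mean responsiveness
#' observations at the study's ages (binomial Arc counts within binomial
#' BrdU counts per animal), simulate a noisy proliferation table, refit
#' both models, convolve them and locate the recruitment peak; compare
#' the recovered quantities (slope, zero crossing, exponent, peak age and
#' count) with the noiseless truth. Failures inside a replicate are
#' recorded, not fatal.
#'
#' @param replicates Number of replicates (`>= 1`).
#' @param truth_survival A `power_survival` used as ground truth.
#' @param truth_response A `responsiveness_fit` used as ground truth.
#' @param response_days Neuron ages (days) at which responsiveness groups
#'   are simulated.
#' @param animals_per_day Animals per responsiveness group.
#' @param brdu_fraction_by_day BrdU fractions at `response_days` (sets
#'   the per-animal denominator of the responding fraction).
#' @param granule_cells_mean Sampled granule cells per animal.
#' @param prolif_ages,prolif_cv Ages and noise CV for the proliferation
#'   table.
#' @param t_max Convolution horizon in days.
#' @param seed Integer seed for the whole experiment.
#' @return A list of class `recovery_report` with `results` (one row per
#'   replicate), `truth`, and `summary` (negative-slope rate, median peak
#'   age, biases).
#' @export
recovery_experiment <- function(replicates,
                                truth_survival = power_survival_model(),
                                truth_response = fit_responsiveness(response_points()),
                                response_days = c(30, 45, 150),
                                animals_per_day = c(4, 3, 3),
                                brdu_fraction_by_day = c(0.0017, 0.0015, 0.0015),
                                granule_cells_mean = 80000,
                                prolif_ages = c(70, 100, 150, 200, 250, 300,
                                                400, 500),
                                prolif_cv = 0.2,
                                t_max = 600,
                                seed = NULL) {
  stopifnot(replicates >= 1,
            length(animals_per_day) == length(response_days),
            length(brdu_fraction_by_day) == length(response_days))
  if (!is.null(seed)) set.seed(seed)
  truth_curve <- recruitment_curve(truth_survival, truth_response, t_max)
  truth_peak <- peak_recruitment(truth_curve)
  p_true <- response_probability(truth_response, response_days, "raw")
  res <- vector("list", replicates)
  for (k in seq_len(replicates)) {
    res[[k]] <- tryCatch({
      frac <- vapply(seq_along(response_days), function(j) {
        per_animal <- vapply(seq_len(animals_per_day[j]), function(i) {
          total <- round(granule_cells_mean * stats::runif(1, 0.9, 1.1))
          brdu <- stats::rbinom(1, total, brdu_fraction_by_day[j])
          if (brdu == 0) return(NA_real_)
          stats::rbinom(1, brdu, p_true[j]) / brdu
        }, numeric(1))
        mean(per_animal, na.rm = TRUE)
      }, numeric(1))
      resp_fit <- fit_responsiveness(
        data.frame(age_days = response_days,
                   fraction_responding = pmin(1, frac)),
        maturation_age_days = truth_response$maturation_age_days
      )
      prolif <- generate_proliferation_data(
        truth_survival$scale, truth_survival$exponent,
        ages = prolif_ages, noise_cv = prolif_cv
      )
      surv_fit <- fit_power_survival(
        prolif, anchor_age_days = truth_survival$anchor_age_days,
        anchor_count = truth_survival$anchor_count,
        start_age_days = truth_survival$start_age_days
      )
      pk <- peak_recruitment(recruitment_curve(surv_fit, resp_fit, t_max))
      data.frame(
        replicate = k, ok = TRUE, error = NA_character_,
        slope = resp_fit$slope_per_day,
        zero_crossing = resp_fit$zero_crossing_age_days,
        exponent = surv_fit$exponent,
        peak_age = pk$age_days, peak_count = pk$count,
        stringsAsFactors = FALSE
      )
    }, error = function(e) {
      data.frame(replicate = k, ok = FALSE, error = conditionMessage(e),
                 slope = NA_real_, zero_crossing = NA_real_,
                 exponent = NA_real_, peak_age = NA_real_,
                 peak_count = NA_real_, stringsAsFactors = FALSE)
    })
  }
  results <- do.call(rbind, res)
  ok <- results[results$ok, , drop = FALSE]
  summary <- list(
    n_ok = nrow(ok),
    negative_slope_rate = mean(ok$slope < 0),
    median_peak_age = stats::median(ok$peak_age),
    peak_age_bias = stats::median(ok$peak_age) - truth_peak$age_days,
    exponent_bias = mean(ok$exponent) - truth_survival$exponent,
    median_zero_crossing = stats::median(ok$zero_crossing, na.rm = TRUE)
  )
  structure(
    list(results = results,
         truth = list(peak_age = truth_peak$age_days,
                      peak_count = truth_peak$count,
                      slope = truth_response$slope_per_day,
                      zero_crossing = truth_response$zero_crossing_age_days,
                      exponent = truth_survival$exponent),
         summary = summary),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  s <- x$summary
  cat("Parameter-recovery experiment:", nrow(x$results), "replicates (",
      s$n_ok, "ok )\n")
  cat(sprintf("  negative-slope rate:  %.3f\n", s$negative_slope_rate))
  cat(sprintf("  median peak age:      %.0f d (truth %.0f, bias %+.0f)\n",
              s$median_peak_age, x$truth$peak_age, s$peak_age_bias))
  cat(sprintf("  exponent bias:        %+.4f\n", s$exponent_bias))
  invisible(x)
}

#' Write per-animal count records as CSV
#'
#' @param records Data frame of records (see [read_animal_counts()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_animal_counts <- function(records, path) {
  validate_animal_counts(records)
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
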