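#' Pipeline configuration
#'
#' Assembles the constants and switches of the full analysis into one
#' validated list. Either build it in code or load it from a YAML file
#' with the same keys.
#'
#' @param response_points_csv Path to a response-point CSV, or `NULL` to
#'   use the packaged observations ([response_points()]).
#' @param percent Interpret the CSV responding column as percentages.
#' @param proliferation_csv Path to a proliferation CSV to fit the
#'   survival curve from, or `NULL` for the reference parametrization
#'   (scale 2218.2 solved against the anchor).
#' @param variant `"adult"` (cohorts from day 70) or `"postnatal"`
#'   (cohorts from day 1).
#' @param maturation_age_days Neuron age at which the specific response
#'   begins. Default 30.
#' @param anchor_age_days,anchor_count Survival-curve anchor. Defaults
#'   150 d, 345 cells.
#' @param scale Reference survival scale when no proliferation table is
#'   supplied. Default 2218.2.
#' @param t_max Convolution horizon (days of animal age). Default 600.
#' @param seed Integer seed recorded in outputs (the core pipeline is
#'   deterministic; the seed matters when synthetic inputs are generated
#'   around it).
#' @param out_dir Directory for output files, or `NULL` to skip writing.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(response_points_csv = NULL, percent = FALSE,
                            proliferation_csv = NULL,
                            variant = c("adult", "postnatal"),
                            maturation_age_days = 30,
                            anchor_age_days = 150, anchor_count = 345,
                            scale = 2218.2, t_max = 600,
                            seed = 1L, out_dir = NULL) {
  variant <- match.arg(variant)
  bad <- c(maturation = maturation_age_days, anchor_age = anchor_age_days,
           anchor_count = anchor_count, scale = scale, t_max = t_max)
  if (any(!is.finite(bad)) || any(bad <= 0)) {
    stop("schema error: these constants must be positive: ",
         paste(names(bad)[!is.finite(bad) | bad <= 0], collapse = ", "))
  }
  structure(
    list(response_points_csv = response_points_csv, percent = percent,
         proliferation_csv = proliferation_csv, variant = variant,
         maturation_age_days = maturation_age_days,
         anchor_age_days = anchor_age_days, anchor_count = anchor_count,
         scale = scale, t_max = t_max, seed = as.integer(seed),
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("schema error: unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, raw)
}

#' Run the full recruitment pipeline
#'
#' Executes fit-response, fit-survival (or the reference
#' parametrization), the recruitment convolution with its peak and
#' population share, the early non-specific background with its share
#' comparisons, and the census arithmetic. Returns everything as one
#' bundle; if `config$out_dir` is set, also writes the curves (CSV), the
#' fitted parameters and headline summary (JSON), and a plain-text
#' report. All outputs carry a provenance line with the seed and a hash
#' of the configuration, and contain no timestamps, so runs with the
#' same configuration are byte-identical.
#'
#' @param config A `pipeline_config`.
#' @return A list of class `dg_pipeline_result` with components
#'   `response_fit`, `survival`, `curve`, `peak`, `share_percent`,
#'   `background`, `background_max`, `background_share_cc`,
#'   `background_share_se`, `census`, `report` (character vector) and
#'   `summary` (flat named list used for the JSON output).
#' @examples
#' res <- run_pipeline(pipeline_config())
#' cat(res$report, sep = "\n")
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  cc <- census_constants()

  pts <- if (is.null(config$response_points_csv)) {
    response_points()
  } else {
    if (!file.exists(config$response_points_csv)) {
      stop("missing input: ", config$response_points_csv)
    }
    read_response_points(config$response_points_csv, percent = config$percent)
  }
  resp <- fit_responsiveness(pts, maturation_age_days = config$maturation_age_days)

  start_age <- if (config$variant == "postnatal") 1 else 70
  surv <- if (is.null(config$proliferation_csv)) {
    power_survival_model(scale = config$scale,
                         anchor_age_days = config$anchor_age_days,
                         anchor_count = config$anchor_count,
                         start_age_days = start_age)
  } else {
    if (!file.exists(config$proliferation_csv)) {
      stop("missing input: ", config$proliferation_csv)
    }
    fit_power_survival(read_proliferation(config$proliferation_csv),
                       anchor_age_days = config$anchor_age_days,
                       anchor_count = config$anchor_count,
                       start_age_days = start_age)
  }

  curve <- recruitment_curve(surv, resp, config$t_max)
  peak <- peak_recruitment(curve)

  region_total <- scale_to_region(cc$sampled_cells, cc$sampled_extent_um,
                                  cc$region_extent_um,
                                  round_to_thousand = TRUE)
  total_responding <- responding_population(region_total, cc$arc_fraction_se)
  share <- recruitment_share(peak$count, total_responding)

  early <- calibrate_early_expression()
  bg <- early_background_curve(early, surv, region_total, config$t_max)
  bg_max <- attr(bg, "max_proportion")

  census <- list(
    region_granule_cells = region_total,
    total_responding = total_responding,
    daily_surviving_births = responding_population(
      cc$whole_dg_cells, cc$one_day_survival_fraction),
    percent_died_7_to_45 = survival_decline(0.0035, 0.0015)
  )

  summary <- list(
    variant = config$variant,
    r_squared = resp$r_squared,
    slope_per_day = resp$slope_per_day,
    intercept_at_birth = resp$intercept_at_birth,
    zero_crossing_age_days = resp$zero_crossing_age_days,
    survival_scale = surv$scale,
    survival_exponent = surv$exponent,
    peak_age_days = peak$age_days,
    peak_onset_day = peak$onset_day,
    peak_count = peak$count,
    share_percent = share,
    background_max_percent = 100 * bg_max,
    background_share_cc_percent = background_share(bg_max, cc$arc_fraction_cc),
    background_share_se_percent = background_share(bg_max, cc$arc_fraction_se),
    region_granule_cells = census$region_granule_cells,
    total_responding = census$total_responding,
    daily_surviving_births = census$daily_surviving_births
  )

  report <- c(
    sprintf("variant: %s (cohorts from day %d)", config$variant, start_age),
    sprintf("responsiveness: P(age) = %.6f %+.6g * age; R^2 = %.4f",
            resp$intercept_at_birth, resp$slope_per_day, resp$r_squared),
    sprintf("zero crossing: %.2f d (reported %d)",
            resp$zero_crossing_age_days, round(resp$zero_crossing_age_days)),
    sprintf("survival: N(tau) = %.1f * tau^%.4f, anchored N(%g) = %g",
            surv$scale, surv$exponent, surv$anchor_age_days,
            surv$anchor_count),
    sprintf("recruitment peak: %d cells at animal age %d d (recruitment day %d)",
            round(peak$count), round(peak$age_days), round(peak$onset_day)),
    sprintf("share of responding population: %.1f%% of %d cells",
            share, total_responding),
    sprintf("early background: max %.3f%% of %d granule cells", 100 * bg_max,
            region_total),
    sprintf("background vs cage-control Arc (%.2f%%): %.1f%%",
            100 * cc$arc_fraction_cc,
            background_share(bg_max, cc$arc_fraction_cc)),
    sprintf("background vs exploration Arc (%.2f%%): %.1f%%",
            100 * cc$arc_fraction_se,
            background_share(bg_max, cc$arc_fraction_se)),
    sprintf("census: %d region cells; %d responding; %d daily surviving births",
            census$region_granule_cells, census$total_responding,
            census$daily_surviving_births)
  )

  result <- structure(
    list(response_fit = resp, survival = surv, curve = curve, peak = peak,
         share_percent = share, background = bg, background_max = bg_max,
         background_share_cc = summary$background_share_cc_percent,
         background_share_se = summary$background_share_se_percent,
         census = census, report = report, summary = summary,
         config = config),
    class = "dg_pipeline_result"
  )

  if (!is.null(config$out_dir)) write_pipeline_outputs(result)
  result
}

#' @export
print.dg_pipeline_result <- function(x, ...) {
  cat(x$report, sep = "\n")
  invisible(x)
}

config_hash <- function(config) {
  flat <- config[order(names(config))]
  flat$out_dir <- NULL
  txt <- paste(names(flat),
               vapply(flat, function(v) paste(format(v), collapse = ","),
                      character(1)),
               sep = "=", collapse = ";")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

write_pipeline_outputs <- function(result) {
  dir <- result$config$out_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  prov <- sprintf("# dgrecruit pipeline; seed=%d; config=%s",
                  result$config$seed, config_hash(result$config))
  write_with_header <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(prov, con)
    utils::write.csv(df, con, row.names = FALSE)
  }
  write_with_header(as.data.frame(result$curve), file.path(dir, "recruitment_curve.csv"))
  write_with_header(as.data.frame(result$background), file.path(dir, "background_curve.csv"))
  jsonlite::write_json(c(list(provenance = prov), result$summary),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(c(prov, result$report), file.path(dir, "report.txt"))
  invisible(dir)
}
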