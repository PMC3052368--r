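#' Census constants of the study region
#'
#' The fixed quantities linking sampled counts to population predictions:
#' about 80,000 upper-blade granule cells were sampled per animal from
#' 450 um along the antero-posterior axis of a 1300 um region; the whole
#' dentate gyrus holds about 1,200,000 granule cells; 0.15% of the
#' granule population is one day's births that survive long term; 1.5% of
#' granule cells express Arc after spatial exploration and about 0.31% in
#' cage controls.
#'
#' @return A named list of constants.
#' @export
census_constants <- function() {
  list(
    sampled_cells = 80000,
    sampled_extent_um = 450,
    region_extent_um = 1300,
    whole_dg_cells = 1200000,
    one_day_survival_fraction = 0.0015,
    arc_fraction_se = 0.015,
    arc_fraction_cc = 0.0031
  )
}

#' Scale a per-animal cell count to the full region
#'
#' Linear scaling by the ratio of anatomical extents, with optional
#' rounding to the nearest thousand (the convention used for the
#' published 231,000 = 80,000 x 1300/450 figure). Rounding is applied
#' last.
#'
#' @param per_animal_cells Cells counted in the sampled extent.
#' @param sampled_extent_um,region_extent_um Extents in micrometers,
#'   positive.
#' @param round_to_thousand Logical; round the result to the nearest
#'   thousand?
#' @return Scaled cell count.
#' @examples
#' scale_to_region(80000, 450, 1300, round_to_thousand = TRUE)  # 231000
#' @export
scale_to_region <- function(per_animal_cells, sampled_extent_um,
                            region_extent_um, round_to_thousand = FALSE) {
  if (!is.finite(sampled_extent_um) || sampled_extent_um <= 0 ||
      !is.finite(region_extent_um) || region_extent_um <= 0) {
    stop("extents must be positive")
  }
  x <- per_animal_cells * region_extent_um / sampled_extent_um
  if (round_to_thousand) x <- round(x / 1000) * 1000
  x
}

#' Number of cells in a population meeting a response fraction
#'
#' Product of a population size and a fraction, rounded to the nearest
#' integer cell: 1.5% of the 231,000-cell region gives the 3,465 cells
#' responding to exploration; 0.15% of the 1,200,000-cell dentate gyrus
#' gives the ~1,800 cells born per day that survive.
#'
#' @param total_cells Population size, non-negative.
#' @param response_fraction Fraction in `[0, 1]`.
#' @return Integer cell count.
#' @export
responding_population <- function(total_cells, response_fraction) {
  if (any(total_cells < 0)) stop("total_cells must be non-negative")
  if (any(response_fraction < 0 | response_fraction > 1)) {
    stop("response_fraction must lie in [0, 1]")
  }
  round(total_cells * response_fraction)
}

#' Percent of early-detected cells that died
#'
#' Relative decline between the BrdU-positive fraction at day 7 and at
#' day 45 after labelling: `100 * (f7 - f45) / f7`. With the observed
#' 0.35% and 0.15% this gives 57.1% (reported as roughly 60%).
#'
#' @param fraction_day7 BrdU fraction at 7 days, positive.
#' @param fraction_day45 BrdU fraction at 45 days.
#' @return Percent of day-7 cells that died.
#' @export
survival_decline <- function(fraction_day7, fraction_day45) {
  if (any(!is.finite(fraction_day7)) || any(fraction_day7 <= 0)) {
    stop("fraction_day7 must be positive")
  }
  100 * (fraction_day7 - fraction_day45) / fraction_day7
}

dg_layers <- function() c("SGZ", "L1", "L2", "L3")

validate_animal_counts <- function(records) {
  need <- c("animal_id", "pbi_days", "condition", "layer", "brdu_positive",
            "arc_positive", "brdu_arc_double", "total_granule_sampled")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    stop("animal count records must have columns: ",
         paste(need, collapse = ", "))
  }
  if (nrow(records) == 0) stop("no records")
  if (!all(records$layer %in% dg_layers())) {
    stop("layer must be one of ", paste(dg_layers(), collapse = ", "))
  }
  cnt <- c("brdu_positive", "arc_positive", "brdu_arc_double")
  if (any(as.matrix(records[cnt]) < 0)) stop("counts must be non-negative")
  if (any(records$brdu_arc_double > pmin(records$brdu_positive,
                                         records$arc_positive))) {
    stop("double-labelled count exceeds BrdU or Arc count in some layer")
  }
  invisible(records)
}

#' Read per-animal count records from CSV
#'
#' One row per animal x layer, with columns `animal_id, pbi_days,
#' condition, layer, brdu_positive, arc_positive, brdu_arc_double,
#' total_granule_sampled`.
#'
#' @param path Path to a CSV file.
#' @return A validated data frame of records.
#' @export
read_animal_counts <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_animal_counts(rec)
  rec
}

#' Summarize per-animal counts into group proportions
#'
#' Collapses the per-animal, per-layer triple-label counts into the
#' descriptive quantities of the study: per (days-post-injection,
#' condition) group, the mean BrdU fraction of the granule total, the
#' mean absolute BrdU count, the layer distribution of BrdU cells, the
#' Arc fraction of the granule total, and the fraction of BrdU cells that
#' are double labelled (Arc-positive) overall plus the layer distribution
#' of the double-labelled cells. Fractions are computed per animal and
#' then averaged across the group (the published plots are group means of
#' per-animal percentages); set `pooled = TRUE` to instead pool counts
#' within each group before forming fractions.
#'
#' Animals with zero BrdU cells have an undefined double-labelled
#' fraction and are excluded from that group mean with a warning.
#'
#' @param records Data frame of per-animal, per-layer counts (see
#'   [read_animal_counts()]).
#' @param pooled Logical; pool counts within groups instead of averaging
#'   per-animal fractions.
#' @return A list of class `dg_group_summary` with elements `groups` (one
#'   row per group) and `animals` (one row per animal, retained for
#'   downstream comparison tests).
#' @export
group_summaries <- function(records, pooled = FALSE) {
  validate_animal_counts(records)
  layers <- dg_layers()
  per_animal <- do.call(rbind, lapply(
    split(records, records$animal_id),
    function(d) {
      gran <- unique(d$total_granule_sampled)
      if (length(gran) != 1) {
        stop("inconsistent total_granule_sampled within animal ",
             d$animal_id[1])
      }
      brdu_l <- vapply(layers, function(l)
        sum(d$brdu_positive[d$layer == l]), numeric(1))
      dbl_l <- vapply(layers, function(l)
        sum(d$brdu_arc_double[d$layer == l]), numeric(1))
      brdu <- sum(brdu_l)
      arc <- sum(d$arc_positive)
      dbl <- sum(dbl_l)
      if (sum(brdu_l) > gran) stop("layer BrdU sum exceeds granule total")
      out <- data.frame(
        animal_id = d$animal_id[1],
        pbi_days = d$pbi_days[1],
        condition = d$condition[1],
        granule_total = gran,
        brdu_count = brdu,
        brdu_frac = brdu / gran,
        arc_frac = arc / gran,
        double_frac = if (brdu > 0) dbl / brdu else NA_real_,
        stringsAsFactors = FALSE
      )
      for (i in seq_along(layers)) {
        out[[paste0("brdu_dist_", layers[i])]] <-
          if (brdu > 0) brdu_l[i] / brdu else NA_real_
        out[[paste0("double_dist_", layers[i])]] <-
          if (dbl > 0) dbl_l[i] / dbl else NA_real_
      }
      out
    }
  ))
  rownames(per_animal) <- NULL
  dropped <- per_animal$animal_id[!is.finite(per_animal$double_frac)]
  if (length(dropped) > 0) {
    warning("excluding animals with zero BrdU cells from double-labelled ",
            "fractions: ", paste(dropped, collapse = ", "))
  }
  grp_key <- interaction(per_animal$pbi_days, per_animal$condition,
                         drop = TRUE)
  groups <- do.call(rbind, lapply(split(per_animal, grp_key), function(g) {
    mean_cols <- grep("^(brdu_frac|arc_frac|double_frac|brdu_dist_|double_dist_)",
                      names(g), value = TRUE)
    row <- data.frame(
      pbi_days = g$pbi_days[1],
      condition = g$condition[1],
      n_animals = nrow(g),
      brdu_count_mean = mean(g$brdu_count),
      stringsAsFactors = FALSE
    )
    if (pooled) {
      # recompute pooled fractions from counts (denominator-weighted)
      row$brdu_frac <- sum(g$brdu_count) / sum(g$granule_total)
      row$arc_frac <- sum(g$arc_frac * g$granule_total) / sum(g$granule_total)
      row$double_frac <- if (sum(g$brdu_count) > 0) {
        sum(g$double_frac * g$brdu_count, na.rm = TRUE) / sum(g$brdu_count)
      } else NA_real_
      for (cl in grep("dist_", mean_cols, value = TRUE)) {
        row[[cl]] <- mean(g[[cl]], na.rm = TRUE)
      }
    } else {
      for (cl in mean_cols) row[[cl]] <- mean(g[[cl]], na.rm = TRUE)
    }
    row
  }))
  rownames(groups) <- NULL
  groups <- groups[order(groups$condition, groups$pbi_days), ]
  structure(list(groups = groups, animals = per_animal),
            class = "dg_group_summary")
}

#' @export
print.dg_group_summary <- function(x, ...) {
  cat("Group summaries (", nrow(x$animals), " animals, ",
      nrow(x$groups), " groups)\n", sep = "")
  print(x$groups[, c("pbi_days", "condition", "n_animals", "brdu_frac",
                     "arc_frac", "double_frac")], digits = 4)
  invisible(x)
}

#' Compare groups with standard ANOVA machinery
#'
#' A reporting convenience delegating to `stats::aov` (one or two
#' factors) and, for a single factor, Bonferroni-corrected pairwise
#' t-tests. Bespoke modelling lives elsewhere in the package; this simply
#' wraps the stock tests used for the descriptive group comparisons.
#'
#' @param summary A `dg_group_summary` (or its `animals` data frame).
#' @param response Name of the per-animal column to compare
#'   (default `"double_frac"`).
#' @param factors Character vector of one or two grouping columns from
#'   the per-animal table.
#' @return A data frame with columns `term`, `statistic`, `df`, `p`,
#'   `p_corrected` (corrected p-values only on pairwise rows).
#' @export
compare_groups <- function(summary, response = "double_frac",
                           factors = c("condition", "pbi_days")) {
  animals <- if (inherits(summary, "dg_group_summary")) summary$animals
             else summary
  stopifnot(is.data.frame(animals), response %in% names(animals),
            all(factors %in% names(animals)), length(factors) %in% 1:2)
  d <- animals[is.finite(animals[[response]]), , drop = FALSE]
  for (f in factors) d[[f]] <- factor(d[[f]])
  grp <- interaction(d[factors], drop = TRUE)
  sizes <- table(grp)
  if (length(sizes) < 2 || any(sizes < 2)) {
    stop("insufficient replication: need at least 2 groups with at least ",
         "2 animals each (got ", paste(sizes, collapse = ","), ")")
  }
  fml <- stats::as.formula(paste(response, "~",
                                 paste(factors, collapse = " * ")))
  av <- summary(stats::aov(fml, data = d))[[1]]
  terms <- trimws(rownames(av))
  keep <- terms != "Residuals"
  out <- data.frame(
    term = terms[keep],
    statistic = av[keep, "F value"],
    df = av[keep, "Df"],
    p = av[keep, "Pr(>F)"],
    p_corrected = NA_real_,
    stringsAsFactors = FALSE
  )
  if (length(factors) == 1) {
    pw <- stats::pairwise.t.test(d[[response]], d[[factors]],
                                 p.adjust.method = "bonferroni")
    pm <- pw$p.value
    for (i in seq_len(nrow(pm))) for (j in seq_len(ncol(pm))) {
      if (!is.na(pm[i, j])) {
        out <- rbind(out, data.frame(
          term = paste0(rownames(pm)[i], " vs ", colnames(pm)[j]),
          statistic = NA_real_, df = NA_real_, p = NA_real_,
          p_corrected = pm[i, j], stringsAsFactors = FALSE
        ))
      }
    }
  }
  rownames(out) <- NULL
  out
}
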