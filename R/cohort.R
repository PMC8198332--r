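#' Fold changes over wild-type controls
#'
#' Divides every value by the mean of the control-genotype values of its own
#' cohort and metric, so measurements from different animal cohorts become
#' comparable and the control-group mean maps to 1.0 in every cohort.
#'
#' @param table A data frame with columns `animal_id`, `genotype`, `cohort`,
#'   `metric_name` and `value` (finite).
#' @param control Genotype label of the control group (default `"WT"`).
#' @return The input as a tibble with an added `fold_change` column.
#' @export
fold_change_over_wt <- function(table, control = "WT") {
  table <- check_cohort_table(table)
  out <- dplyr::group_by(table, .data$cohort, .data$metric_name)
  out <- dplyr::mutate(
    out,
    .wt_mean = mean(.data$value[.data$genotype == control]),
    fold_change = .data$value / .data$.wt_mean
  )
  out <- dplyr::ungroup(out)
  if (anyNA(out$.wt_mean)) {
    bad <- unique(out$cohort[is.na(out$.wt_mean)])
    stop_arg(sprintf("cohort(s) without %s rows: %s",
                     control, paste(bad, collapse = ", ")),
             class = "thyromorph_cohort_error")
  }
  dplyr::select(out, -".wt_mean")
}

check_cohort_table <- function(table) {
  need <- c("animal_id", "genotype", "cohort", "metric_name", "value")
  missing <- setdiff(need, names(table))
  if (length(missing)) {
    stop_arg(sprintf("cohort table lacks column(s): %s",
                     paste(missing, collapse = ", ")))
  }
  if (anyNA(table$value) || any(!is.finite(table$value))) {
    stop_arg("cohort values must be finite")
  }
  tibble::as_tibble(table)
}

#' Many-to-one genotype comparison (one-way ANOVA with Dunnett correction)
#'
#' Compares every genotype against the control group with a one-way ANOVA
#' followed by Dunnett's many-to-one adjustment, per metric, on the
#' fold-change scale ([fold_change_over_wt()] is applied internally). By
#' default the analysis unit is the animal (animal means are compared);
#' `unit = "observation"` uses the raw rows instead. Significance is flagged
#' at `alpha`.
#'
#' @param table A cohort table (see [fold_change_over_wt()]).
#' @param control Control genotype label.
#' @param unit `"animal"` (default) or `"observation"`.
#' @param alpha Significance level for the `significant` flag.
#' @return An object of class `thyro_comparison`. [tidy()] returns one row
#'   per metric and non-control genotype with `fold_change_mean`,
#'   `fold_change_sd`, `estimate` (difference of fold-change means vs
#'   control), `adjusted_p` and `significant`; [glance()] returns one row per
#'   metric.
#' @export
many_to_one_compare <- function(table, control = "WT",
                                unit = c("animal", "observation"),
                                alpha = 0.05) {
  unit <- match.arg(unit)
  fc <- fold_change_over_wt(table, control = control)
  if (unit == "animal") {
    fc <- dplyr::summarise(
      dplyr::group_by(fc, .data$metric_name, .data$cohort, .data$genotype,
                      .data$animal_id),
      fold_change = mean(.data$fold_change), .groups = "drop")
  }
  results <- list()
  fits <- list()
  for (metric in unique(fc$metric_name)) {
    d <- fc[fc$metric_name == metric, , drop = FALSE]
    counts <- base::table(d$genotype)
    if (length(counts) < 2L) {
      stop_arg(sprintf("metric '%s' needs >= 2 genotype groups", metric),
               class = "thyromorph_cohort_error")
    }
    if (any(counts < 2L)) {
      stop_arg(sprintf("singleton group(s) for metric '%s': %s", metric,
                       paste(names(counts)[counts < 2L], collapse = ", ")),
               class = "thyromorph_cohort_error")
    }
    d$genotype <- stats::relevel(factor(d$genotype), ref = control)
    fit <- stats::aov(fold_change ~ genotype, data = d)
    glht_fit <- multcomp::glht(fit, linfct = multcomp::mcp(genotype = "Dunnett"))
    sm <- summary(glht_fit)
    geno <- sub(paste0(" - ", control), "", names(sm$test$coefficients),
                fixed = TRUE)
    stats_tbl <- dplyr::summarise(
      dplyr::group_by(d, .data$genotype),
      fold_change_mean = mean(.data$fold_change),
      fold_change_sd = stats::sd(.data$fold_change), .groups = "drop")
    res <- tibble::tibble(
      metric_name = metric,
      genotype = geno,
      estimate = unname(sm$test$coefficients),
      adjusted_p = unname(as.numeric(sm$test$pvalues))
    )
    res <- dplyr::left_join(res, stats_tbl, by = "genotype")
    res$significant <- res$adjusted_p < alpha
    results[[metric]] <- res
    fits[[metric]] <- glht_fit
  }
  structure(
    list(results = dplyr::bind_rows(results), fits = fits,
         control = control, unit = unit, alpha = alpha),
    class = "thyro_comparison"
  )
}

#' @export
print.thyro_comparison <- function(x, ...) {
  cat(sprintf("<thyro_comparison> Dunnett many-to-one vs %s (unit: %s)\n",
              x$control, x$unit))
  print(x$results)
  invisible(x)
}

#' @rdname many_to_one_compare
#' @param x A `thyro_comparison` object.
#' @param ... Unused.
#' @export
tidy.thyro_comparison <- function(x, ...) {
  dplyr::select(x$results, "metric_name", "genotype", "fold_change_mean",
                "fold_change_sd", "estimate", "adjusted_p", "significant")
}

#' @rdname many_to_one_compare
#' @export
glance.thyro_comparison <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$results, .data$metric_name),
    n_comparisons = dplyr::n(),
    n_significant = sum(.data$significant),
    alpha = x$alpha,
    .groups = "drop")
}

#' Normalize a band density to total lane protein
#'
#' Generic densitometry ratio: an immunoblot band intensity divided by the
#' total stained protein of its lane. Vectorized.
#'
#' @param band Band intensity sum (>= 0).
#' @param lane_total Total lane intensity (> 0).
#' @return `band / lane_total`.
#' @export
normalize_band_density <- function(band, lane_total) {
  if (any(!is.finite(lane_total)) || any(lane_total <= 0)) {
    stop_arg("`lane_total` must be > 0")
  }
  band / lane_total
}
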