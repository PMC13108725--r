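#' Robust modified z-scores
#'
#' Standardizes a numeric vector with the median/MAD-based modified z-score
#' `0.6745 * (x - median(x)) / MAD(x)`, where `MAD` is the *raw* (unscaled)
#' median absolute deviation `median(|x - median(x)|)`. A score of +0.6745
#' means the observation lies exactly one MAD above the dataset median. The
#' statistic is the package's phenotype measure: applied per analyte across
#' all tumor-conditioned-media observations it puts donors and analytes with
#' very different dynamic ranges on one comparable scale without assuming
#' normality and without discarding outliers.
#'
#' When all deviations from the median are zero the MAD is zero and the score
#' is undefined; the default fallback rescales by the mean absolute deviation
#' with consistency constant 0.7979 (its normal-consistency analogue), or the
#' function can be asked to fail instead.
#'
#' @param x numeric vector, length >= 2.
#' @param constant consistency constant multiplying the median/MAD ratio.
#'   Default 0.6745 (the normal quantile making the score comparable to a
#'   classical z-score).
#' @param mad_fallback what to do when `MAD(x) == 0`: `"mean_abs_dev"`
#'   rescales by the mean absolute deviation with constant 0.7979;
#'   `"error"` aborts.
#' @return numeric vector of scores, same length as `x`.
#' @examples
#' modified_z(c(1, 2, 3, 4, 100))
#' @export
modified_z <- function(x, constant = 0.6745,
                       mad_fallback = c("mean_abs_dev", "error")) {
  mad_fallback <- match.arg(mad_fallback)
  if (!is.numeric(x) || length(x) < 2) {
    abort("`x` must be a numeric vector of length >= 2.")
  }
  if (anyNA(x)) abort("`x` must not contain missing values.")
  med <- median(x)
  dev <- x - med
  mad_raw <- median(abs(dev))
  if (mad_raw > 0) {
    return(constant * dev / mad_raw)
  }
  if (mad_fallback == "error") {
    abort("MAD is zero: modified z-scores undefined for this vector.")
  }
  mean_ad <- mean(abs(dev))
  if (mean_ad == 0) {
    # perfectly constant vector: every point IS the median
    return(rep(0, length(x)))
  }
  warn("MAD is zero; falling back to mean absolute deviation scaling (0.7979).")
  0.7979 * dev / mean_ad
}

#' Retain analytes by censoring fraction
#'
#' An analyte is excluded when the fraction of its observations below the
#' assay's lower limit of quantification (LLoQ) exceeds
#' `max_censored_fraction`. With the default 0.40, analytes censored at 43%
#' or more are dropped while fully quantified analytes are kept.
#'
#' @param table measurement tibble with columns `analyte` and `below_lloq`.
#' @param max_censored_fraction maximum tolerated censored fraction
#'   (strictly greater is excluded). Default 0.4.
#' @return tibble with one row per analyte: `analyte`, `n_obs`,
#'   `censored_fraction`, `retained`.
#' @export
filter_analytes_by_lloq <- function(table, max_censored_fraction = 0.4) {
  check_columns(table, c("analyte", "below_lloq"), "measurement table")
  table |>
    dplyr::group_by(analyte = .data$analyte) |>
    dplyr::summarise(
      n_obs = dplyr::n(),
      censored_fraction = mean(.data$below_lloq),
      .groups = "drop"
    ) |>
    dplyr::mutate(retained = .data$censored_fraction <= max_censored_fraction)
}

#' Handle censored (below-LLoQ) values in retained analytes
#'
#' Sporadic below-LLoQ observations in analytes that survive the censoring
#' filter are replaced before scoring. `half_lloq` (default, standard
#' practice for left-censored assay data) substitutes LLoQ/2, `lloq`
#' substitutes the LLoQ itself, `drop` removes the rows.
#'
#' @param table measurement tibble with columns `analyte`, `concentration`,
#'   `below_lloq`.
#' @param lloq_map named numeric vector, analyte -> LLoQ (pg/mL).
#' @param method one of `"half_lloq"`, `"lloq"`, `"drop"`.
#' @return the tibble with censored concentrations imputed (flags preserved)
#'   or censored rows removed.
#' @export
impute_censored <- function(table, lloq_map,
                            method = c("half_lloq", "lloq", "drop")) {
  method <- match.arg(method)
  check_columns(table, c("analyte", "concentration", "below_lloq"),
                "measurement table")
  missing_lloq <- setdiff(unique(table$analyte), names(lloq_map))
  if (length(missing_lloq) > 0) {
    abort(paste0("No LLoQ provided for analyte(s): ",
                 paste(missing_lloq, collapse = ", ")))
  }
  if (method == "drop") {
    return(dplyr::filter(table, !.data$below_lloq))
  }
  scale <- if (method == "half_lloq") 0.5 else 1
  dplyr::mutate(
    table,
    concentration = ifelse(.data$below_lloq,
                           scale * unname(lloq_map[.data$analyte]),
                           .data$concentration)
  )
}

#' Score all observations of a measurement table
#'
#' Computes per-observation modified z-scores for each analyte. Under
#' `pooling = "pooled"` (default) the "dataset" for an analyte is every
#' observation of that analyte — all donors, cell lines and controls pooled —
#' so control wells sit on the same scale as treated wells. Under
#' `"per_donor"` each donor's observations are standardized separately.
#'
#' @param table measurement tibble with columns `donor`, `unit`, `analyte`,
#'   `concentration`.
#' @param pooling `"pooled"` or `"per_donor"`.
#' @param constant,mad_fallback passed to [modified_z()].
#' @return the tibble with an added `mod_z` column.
#' @export
score_observations <- function(table, pooling = c("pooled", "per_donor"),
                               constant = 0.6745,
                               mad_fallback = "mean_abs_dev") {
  pooling <- match.arg(pooling)
  check_columns(table, c("donor", "unit", "analyte", "concentration"),
                "measurement table")
  groups <- if (pooling == "pooled") "analyte" else c("analyte", "donor")
  table |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::mutate(mod_z = modified_z(.data$concentration, constant = constant,
                                     mad_fallback = mad_fallback)) |>
    dplyr::ungroup()
}

#' Aggregate per-observation scores to per-unit means
#'
#' Averages each unit's (cell line's or control's) modified z-scores across
#' donors, per analyte, reporting the mean and the standard error of the mean
#' (SEM = sd / sqrt(n); `NA` for a single donor).
#'
#' @param scored tibble from [score_observations()] (columns `donor`, `unit`,
#'   `analyte`, `mod_z`).
#' @param control_units character vector of unit ids that are untreated
#'   controls; they are aggregated identically but flagged `is_control`.
#' @return tibble with `unit`, `analyte`, `mean_z`, `sem`, `n_donors`,
#'   `is_control`.
#' @export
aggregate_scores <- function(scored, control_units = character()) {
  check_columns(scored, c("donor", "unit", "analyte", "mod_z"),
                "scored table")
  scored |>
    dplyr::group_by(unit = .data$unit, analyte = .data$analyte) |>
    dplyr::summarise(
      mean_z = mean(.data$mod_z),
      sem = ifelse(dplyr::n() > 1, sd(.data$mod_z) / sqrt(dplyr::n()),
                   NA_real_),
      n_donors = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(is_control = .data$unit %in% control_units)
}

#' Top/bottom quartile membership for one analyte
#'
#' Splits the scored (non-control) units into the top and bottom quartiles of
#' mean modified z-score, each of size `ceiling(n / 4)` — for 23 scored lines
#' that gives groups of 6, for 25 lines groups of 7. Ties at the group
#' boundary are broken deterministically by lexicographic unit id.
#'
#' @param unit_scores tibble from [aggregate_scores()].
#' @param analyte analyte name to split on.
#' @return tibble with `unit`, `analyte`, `mean_z`, `quartile` in
#'   `{"top", "bottom", "middle"}` for every scored non-control unit.
#' @export
assign_quartiles <- function(unit_scores, analyte) {
  check_columns(unit_scores, c("unit", "analyte", "mean_z"), "unit scores")
  scores <- unit_scores |>
    dplyr::filter(.data$analyte == !!analyte)
  if ("is_control" %in% names(scores)) {
    scores <- dplyr::filter(scores, !.data$is_control)
  }
  n <- nrow(scores)
  if (n < 8) {
    abort(paste0("Need >= 8 scored units to form quartiles for '", analyte,
                 "'; got ", n, "."))
  }
  k <- ceiling(n / 4)
  if (2 * k > n) abort("quartiles overlap: 2 * ceiling(n/4) > n.")
  # descending score, unit id as the deterministic tie-break
  ord <- order(-scores$mean_z, scores$unit)
  quartile <- rep("middle", n)
  quartile[ord[seq_len(k)]] <- "top"
  quartile[ord[seq(n - k + 1, n)]] <- "bottom"
  scores |>
    dplyr::select("unit", "analyte", "mean_z") |>
    dplyr::mutate(quartile = quartile)
}

#' Full polarization-scoring stage
#'
#' Runs the whole scoring pipeline on a validated measurement table: censoring
#' filter, imputation of sporadic censored values, per-observation modified
#' z-scores, donor aggregation, and top/bottom quartile labels per retained
#' analyte.
#'
#' @param table measurement tibble (see [read_measurement_table()] or
#'   [simulate_cytokine_experiment()]).
#' @param lloq_map named numeric vector analyte -> LLoQ.
#' @param max_censored_fraction censoring threshold for analyte retention.
#' @param imputation censored-value method, see [impute_censored()].
#' @param pooling z-score dataset definition, see [score_observations()].
#' @param control_units unit ids treated as controls (excluded from
#'   quartiles, scored and reported alongside).
#' @return object of class `polar_scores`: a list with `per_observation`,
#'   `per_unit`, `quartiles`, `analyte_retention`, `retained_analytes` and
#'   the parameters used.
#' @export
score_polarization <- function(table, lloq_map,
                               max_censored_fraction = 0.4,
                               imputation = "half_lloq",
                               pooling = "pooled",
                               control_units = character()) {
  retention <- filter_analytes_by_lloq(table, max_censored_fraction)
  retained <- retention$analyte[retention$retained]
  if (length(retained) == 0) abort("No analyte survives the LLoQ filter.")
  kept <- dplyr::filter(table, .data$analyte %in% retained)
  kept <- impute_censored(kept, lloq_map, method = imputation)
  scored <- score_observations(kept, pooling = pooling)
  per_unit <- aggregate_scores(scored, control_units = control_units)
  quartiles <- purrr::map_dfr(retained, function(a) {
    assign_quartiles(per_unit, a)
  })
  structure(
    list(
      per_observation = scored,
      per_unit = per_unit,
      quartiles = quartiles,
      analyte_retention = retention,
      retained_analytes = retained,
      params = list(max_censored_fraction = max_censored_fraction,
                    imputation = imputation, pooling = pooling,
                    control_units = control_units)
    ),
    class = "polar_scores"
  )
}

#' @export
print.polar_scores <- function(x, ...) {
  cat("<polar_scores>\n")
  cat("  analytes retained:", length(x$retained_analytes), "of",
      nrow(x$analyte_retention), "\n")
  cat("  units scored:", length(unique(x$per_unit$unit)), "\n")
  cat("  pooling:", x$params$pooling, "\n")
  invisible(x)
}

# internal: fail early with the missing column's name
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0("The ", what, " is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(df)
}
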