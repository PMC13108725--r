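#' Quartile-membership statistic
#'
#' The observed overrepresentation statistic. For a cell line: the number of
#' analytes in which the line carries the given quartile label. For a tumor
#' type (when `metadata` maps lines to types): the total number of labeled
#' quartile slots occupied by lines of that type, summed across analytes.
#'
#' @param quartile_labels tibble with columns `analyte`, `unit`, `quartile`.
#' @param unit cell-line id, or tumor-type label when `metadata` is given.
#' @param direction `"top"` or `"bottom"`.
#' @param metadata optional tibble `unit`, `tumor_type` switching the
#'   statistic to tumor-type counting.
#' @return non-negative integer.
#' @export
quartile_membership_statistic <- function(quartile_labels, unit,
                                          direction = c("top", "bottom"),
                                          metadata = NULL) {
  direction <- match.arg(direction)
  check_columns(quartile_labels, c("analyte", "unit", "quartile"),
                "quartile labels")
  lab <- dplyr::filter(quartile_labels, .data$quartile == direction)
  if (is.null(metadata)) {
    if (!unit %in% quartile_labels$unit) {
      abort(paste0("Unknown unit '", unit, "'."))
    }
    return(sum(lab$unit == unit))
  }
  check_columns(metadata, c("unit", "tumor_type"), "metadata")
  if (!unit %in% metadata$tumor_type) {
    abort(paste0("Unknown tumor type '", unit, "'."))
  }
  members <- metadata$unit[metadata$tumor_type == unit]
  sum(lab$unit %in% members)
}

#' Permutation null for the quartile-membership statistic
#'
#' Each permutation draws, independently for each analyte, a uniformly
#' random quartile set of the given size from the unit pool and recounts the
#' statistic for a focal entity occupying `unit_multiplicity` units of the
#' pool (1 for a cell line; the number of member lines for a tumor type).
#' The per-analyte hit count of a uniformly drawn size-k set within a fixed
#' m-unit focal subset is hypergeometric, so the null is sampled directly
#' from that distribution and summed over analytes.
#'
#' @param n_units pool size.
#' @param quartile_size units per quartile draw.
#' @param n_analytes number of independent analyte draws summed.
#' @param unit_multiplicity focal-subset size (default 1).
#' @param n_permutations number of null draws.
#' @param seed optional integer seed.
#' @return integer vector of `n_permutations` null statistics.
#' @export
permutation_null_counts <- function(n_units, quartile_size, n_analytes,
                                    unit_multiplicity = 1,
                                    n_permutations = 20000, seed = NULL) {
  if (unit_multiplicity > n_units) {
    abort("unit_multiplicity cannot exceed the unit pool.")
  }
  if (2 * quartile_size > n_units) {
    abort("Quartile size too large for the unit pool.")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  draws <- matrix(
    rhyper(n_permutations * n_analytes, m = unit_multiplicity,
           n = n_units - unit_multiplicity, k = quartile_size),
    nrow = n_permutations
  )
  as.integer(rowSums(draws))
}

#' Permutation overrepresentation test across analytes
#'
#' Tests every cell line (and, with `metadata`, every tumor type) for
#' overrepresentation in the top and bottom score quartiles across analytes.
#' P-values use the add-one estimator `(1 + #\{null >= observed\}) /
#' (1 + n_permutations)`, which never returns zero, and are BH-adjusted
#' within each family (cell lines; each tumor-type grouping separately).
#'
#' @param quartile_labels tibble `analyte`, `unit`, `quartile`.
#' @param metadata optional tibble `unit`, `tumor_type` adding the
#'   tumor-type family.
#' @param n_perm_lines permutations for the cell-line family
#'   (default 20000).
#' @param n_perm_types permutations for the tumor-type family
#'   (default 5000).
#' @param seed integer seed (defaults to 1; the null is stochastic).
#' @return tibble: `unit`, `family`, `direction`, `observed`,
#'   `n_permutations`, `p_perm`, `p_adj`, `seed`.
#' @export
overrepresentation_test <- function(quartile_labels, metadata = NULL,
                                    n_perm_lines = 20000,
                                    n_perm_types = 5000, seed = 1L) {
  check_columns(quartile_labels, c("analyte", "unit", "quartile"),
                "quartile labels")
  set.seed(as.integer(seed))
  units <- sort(unique(quartile_labels$unit))
  n_units <- length(units)
  n_analytes <- length(unique(quartile_labels$analyte))
  k <- quartile_labels |>
    dplyr::filter(.data$quartile == "top") |>
    dplyr::count(.data$analyte)
  quartile_size <- k$n[1]

  run_family <- function(focal_units, multiplicities, family, n_perm,
                         meta) {
    out <- list()
    for (dir in c("top", "bottom")) {
      null <- NULL
      for (i in seq_along(focal_units)) {
        u <- focal_units[i]
        m <- multiplicities[i]
        obs <- quartile_membership_statistic(quartile_labels, u, dir,
                                             metadata = meta)
        # null depends only on the multiplicity; reuse across units
        null <- permutation_null_counts(n_units, quartile_size, n_analytes,
                                        unit_multiplicity = m,
                                        n_permutations = n_perm)
        out[[length(out) + 1]] <- tibble::tibble(
          unit = u, family = family, direction = dir,
          observed = obs, n_permutations = n_perm,
          p_perm = (1 + sum(null >= obs)) / (1 + n_perm)
        )
      }
    }
    res <- dplyr::bind_rows(out)
    dplyr::mutate(res, p_adj = adjust_fdr(.data$p_perm, "bh"),
                  seed = as.integer(seed))
  }

  res <- run_family(units, rep(1L, n_units), "cell_line", n_perm_lines,
                    meta = NULL)
  if (!is.null(metadata)) {
    check_columns(metadata, c("unit", "tumor_type"), "metadata")
    missing <- setdiff(units, metadata$unit)
    if (length(missing) > 0) {
      abort(paste0("No tumor type for line(s): ",
                   paste(missing, collapse = ", ")))
    }
    types <- sort(unique(metadata$tumor_type))
    mult <- vapply(types, function(tt) {
      sum(metadata$unit %in% units & metadata$tumor_type == tt)
    }, integer(1))
    res <- dplyr::bind_rows(
      res,
      run_family(types, mult, "tumor_type", n_perm_types, meta = metadata)
    )
  }
  res
}
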