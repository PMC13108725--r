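#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks under ties). Returns `NA`
#' with a warning when either vector has zero rank variance.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in `[-1, 1]`, or `NA`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3) abort("Need at least 3 paired observations.")
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    warn("Zero rank variance: Spearman correlation undefined.")
    return(NA_real_)
  }
  cor(rx, ry)
}

#' P-value for a Spearman correlation
#'
#' `exact_enumeration` (tie-free inputs, n <= 9) computes the two-sided
#' p-value as the proportion of all n! rank permutations whose |rho| is at
#' least the observed |rho|. `t_approx` uses the usual
#' `t = rho * sqrt((n-2)/(1-rho^2))` reference on n-2 degrees of freedom.
#'
#' @param rho observed correlation.
#' @param n number of paired observations.
#' @param method `"t_approx"` or `"exact_enumeration"`.
#' @param ties set `TRUE` if the data contained ties; exact enumeration is
#'   then invalid and falls back to `t_approx` with a warning.
#' @return two-sided p-value in (0, 1].
#' @export
spearman_pvalue <- function(rho, n,
                            method = c("t_approx", "exact_enumeration"),
                            ties = FALSE) {
  method <- match.arg(method)
  if (is.na(rho)) return(NA_real_)
  if (n < 3) abort("Need n >= 3.")
  if (method == "exact_enumeration") {
    if (ties) {
      warn("Exact enumeration invalid with ties; using t approximation.")
      method <- "t_approx"
    } else if (n > 9) {
      abort("Exact enumeration supported only for n <= 9.")
    }
  }
  if (method == "exact_enumeration") {
    perms <- all_permutations(n)
    r0 <- seq_len(n)
    # tie-free closed form: rho = 1 - 6*sum(d^2) / (n(n^2-1))
    d2 <- rowSums((perms - matrix(r0, nrow(perms), n, byrow = TRUE))^2)
    rhos <- 1 - 6 * d2 / (n * (n^2 - 1))
    return(mean(abs(rhos) >= abs(rho) - 1e-12))
  }
  if (abs(rho) >= 1) return(0)
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(-abs(tval), df = n - 2)
}

# all permutations of 1..n as an n! x n matrix (recursive construction)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    block <- cbind(rep(k, nrow(sub)), sub + (sub >= k))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Multiple-testing adjustment
#'
#' `"bh"` applies Benjamini-Hochberg step-up adjustment. `"storey"` computes
#' q-values with the null proportion estimated at lambda = 0.5:
#' `pi0 = min(1, #\{p > 0.5\} / (0.5 m))`, `q_(i) = pi0 * m * p_(i) / i` with
#' step-up (cumulative-minimum) enforcement and a cap at 1. Missing p-values
#' propagate as missing and are excluded from `m`.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @param method `"bh"` or `"storey"`.
#' @return vector of adjusted p-values / q-values, same length and order.
#' @export
adjust_fdr <- function(p, method = c("bh", "storey")) {
  method <- match.arg(method)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort("p-values must lie in [0, 1].")
  if (method == "bh") {
    out <- rep(NA_real_, length(p))
    out[ok] <- p.adjust(p[ok], method = "BH")
    return(out)
  }
  m <- sum(ok)
  out <- rep(NA_real_, length(p))
  if (m == 0) return(out)
  pv <- p[ok]
  pi0 <- min(1, sum(pv > 0.5) / (0.5 * m))
  ord <- order(pv)
  q <- pi0 * m * pv[ord] / seq_len(m)
  q <- rev(cummin(rev(pmin(q, 1))))
  out[ok][ord] <- q
  out
}

#' Pairwise cytokine-cytokine correlations
#'
#' Spearman correlations between all unordered pairs of retained analytes,
#' using donor-averaged per-unit mean scores (controls excluded), BH-adjusted
#' across all pairs. Seven analytes give the full 21 pairs.
#'
#' @param scores a `polar_scores` object or a per-unit tibble with columns
#'   `unit`, `analyte`, `mean_z` (and optionally `is_control`).
#' @param p_method p-value method passed to [spearman_pvalue()].
#' @return tibble: `analyte_a`, `analyte_b`, `rho`, `n`, `p_raw`,
#'   `p_adj_bh`.
#' @export
pairwise_cytokine_correlations <- function(scores, p_method = "t_approx") {
  per_unit <- if (inherits(scores, "polar_scores")) scores$per_unit else scores
  check_columns(per_unit, c("unit", "analyte", "mean_z"), "per-unit scores")
  if ("is_control" %in% names(per_unit)) {
    per_unit <- dplyr::filter(per_unit, !.data$is_control)
  }
  wide <- tidyr::pivot_wider(per_unit[c("unit", "analyte", "mean_z")],
                             names_from = "analyte", values_from = "mean_z")
  analytes <- sort(setdiff(names(wide), "unit"))
  if (length(analytes) < 2) abort("Need at least 2 retained analytes.")
  pairs <- utils::combn(analytes, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- wide[[pairs[1, i]]]
    b <- wide[[pairs[2, i]]]
    ok <- complete.cases(a, b)
    if (sum(ok) < 3) {
      return(tibble::tibble(analyte_a = pairs[1, i], analyte_b = pairs[2, i],
                            rho = NA_real_, n = sum(ok), p_raw = NA_real_))
    }
    rho <- spearman_rho(a[ok], b[ok])
    has_ties <- anyDuplicated(a[ok]) > 0 || anyDuplicated(b[ok]) > 0
    tibble::tibble(
      analyte_a = pairs[1, i], analyte_b = pairs[2, i], rho = rho,
      n = sum(ok),
      p_raw = spearman_pvalue(rho, sum(ok), method = p_method,
                              ties = has_ties)
    )
  })
  dplyr::mutate(res, p_adj_bh = adjust_fdr(.data$p_raw, "bh"))
}

#' Genome-wide gene-expression vs polarization-score screen
#'
#' Correlates every gene's expression with one analyte's donor-averaged
#' per-unit modified z-scores (Spearman), with BH-adjusted p-values and
#' Storey q-values. Zero-variance genes are excluded (their count is
#' reported via a message). Samples are matched to scored units by id.
#'
#' @param bundle an `expression_bundle`.
#' @param scores a `polar_scores` object or per-unit tibble.
#' @param analyte analyte whose scores drive the screen.
#' @param matrix_choice `"normalized"` (default) or `"counts"`: which matrix
#'   of the bundle to screen.
#' @param fdr_method method for the `q_value` column: `"storey"` (default)
#'   or `"bh"`.
#' @return tibble: `gene`, `rho`, `n`, `p_raw`, `p_adj_bh`, `q_value`,
#'   `matrix_used`, sorted by decreasing |rho|.
#' @export
gene_score_screen <- function(bundle, scores, analyte,
                              matrix_choice = c("normalized", "counts"),
                              fdr_method = "storey") {
  matrix_choice <- match.arg(matrix_choice)
  per_unit <- if (inherits(scores, "polar_scores")) scores$per_unit else scores
  check_columns(per_unit, c("unit", "analyte", "mean_z"), "per-unit scores")
  if ("is_control" %in% names(per_unit)) {
    per_unit <- dplyr::filter(per_unit, !.data$is_control)
  }
  sc <- dplyr::filter(per_unit, .data$analyte == !!analyte)
  if (nrow(sc) == 0) abort(paste0("No scores for analyte '", analyte, "'."))
  expr <- bundle[[matrix_choice]]
  shared <- intersect(colnames(expr), sc$unit)
  if (length(shared) == 0) {
    abort("No shared samples between expression matrix and scored units.")
  }
  if (length(shared) < 5) {
    abort("Need at least 5 shared samples for the screen.")
  }
  expr <- expr[, shared, drop = FALSE]
  z <- sc$mean_z[match(shared, sc$unit)]
  keep <- row_vars(expr) > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    inform(paste0("Excluded ", n_dropped, " zero-variance gene(s)."))
  }
  expr <- expr[keep, , drop = FALSE]
  # rank-transform rows once, then a single crossprod gives all correlations
  rz <- rank(z)
  rexpr <- t(apply(expr, 1, rank))
  rho <- as.vector(cor(t(rexpr), rz))
  n <- length(shared)
  tval <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-15))
  p_raw <- 2 * pt(-abs(tval), df = n - 2)
  p_raw[abs(rho) >= 1] <- 0
  res <- tibble::tibble(
    gene = rownames(expr), rho = rho, n = n, p_raw = p_raw,
    p_adj_bh = adjust_fdr(p_raw, "bh"),
    q_value = adjust_fdr(p_raw, fdr_method),
    matrix_used = matrix_choice
  )
  dplyr::arrange(res, dplyr::desc(abs(.data$rho)))
}

# internal row-variance helper
row_vars <- function(m) {
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / max(1, ncol(m) - 1)
}
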