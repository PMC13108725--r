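#' Filter low-information genes
#'
#' Removes a gene when its total count across samples is at most `min_total`
#' (default 3) or it is detected (nonzero) in fewer than
#' `min_detect_fraction` (default 0.5) of samples. A gene detected in
#' exactly half the samples is kept.
#'
#' @param counts integer gene x sample matrix.
#' @param min_total total-count threshold (<= is removed).
#' @param min_detect_fraction minimum detection fraction (< is removed).
#' @return list: `kept` (filtered matrix) and `removed` (tibble `gene`,
#'   `reason`).
#' @export
filter_genes <- function(counts, min_total = 3, min_detect_fraction = 0.5) {
  if (length(counts) == 0 || nrow(counts) == 0) abort("Empty count matrix.")
  low_total <- rowSums(counts) <= min_total
  low_detect <- rowMeans(counts > 0) < min_detect_fraction
  removed <- low_total | low_detect
  reason <- dplyr::case_when(
    low_total & low_detect ~ "low_total;low_detection",
    low_total ~ "low_total",
    low_detect ~ "low_detection",
    TRUE ~ NA_character_
  )
  list(
    kept = counts[!removed, , drop = FALSE],
    removed = tibble::tibble(gene = rownames(counts)[removed],
                             reason = reason[removed])
  )
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling constants: each sample's median ratio of counts to the
#' per-gene geometric means, computed over reference genes with all-positive
#' counts. When no gene is positive in every sample, geometric means are
#' taken over positive entries only (poscounts-style fallback, reported via
#' a message).
#'
#' @param counts integer gene x sample matrix.
#' @return positive numeric vector, one size factor per sample.
#' @export
size_factors <- function(counts) {
  zero_sample <- colSums(counts) == 0
  if (any(zero_sample)) {
    abort(paste0("Sample(s) with all-zero counts: ",
                 paste(colnames(counts)[zero_sample], collapse = ", ")))
  }
  all_pos <- rowSums(counts == 0) == 0
  # the median is taken on the log-ratio scale (geometric interpolation
  # between middle values at even counts), the usual convention
  if (any(all_pos)) {
    ref <- counts[all_pos, , drop = FALSE]
    loggeo <- rowMeans(log(ref))
    sf <- exp(apply(log(ref) - loggeo, 2, median))
  } else {
    inform("No all-positive gene; using positive-entry geometric means.")
    lg <- log(counts)
    lg[!is.finite(lg)] <- NA
    loggeo <- rowMeans(lg, na.rm = TRUE)
    lr <- lg - loggeo
    sf <- exp(apply(lr, 2, median, na.rm = TRUE))
  }
  if (any(!is.finite(sf) | sf <= 0)) {
    abort("Could not compute positive size factors for every sample.")
  }
  sf
}

#' Per-gene negative-binomial dispersion estimates
#'
#' Method-of-moments dispersion on size-factor-normalized counts,
#' `alpha_hat = max(alpha_min, (s2 - mu) / mu^2)`, moderated 50/50 in log
#' space toward a mean-dispersion trend `a + b / mu` fitted across genes by
#' robust regression with the decreasing shape enforced (`b >= 0`,
#' `a >= alpha_min`).
#'
#' @param counts integer gene x sample matrix (>= 2 samples).
#' @param sf size factors from [size_factors()].
#' @param alpha_min dispersion floor (default 1e-8).
#' @return tibble: `gene`, `mu` (mean normalized count), `alpha_mom`,
#'   `alpha_trend`, `alpha` (moderated).
#' @export
estimate_dispersion <- function(counts, sf, alpha_min = 1e-8) {
  if (ncol(counts) < 2) {
    abort("Dispersion unidentifiable with a single sample.")
  }
  norm <- sweep(counts, 2, sf, `/`)
  mu <- rowMeans(norm)
  s2 <- row_vars(norm)
  alpha_mom <- pmax(alpha_min, (s2 - mu) / pmax(mu, 1e-8)^2)
  ok <- mu > 0
  fit_df <- data.frame(a = alpha_mom[ok], x = 1 / mu[ok])
  trend <- tryCatch({
    rfit <- MASS::rlm(a ~ x, data = fit_df, maxit = 50)
    cf <- stats::coef(rfit)
    c(max(cf[1], alpha_min), max(cf[2], 0))
  }, error = function(e) c(max(median(alpha_mom[ok]), alpha_min), 0))
  alpha_trend <- pmax(alpha_min, trend[1] + trend[2] / pmax(mu, 1e-8))
  alpha <- exp(0.5 * log(alpha_mom) + 0.5 * log(alpha_trend))
  tibble::tibble(gene = rownames(counts), mu = mu, alpha_mom = alpha_mom,
                 alpha_trend = alpha_trend, alpha = pmax(alpha, alpha_min))
}

#' Negative-binomial Wald tests between two groups
#'
#' Per gene, a log-link NB GLM with design `[intercept, group]` and
#' log-size-factor offsets is fitted by iteratively reweighted least squares
#' (vectorized across genes) with a small ridge penalty (1e-6) on the group
#' coefficient, which bounds the fold-change when one group has all-zero
#' counts while leaving well-expressed genes effectively unpenalized. The
#' Wald statistic is the log2 fold change over its standard error, referred
#' to the standard normal.
#'
#' @param counts integer gene x sample matrix.
#' @param sf size factors.
#' @param dispersions per-gene dispersion vector or the tibble from
#'   [estimate_dispersion()].
#' @param groups binary labels (factor/character/logical) over samples; the
#'   second level is the "high" group whose excess expression gives positive
#'   fold changes.
#' @param ridge ridge penalty on the group coefficient.
#' @param max_iter IRLS iteration cap; genes not converged are flagged with
#'   missing p-values.
#' @param minmu floor on the fitted means inside the IRLS weights.
#' @return tibble: `gene`, `base_mean`, `lfc_mle` (log2), `se`, `wald`,
#'   `p_raw`, `converged`.
#' @export
wald_test <- function(counts, sf, dispersions, groups, ridge = 1e-6,
                      max_iter = 100L, minmu = 0.5) {
  if (is.data.frame(dispersions)) {
    dispersions <- setNames(dispersions$alpha, dispersions$gene)
    dispersions <- dispersions[rownames(counts)]
  }
  g <- factor(groups)
  if (nlevels(g) != 2) abort("`groups` must have exactly 2 levels.")
  if (any(table(g) == 0)) abort("Both groups must be non-empty.")
  x <- as.numeric(g == levels(g)[2])
  Y <- counts
  G <- nrow(Y)
  S <- ncol(Y)
  off <- log(sf)
  offm <- matrix(off, G, S, byrow = TRUE)
  xm <- matrix(x, G, S, byrow = TRUE)
  alpha <- as.numeric(dispersions)

  norm <- sweep(Y, 2, sf, `/`)
  b0 <- log(pmax(rowMeans(norm), 1e-8))
  b1 <- rep(0, G)
  active <- rep(TRUE, G)
  # convergence on the relative negative-binomial deviance change, which
  # also settles for genes whose coefficient drifts under the ridge bound
  # (one group observed at zero)
  nb_dev <- function(mu) {
    ylog <- Y * log(pmax(Y, 1) / mu)
    2 * rowSums(ylog - (Y + 1 / alpha) * log((1 + alpha * Y) /
                                               (1 + alpha * mu)))
  }
  dev_old <- rep(Inf, G)
  for (it in seq_len(max_iter)) {
    eta <- b0 + b1 * xm + offm
    mu <- pmin(exp(eta), 1e12)
    # fitted means floored inside the weights so that groups observed at
    # zero keep non-vanishing information (bounds the fold change and its
    # standard error under complete separation)
    muw <- pmax(mu, minmu)
    w <- muw / (1 + alpha * muw)
    # the working response is floored so that a group observed all-zero
    # settles at a negligible cell mean instead of drifting to -Inf; this
    # bounds the separated-gene fold change at a finite value
    z <- pmax(eta - offm + (Y - mu) / mu, log(minmu) - 7)
    wz <- w * z
    s0 <- rowSums(w)
    s1 <- rowSums(w * xm)
    s2 <- s1 # x is 0/1 so x^2 = x
    t0 <- rowSums(wz)
    t1 <- rowSums(wz * xm)
    det <- s0 * (s2 + ridge) - s1^2
    nb0 <- ((s2 + ridge) * t0 - s1 * t1) / det
    nb1 <- (s0 * t1 - s1 * t0) / det
    step_ok <- is.finite(nb0) & is.finite(nb1)
    b0[step_ok] <- nb0[step_ok]
    b1[step_ok] <- nb1[step_ok]
    dev <- nb_dev(pmin(exp(b0 + b1 * xm + offm), 1e12))
    dconv <- abs(dev - dev_old) / (abs(dev) + 0.1) < 1e-8
    dev_old <- dev
    active <- active & step_ok & !dconv
    if (!any(active)) break
  }
  converged <- !active
  # penalized-information standard error of the group coefficient
  eta <- b0 + b1 * xm + offm
  mu <- pmin(exp(eta), 1e12)
  muw <- pmax(mu, minmu)
  w <- muw / (1 + alpha * muw)
  s0 <- rowSums(w)
  s1 <- rowSums(w * xm)
  det <- s0 * (s1 + ridge) - s1^2
  se_nat <- sqrt(s0 / det)
  lfc <- b1 / log(2)
  se <- se_nat / log(2)
  wald <- lfc / se
  p <- 2 * pnorm(-abs(wald))
  p[!converged] <- NA_real_
  tibble::tibble(gene = rownames(Y), base_mean = rowMeans(norm),
                 lfc_mle = lfc, se = se, wald = wald, p_raw = p,
                 converged = converged)
}

#' Empirical-Bayes shrinkage of log2 fold changes
#'
#' Normal-prior posterior-mean shrinkage: the prior variance `tau2` is
#' solved by method of moments from the excess of the observed fold-change
#' variance over the average squared standard error (floored at 1e-4), and
#' each gene's shrunken estimate is `lfc_mle * tau2 / (tau2 + se^2)` with a
#' 95% interval from the posterior standard deviation. Imprecise estimates
#' are pulled harder; precise ones are nearly untouched.
#'
#' @param results tibble from [wald_test()] (>= 10 genes).
#' @param tau2_floor lower bound on the prior variance.
#' @return `results` plus `lfc_shrunken`, `ci_low`, `ci_high`, and the
#'   prior variance as attribute `tau2`.
#' @export
shrink_lfc <- function(results, tau2_floor = 1e-4) {
  check_columns(results, c("lfc_mle", "se"), "DE results")
  ok <- is.finite(results$lfc_mle) & is.finite(results$se)
  if (sum(ok) < 10) abort("Need >= 10 genes with finite estimates to shrink.")
  tau2 <- max(tau2_floor,
              mean(results$lfc_mle[ok]^2) - mean(results$se[ok]^2))
  shrink <- tau2 / (tau2 + results$se^2)
  post_sd <- sqrt(tau2 * results$se^2 / (tau2 + results$se^2))
  out <- dplyr::mutate(
    results,
    lfc_shrunken = .data$lfc_mle * shrink,
    ci_low = .data$lfc_mle * shrink - 1.96 * post_sd,
    ci_high = .data$lfc_mle * shrink + 1.96 * post_sd
  )
  attr(out, "tau2") <- tau2
  out
}

#' Call differentially expressed genes
#'
#' BH-adjusts the Wald p-values and flags a gene significant when
#' `p_adj <= alpha` and its |shrunken log2 fold change| (or |MLE|, when
#' `use_shrunken = FALSE`) reaches `lfc_min`.
#'
#' @param results tibble from [shrink_lfc()] (or [wald_test()] with
#'   `use_shrunken = FALSE`).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param lfc_min minimum |log2 fold change| (default 1).
#' @param use_shrunken apply the fold-change threshold to the shrunken
#'   estimate (default) or the MLE.
#' @return `results` plus `p_adj` and `significant`.
#' @export
call_de <- function(results, alpha = 0.05, lfc_min = 1,
                    use_shrunken = TRUE) {
  check_columns(results, "p_raw", "DE results")
  lfc_col <- if (use_shrunken && "lfc_shrunken" %in% names(results)) {
    "lfc_shrunken"
  } else {
    "lfc_mle"
  }
  out <- dplyr::mutate(
    results,
    p_adj = adjust_fdr(.data$p_raw, "bh"),
    significant = !is.na(.data$p_adj) & .data$p_adj <= alpha &
      abs(.data[[lfc_col]]) >= lfc_min
  )
  inform(paste0(sum(out$significant), " significant gene(s) of ",
                nrow(out), " tested."))
  out
}

#' Quartile differential-expression stage
#'
#' Runs the complete top-vs-bottom-quartile DE analysis for one analyte:
#' subsets the count matrix to the quartile samples, applies the gene
#' filter, computes size factors, dispersions, Wald statistics, shrinkage,
#' and significance calls. Positive fold changes mean higher expression in
#' the top (high-stimulator) quartile.
#'
#' @param bundle an `expression_bundle`.
#' @param quartiles quartile-label tibble (columns `unit`, `analyte`,
#'   `quartile`) from [score_polarization()] or [assign_quartiles()].
#' @param analyte analyte whose quartile split drives the comparison.
#' @param alpha,lfc_min,use_shrunken significance parameters, see
#'   [call_de()].
#' @param min_total,min_detect_fraction gene-filter parameters.
#' @return tibble of per-gene results (one row per tested gene), with the
#'   removed-gene table as attribute `removed` and prior variance as
#'   attribute `tau2`.
#' @export
quartile_de <- function(bundle, quartiles, analyte, alpha = 0.05,
                        lfc_min = 1, use_shrunken = TRUE, min_total = 3,
                        min_detect_fraction = 0.5) {
  q <- dplyr::filter(quartiles, .data$analyte == !!analyte,
                     .data$quartile %in% c("top", "bottom"))
  samples <- intersect(bundle$sample_ids, q$unit)
  if (length(samples) < 4) {
    abort("Too few quartile samples with expression data.")
  }
  labels <- q$quartile[match(samples, q$unit)]
  if (length(unique(labels)) < 2) abort("Both quartiles must be represented.")
  counts <- bundle$counts[, samples, drop = FALSE]
  filt <- filter_genes(counts, min_total, min_detect_fraction)
  sf <- size_factors(filt$kept)
  disp <- estimate_dispersion(filt$kept, sf)
  res <- wald_test(filt$kept, sf, disp,
                   groups = factor(labels, levels = c("bottom", "top")))
  res <- shrink_lfc(res)
  tau2 <- attr(res, "tau2")
  res <- call_de(res, alpha = alpha, lfc_min = lfc_min,
                 use_shrunken = use_shrunken)
  attr(res, "removed") <- filt$removed
  attr(res, "tau2") <- tau2
  res
}
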