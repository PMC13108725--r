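#' Fit a Gaussian random-intercept mixed model
#'
#' Maximizes the (restricted) likelihood of
#' `y ~ Normal(X beta, sigma2_e * (I + theta Z Z'))`, where `Z` indicates the
#' grouping factor (donor) and `theta = sigma2_d / sigma2_e` is the
#' variance ratio. The fit profiles `beta` and `sigma2_e` out in closed form
#' by generalized least squares and optimizes the 1-D profile log-likelihood
#' over `log(theta)`, also evaluating the `theta = 0` boundary. The
#' intraclass correlation is `sigma2_d / (sigma2_d + sigma2_e) =
#' theta / (1 + theta)`.
#'
#' The denominator degrees of freedom are the containment-style
#' `n_obs - rank(X) - (n_groups - 1)`, which reproduces the F(2, 58) shape of
#' a 63-observation, 3-condition, 3-donor fractionation design.
#'
#' @param data data frame holding the model variables.
#' @param formula fixed-effects formula, e.g. `response ~ condition`.
#' @param group name (string) of the grouping column (random intercept).
#' @param method `"ml"` (default; valid for likelihood-ratio tests on the
#'   random effect) or `"reml"` (preferred for variance reporting).
#' @return object of class `ri_fit` with elements `beta`, `se`, `ci`
#'   (95%), `vcov_beta`, `sigma2_donor`, `sigma2_resid`, `icc`, `theta`,
#'   `loglik`, `n_obs`, `n_groups`, `rank_x`, `df_denominator`,
#'   `r2_marginal`, `r2_conditional`, plus the pieces needed to refit
#'   (`y`, `X`, `group_vec`, `data`, `formula`, `method`).
#' @export
fit_random_intercept <- function(data, formula, group = "donor",
                                 method = c("ml", "reml")) {
  method <- match.arg(method)
  mf <- stats::model.frame(formula, data = data)
  y <- stats::model.response(mf)
  X <- model.matrix(formula, data = data)
  g <- factor(data[[group]])
  if (nlevels(g) < 2) abort("random effect unidentifiable: need >= 2 groups.")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("Design is rank deficient; aliased column(s): ",
                 paste(aliased, collapse = ", ")))
  }
  n <- length(y)
  p <- ncol(X)
  if (n <= p) abort("More coefficients than observations.")

  prof <- function(log_theta) ri_profile(exp(log_theta), y, X, g, method)$ll
  opt <- optimize(prof, interval = c(-30, 15), maximum = TRUE,
                  tol = 1e-10)
  cand_theta <- c(0, exp(opt$maximum))
  lls <- vapply(cand_theta, function(th) ri_profile(th, y, X, g, method)$ll,
                numeric(1))
  theta <- cand_theta[which.max(lls)]
  fit <- ri_profile(theta, y, X, g, method)

  sigma2_e <- fit$sigma2
  sigma2_d <- theta * sigma2_e
  icc <- if (sigma2_d + sigma2_e > 0) sigma2_d / (sigma2_d + sigma2_e) else 0
  # SEs and Wald tests use the degrees-of-freedom-corrected residual
  # variance (the ML plug-in q/n would make them anti-conservative)
  sigma2_inf <- if (method == "ml") sigma2_e * n / (n - p) else sigma2_e
  vcov_beta <- sigma2_inf * fit$xvx_inv
  se <- sqrt(diag(vcov_beta))
  df_den <- n - qrX$rank - (nlevels(g) - 1)
  tcrit <- stats::qt(0.975, df = max(df_den, 1))
  fitted_fixed <- drop(X %*% fit$beta)
  sigma2_f <- mean((fitted_fixed - mean(fitted_fixed))^2)
  tot <- sigma2_f + sigma2_d + sigma2_e
  structure(
    list(beta = setNames(fit$beta, colnames(X)), se = setNames(se, colnames(X)),
         ci = cbind(lower = fit$beta - tcrit * se,
                    upper = fit$beta + tcrit * se),
         vcov_beta = vcov_beta,
         sigma2_donor = sigma2_d, sigma2_resid = sigma2_e, icc = icc,
         theta = theta, loglik = fit$ll, n_obs = n, n_groups = nlevels(g),
         rank_x = qrX$rank, df_denominator = df_den,
         r2_marginal = if (tot > 0) sigma2_f / tot else NA_real_,
         r2_conditional = if (tot > 0) (sigma2_f + sigma2_d) / tot
                          else NA_real_,
         fitted_fixed = fitted_fixed,
         y = y, X = X, group_vec = g, data = data, formula = formula,
         method = method),
    class = "ri_fit"
  )
}

# profile log-likelihood at a fixed variance ratio theta.
# V = I + theta * Z Z' is block diagonal: per group of size m,
# V_g^{-1} = I - theta/(1 + m theta) * J and |V_g| = 1 + m theta.
ri_profile <- function(theta, y, X, g, method) {
  n <- length(y)
  p <- ncol(X)
  idx <- split(seq_len(n), g)
  m <- lengths(idx)
  vinv <- function(a) {
    a <- as.matrix(a)
    out <- a
    for (k in seq_along(idx)) {
      rows <- idx[[k]]
      shrink <- theta / (1 + m[k] * theta)
      out[rows, ] <- a[rows, , drop = FALSE] -
        matrix(shrink * colSums(a[rows, , drop = FALSE]),
               nrow = m[k], ncol = ncol(a), byrow = TRUE)
    }
    out
  }
  logdet_v <- sum(log1p(m * theta))
  vy <- vinv(y)
  vx <- vinv(X)
  xvx <- crossprod(X, vx)
  xvy <- crossprod(X, vy)
  xvx_inv <- solve(xvx)
  beta <- drop(xvx_inv %*% xvy)
  r <- y - drop(X %*% beta)
  q <- sum(r * vinv(r))
  if (method == "ml") {
    sigma2 <- q / n
    ll <- -0.5 * (n * log(2 * pi * sigma2) + logdet_v + n)
  } else {
    sigma2 <- q / (n - p)
    ll <- -0.5 * ((n - p) * log(2 * pi * sigma2) + logdet_v +
                    determinant(xvx, logarithm = TRUE)$modulus + (n - p))
  }
  list(ll = as.numeric(ll), beta = beta, sigma2 = sigma2, xvx_inv = xvx_inv)
}

#' @export
print.ri_fit <- function(x, ...) {
  cat("<ri_fit> ", x$n_obs, " obs, ", x$n_groups, " groups (",
      x$method, ")\n", sep = "")
  cat("  ICC ", signif(x$icc, 4), "  sigma2_donor ",
      signif(x$sigma2_donor, 4), "  sigma2_resid ",
      signif(x$sigma2_resid, 4), "\n", sep = "")
  cat("  logLik ", signif(x$loglik, 8), "\n", sep = "")
  invisible(x)
}

#' Wald F-test of the fixed effects
#'
#' Joint test that all non-intercept fixed coefficients are zero, using the
#' fitted coefficient covariance and the containment denominator df — the
#' overall treatment-effect test of a one-factor mixed model.
#'
#' @param fit an `ri_fit`.
#' @return tibble: `f`, `df1`, `df2`, `p`.
#' @export
anova_fixed <- function(fit) {
  stopifnot(inherits(fit, "ri_fit"))
  idx <- which(names(fit$beta) != "(Intercept)")
  if (length(idx) == 0) abort("Model has no non-intercept fixed effect.")
  b <- fit$beta[idx]
  V <- fit$vcov_beta[idx, idx, drop = FALSE]
  fstat <- drop(t(b) %*% solve(V, b)) / length(idx)
  df2 <- max(fit$df_denominator, 1)
  tibble::tibble(f = fstat, df1 = length(idx), df2 = df2,
                 p = stats::pf(fstat, length(idx), df2, lower.tail = FALSE))
}

#' Likelihood-ratio test for the donor random intercept
#'
#' Compares the ML mixed-model fit against ordinary least squares with the
#' same fixed effects: `chi2 = 2 (loglik_full - loglik_ols)`. The headline
#' p-value uses the plain chi-square reference with df = 1; because the null
#' hypothesis `sigma2_donor = 0` lies on the boundary of the parameter
#' space, that reference is conservative, and the boundary-corrected
#' half-mixture `0.5 chi2_0 + 0.5 chi2_1` p-value is reported alongside.
#'
#' @param fit an `ri_fit` fitted with `method = "ml"`.
#' @return tibble: `chi2`, `df`, `p` (df = 1 convention),
#'   `p_boundary` (mixture).
#' @export
lrt_random_intercept <- function(fit) {
  stopifnot(inherits(fit, "ri_fit"))
  if (fit$method != "ml") {
    abort("Likelihood-ratio test requires an ML fit; refit with method = 'ml'.")
  }
  ols <- lm(fit$y ~ fit$X - 1)
  ll0 <- as.numeric(logLik(ols))
  chi2 <- max(0, 2 * (fit$loglik - ll0))
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  p_boundary <- if (chi2 == 0) 1 else 0.5 * p
  tibble::tibble(chi2 = chi2, df = 1L, p = p, p_boundary = p_boundary)
}

#' Tukey-Kramer pairwise contrasts of a one-factor mixed model
#'
#' All unordered pairs of factor levels from a fit whose fixed effects are
#' `response ~ factor`. Standard errors come from the fitted covariance of
#' the coefficients; p-values use the studentized-range distribution with
#' the fit's containment denominator df.
#'
#' @param fit an `ri_fit` whose formula right-hand side is a single
#'   categorical factor.
#' @param factor_name name of the factor column (default: the single
#'   right-hand-side variable of the fit formula).
#' @return tibble: `level_a`, `level_b`, `estimate` (a minus b), `se`,
#'   `df`, `t`, `p_adj`.
#' @export
pairwise_contrasts <- function(fit, factor_name = NULL) {
  stopifnot(inherits(fit, "ri_fit"))
  rhs <- all.vars(fit$formula[[3]])
  if (is.null(factor_name)) {
    if (length(rhs) != 1) {
      abort("Fit must have a single categorical fixed effect.")
    }
    factor_name <- rhs
  }
  f <- factor(fit$data[[factor_name]])
  levels_ <- levels(f)
  if (length(levels_) < 2) abort("Factor must have >= 2 levels.")
  # row of the design matrix representing each level's cell mean
  proto <- fit$data[match(levels_, as.character(f)), , drop = FALSE]
  L <- model.matrix(fit$formula, data = proto)
  pairs <- utils::combn(levels_, 2)
  k <- length(levels_)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]
    b <- pairs[2, i]
    cvec <- L[match(a, levels_), ] - L[match(b, levels_), ]
    est <- sum(cvec * fit$beta)
    se <- sqrt(drop(t(cvec) %*% fit$vcov_beta %*% cvec))
    tval <- est / se
    p <- ptukey(abs(tval) * sqrt(2), nmeans = k,
                df = max(fit$df_denominator, 1), lower.tail = FALSE)
    tibble::tibble(level_a = a, level_b = b, estimate = est, se = se,
                   df = fit$df_denominator, t = tval, p_adj = p)
  })
}

#' Marginal and conditional R-squared of a mixed model
#'
#' Variance-explained decomposition for a random-intercept Gaussian model:
#' with `sigma2_f` the variance of the fixed-effect predictions over the
#' observations, the marginal R2 is `sigma2_f / (sigma2_f + sigma2_d +
#' sigma2_e)` and the conditional R2 adds the donor variance to the
#' numerator.
#'
#' @param fit an `ri_fit`.
#' @return tibble: `r2_marginal`, `r2_conditional`.
#' @export
r2_nakagawa <- function(fit) {
  stopifnot(inherits(fit, "ri_fit"))
  if (is.na(fit$r2_marginal)) abort("Zero total variance: R2 undefined.")
  tibble::tibble(r2_marginal = fit$r2_marginal,
                 r2_conditional = fit$r2_conditional)
}

#' Mixed-effects dose-response fit with optional inverse transform
#'
#' Fits `transform(response) ~ dose` with a donor random intercept. With
#' `transform = "inverse"` (the default, appropriate when the raw
#' dose-response curve saturates) the model is `1/y = a + b dose` and the
#' predicted means at each observed dose are back-transformed as
#' `1 / (a + b dose)`.
#'
#' @param table tibble with columns `donor`, `dose`, `response`.
#' @param transform `"inverse"` or `"identity"`.
#' @param method passed to [fit_random_intercept()].
#' @return list of class `dose_fit`: `fit` (the `ri_fit` on the transformed
#'   scale), `slope`, `slope_se`, `slope_ci`, `predicted` (tibble `dose`,
#'   `predicted_mean` in response units), `transform`.
#' @export
dose_response_fit <- function(table, transform = c("inverse", "identity"),
                              method = "ml") {
  transform <- match.arg(transform)
  check_columns(table, c("donor", "dose", "response"), "dose table")
  if (length(unique(table$dose)) < 2) {
    abort("dose effect unidentifiable: need >= 2 distinct dose levels.")
  }
  if (transform == "inverse") {
    bad <- which(table$response <= 0)
    if (length(bad) > 0) {
      abort(paste0("Inverse transform requires positive responses; ",
                   "offending row(s): ", paste(head(bad, 5), collapse = ", ")))
    }
    table$.tresp <- 1 / table$response
  } else {
    table$.tresp <- table$response
  }
  fit <- fit_random_intercept(table, .tresp ~ dose, group = "donor",
                              method = method)
  doses <- sort(unique(table$dose))
  lin <- fit$beta[1] + fit$beta[2] * doses
  pred <- if (transform == "inverse") 1 / lin else lin
  structure(
    list(fit = fit, slope = unname(fit$beta[2]),
         slope_se = unname(fit$se[2]),
         slope_ci = fit$ci[2, ],
         predicted = tibble::tibble(dose = doses, predicted_mean = pred),
         transform = transform),
    class = "dose_fit"
  )
}

#' @export
print.dose_fit <- function(x, ...) {
  cat("<dose_fit> slope ", signif(x$slope, 4), " (", x$transform,
      " scale)\n", sep = "")
  print(x$predicted)
  invisible(x)
}

#' Exosomal-to-free analyte ratio
#'
#' Ratio of the analyte content of a lysed exosome fraction to the
#' exosome-depleted (free) fraction of the same conditioned media,
#' volume-matched upstream. Non-positive denominators give `NA`.
#'
#' @param lysed_exosome analyte in the lysed exosome fraction, pg/mL.
#' @param depleted analyte in the exosome-depleted fraction, pg/mL.
#' @return numeric ratio(s); `NA` where `depleted <= 0`.
#' @export
exosome_ratio <- function(lysed_exosome, depleted) {
  out <- ifelse(depleted > 0, lysed_exosome / depleted, NA_real_)
  if (anyNA(out)) {
    warn("Non-positive depleted-fraction value(s): ratio undefined (NA).")
  }
  out
}

#' Two-group and one-sample comparisons
#'
#' Thin uniform interface over the standard tests used around the scoring
#' pipeline: Welch and Student t-tests, exact/normal Wilcoxon rank-sum,
#' Kruskal-Wallis for multi-level factors (pass a list of groups as `a`),
#' and the one-sample t-test against a reference. With
#' `normality_check = TRUE` a Shapiro-Wilk pre-test at alpha = 0.05 on each
#' group routes to Wilcoxon on failure and Welch otherwise; the routing is
#' recorded in the result.
#'
#' @param a numeric vector (or list of numeric vectors for `"kruskal"`).
#' @param b second group (two-sample tests) or `NULL`.
#' @param reference numeric reference value for `"one_sample_t"`.
#' @param test one of `"welch_t"`, `"student_t"`, `"wilcoxon"`,
#'   `"kruskal"`, `"one_sample_t"`.
#' @param normality_check logical; Shapiro-Wilk routing as above.
#' @return tibble: `test`, `statistic`, `df`, `p`, `conf_low`, `conf_high`,
#'   `routed`.
#' @export
two_group_compare <- function(a, b = NULL, reference = NULL,
                              test = c("welch_t", "student_t", "wilcoxon",
                                       "kruskal", "one_sample_t"),
                              normality_check = FALSE) {
  test <- match.arg(test)
  routed <- FALSE
  if (normality_check && test %in% c("welch_t", "student_t", "wilcoxon")) {
    shap_p <- c(shapiro.test(a)$p.value, shapiro.test(b)$p.value)
    chosen <- if (any(shap_p < 0.05)) "wilcoxon" else "welch_t"
    routed <- chosen != test
    if (routed) {
      inform(paste0("Normality pre-test routed the comparison to ", chosen,
                    " (Shapiro-Wilk p = ",
                    paste(signif(shap_p, 3), collapse = ", "), ")."))
    }
    test <- chosen
  }
  res <- switch(
    test,
    welch_t = t.test(a, b, var.equal = FALSE),
    student_t = t.test(a, b, var.equal = TRUE),
    wilcoxon = wilcox.test(a, b, exact = TRUE, correct = FALSE),
    kruskal = {
      if (!is.list(a)) a <- list(a, b)
      kruskal.test(a)
    },
    one_sample_t = {
      if (is.null(reference)) abort("one_sample_t needs a `reference` value.")
      if (sd(a) == 0) {
        # degenerate: all values equal; t statistic 0/0 when equal to the
        # reference, define statistic 0 and p 1 in that case
        if (all(a == reference)) {
          return(tibble::tibble(test = test, statistic = 0, df = length(a) - 1,
                                p = 1, conf_low = reference,
                                conf_high = reference, routed = routed))
        }
      }
      t.test(a, mu = reference)
    }
  )
  ci <- if (!is.null(res$conf.int)) res$conf.int else c(NA_real_, NA_real_)
  tibble::tibble(
    test = test,
    statistic = unname(res$statistic),
    df = if (!is.null(res$parameter)) unname(res$parameter) else NA_real_,
    p = res$p.value,
    conf_low = ci[1], conf_high = ci[2],
    routed = routed
  )
}
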