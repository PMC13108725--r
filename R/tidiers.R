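#' Tidy a random-intercept mixed-model fit
#'
#' One row per fixed coefficient with estimate, standard error and 95%
#' confidence limits (containment df).
#'
#' @param x an `ri_fit`.
#' @param ... unused.
#' @return tibble: `term`, `estimate`, `std_error`, `conf_low`,
#'   `conf_high`.
#' @method tidy ri_fit
#' @export
tidy.ri_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$beta),
    estimate = unname(x$beta),
    std_error = unname(x$se),
    conf_low = unname(x$ci[, "lower"]),
    conf_high = unname(x$ci[, "upper"])
  )
}

#' One-row summary of a random-intercept mixed-model fit
#'
#' @param x an `ri_fit`.
#' @param ... unused.
#' @return tibble with variance components, ICC, log-likelihood, R2 values
#'   and dimensions.
#' @method glance ri_fit
#' @export
glance.ri_fit <- function(x, ...) {
  tibble::tibble(
    sigma2_donor = x$sigma2_donor, sigma2_resid = x$sigma2_resid,
    icc = x$icc, loglik = x$loglik,
    r2_marginal = x$r2_marginal, r2_conditional = x$r2_conditional,
    n_obs = x$n_obs, n_groups = x$n_groups,
    df_denominator = x$df_denominator, method = x$method
  )
}

#' @rdname tidy.ri_fit
#' @method tidy dose_fit
#' @export
tidy.dose_fit <- function(x, ...) tidy(x$fit)

#' @rdname glance.ri_fit
#' @method glance dose_fit
#' @export
glance.dose_fit <- function(x, ...) glance(x$fit)
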