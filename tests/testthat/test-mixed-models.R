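test_that("profile-likelihood fit agrees with lme4 on log-likelihood and ICC", {
  skip_if_not_installed("lme4")
  for (seed in c(3, 17, 29)) {
    d <- make_grouped_data(4, 10, sd_group = 0.4, sd_resid = 0.6,
                           seed = seed, standardize_group = FALSE)
    fit <- fit_random_intercept(d, y ~ unit, group = "donor", method = "ml")
    ref <- suppressMessages(
      lme4::lmer(y ~ unit + (1 | donor), data = d, REML = FALSE))
    expect_equal(fit$loglik, as.numeric(stats::logLik(ref)),
                 tolerance = 1e-5)
    v <- as.data.frame(lme4::VarCorr(ref))
    expect_equal(fit$icc, v$vcov[1] / sum(v$vcov), tolerance = 1e-3)
    expect_equal(unname(fit$beta), unname(lme4::fixef(ref)),
                 tolerance = 1e-4)
  }
})

test_that("optimized profile likelihood matches a dense grid-search oracle", {
  worst <- 0
  for (seed in 1:20) {
    d <- make_grouped_data(4, 8, sd_group = runif(1, 0, 0.8),
                           sd_resid = runif(1, 0.3, 1), seed = 400 + seed,
                           standardize_group = FALSE)
    fit <- fit_random_intercept(d, y ~ unit, group = "donor")
    thetas <- exp(seq(log(1e-8), log(1e6), length.out = 1000))
    grid_best <- max(vapply(
      thetas,
      function(th) macpolar:::ri_profile(th, fit$y, fit$X, fit$group_vec,
                                         "ml")$ll,
      numeric(1)))
    worst <- max(worst, grid_best - fit$loglik)
  }
  expect_lt(worst, 1e-6)
})

test_that("balanced one-way REML variance matches the ANOVA moment estimator", {
  rel_err <- vapply(1:50, function(seed) {
    set.seed(seed)
    a <- 6 # groups
    n <- 8 # per group
    g <- gl(a, n)
    y <- rnorm(a, 0, runif(1, 0.2, 1))[g] + rnorm(a * n)
    d <- data.frame(y = y, donor = g)
    fit <- fit_random_intercept(d, y ~ 1, group = "donor", method = "reml")
    msb <- n * var(tapply(y, g, mean))
    msw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2))) / (a * (n - 1))
    mom <- max(0, (msb - msw) / n)
    denom <- max(mom, 1e-3)
    abs(fit$sigma2_donor - mom) / denom
  }, numeric(1))
  expect_lt(max(rel_err), 1e-4)
})

test_that("boundary data give zero donor variance and a null LRT", {
  d <- make_grouped_data(5, 20, sd_group = 0, sd_resid = 0.5, seed = 11)
  fit <- fit_random_intercept(d, y ~ unit, group = "donor")
  expect_lt(fit$sigma2_donor, 1e-6)
  expect_lt(fit$icc, 1e-6)
  lrt <- lrt_random_intercept(fit)
  expect_lt(lrt$chi2, 1e-6)
  expect_gt(lrt$p, 0.99)
})

test_that("the LRT chi-square is never negative and the mixture p is half", {
  for (seed in 1:50) {
    d <- make_grouped_data(3, 6, sd_group = runif(1, 0, 0.5),
                           sd_resid = runif(1, 0.3, 1), seed = 500 + seed,
                           standardize_group = FALSE)
    fit <- fit_random_intercept(d, y ~ unit, group = "donor")
    lrt <- lrt_random_intercept(fit)
    expect_gte(lrt$chi2, 0)
    expect_lte(lrt$p_boundary, lrt$p)
  }
  # REML fits are rejected
  d <- make_grouped_data(3, 6, 0.3, 0.5, seed = 1)
  fr <- fit_random_intercept(d, y ~ unit, group = "donor", method = "reml")
  expect_error(lrt_random_intercept(fr), "ML")
})

test_that("ICC is invariant under affine transforms of the response", {
  d <- make_grouped_data(4, 12, 0.4, 0.5, seed = 23)
  f1 <- fit_random_intercept(d, y ~ unit, group = "donor")
  d$y <- 3.7 * d$y - 11
  f2 <- fit_random_intercept(d, y ~ unit, group = "donor")
  expect_equal(f1$icc, f2$icc, tolerance = 1e-6)
})

test_that("degenerate designs are rejected with informative errors", {
  d <- make_grouped_data(3, 6, 0.3, 0.5, seed = 2)
  d1 <- d[d$donor == "D1", ]
  expect_error(fit_random_intercept(d1, y ~ unit, group = "donor"),
               "unidentifiable")
  d$alias <- d$y * 0 + as.integer(factor(d$unit)) # collinear with unit
  expect_error(
    fit_random_intercept(d, y ~ unit + alias, group = "donor"),
    "rank deficient")
})

test_that("pairwise contrasts recover planted condition effects", {
  d <- simulate_fractionation(condition_effects = c(a = 0, b = 0, c = 1000),
                              donor_sd = 200, residual_sd = 10, seed = 6)
  fit <- fit_random_intercept(d, response ~ condition, group = "donor")
  ctr <- pairwise_contrasts(fit, "condition")
  expect_equal(nrow(ctr), 3) # C(3,2)
  est <- ctr$estimate[ctr$level_a == "a" & ctr$level_b == "c"]
  expect_lt(abs(abs(est) - 1000) / 1000, 0.01)
  # antisymmetry: the a-b contrast is minus the b-a difference of cell means
  means <- tapply(d$response, d$condition, mean)
  expect_equal(sign(ctr$estimate),
               sign(means[ctr$level_a] - means[ctr$level_b]),
               ignore_attr = TRUE)
  # exactly identical group means -> estimates 0, all adjusted p = 1
  set.seed(8)
  base <- rnorm(21, 1500, 300)
  d0 <- tidyr::expand_grid(donor = rep(paste0("D", 1:3)),
                           line = paste0("CL", 1:7),
                           condition = c("a", "b", "c"))
  d0 <- d0[order(d0$condition), ]
  d0$response <- rep(base, 3) # same values in every condition
  ctr0 <- pairwise_contrasts(
    fit_random_intercept(d0, response ~ condition, group = "donor"),
    "condition")
  expect_equal(ctr0$estimate, rep(0, 3), tolerance = 1e-8)
  expect_true(all(ctr0$p_adj > 0.99))
})

test_that("Tukey-Kramer adjusted p never falls below the unadjusted t p", {
  for (seed in c(4, 9, 14)) {
    d <- simulate_fractionation(condition_effects = c(a = 0, b = 150,
                                                      c = 400),
                                seed = seed)
    fit <- fit_random_intercept(d, response ~ condition, group = "donor")
    ctr <- pairwise_contrasts(fit, "condition")
    p_t <- 2 * pt(-abs(ctr$t), df = ctr$df)
    expect_true(all(ctr$p_adj >= p_t - 1e-12))
  }
})

test_that("Nakagawa R2 identities hold and variance shares are recovered", {
  d <- make_grouped_data(4, 12, 0.4, 0.5, seed = 31)
  fit0 <- fit_random_intercept(d, y ~ 1, group = "donor")
  expect_equal(r2_nakagawa(fit0)$r2_marginal, 0)
  # donor variance estimated at the zero boundary: marginal = conditional
  db <- make_grouped_data(5, 20, 0, 0.5, seed = 11)
  fitb <- fit_random_intercept(db, y ~ unit, group = "donor")
  expect_lt(fitb$sigma2_donor, 1e-8)
  r2b <- r2_nakagawa(fitb)
  expect_equal(r2b$r2_marginal, r2b$r2_conditional, tolerance = 1e-6)
  # planted shares (fixed 0.4, donor 0.3, residual 0.3) at n = 500
  set.seed(33)
  n <- 500
  x <- rnorm(n)
  g <- gl(10, n / 10)
  u <- rnorm(10)
  u <- (u - mean(u)) / sd(u) * sqrt(0.3)
  dd <- data.frame(x = sqrt(0.4) / sd(x) * x, donor = g)
  dd$y <- dd$x + u[g] + rnorm(n, 0, sqrt(0.3))
  fit <- fit_random_intercept(dd, y ~ x, group = "donor")
  r2 <- r2_nakagawa(fit)
  expect_lt(abs(r2$r2_marginal - 0.4), 0.05)
  expect_lt(abs(r2$r2_conditional - 0.7), 0.05)
})

test_that("fixed-effect F test is calibrated under the null", {
  ps <- vapply(1:200, function(s) {
    d <- simulate_fractionation(n_donors = 3, n_lines = 7,
                                condition_effects = c(a = 0, b = 0, c = 0),
                                donor_sd = 0, residual_sd = 100, seed = s)
    anova_fixed(
      fit_random_intercept(d, response ~ condition, group = "donor"))$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("dose-response fit recovers the inverse-scale model", {
  d <- simulate_dose_response(seed = 12)
  df <- dose_response_fit(d)
  truth <- attr(d, "truth")
  expect_lt(abs(df$slope - truth$inverse_slope) / abs(truth$inverse_slope),
            0.25)
  expect_equal(df$predicted$dose, c(0, 1.25, 2.5, 5))
  # identity transform on linear data recovers the slope at low noise
  set.seed(13)
  lin <- tidyr::expand_grid(donor = paste0("D", 1:4), dose = c(0, 1, 2, 4))
  lin$response <- 5 + 2 * lin$dose + rnorm(nrow(lin), 0, 0.05)
  fi <- dose_response_fit(lin, transform = "identity")
  expect_lt(abs(fi$slope - 2) / 2, 0.05)
  # non-positive responses are rejected under the inverse transform
  lin$response[1] <- 0
  expect_error(dose_response_fit(lin, transform = "inverse"), "positive")
  # zero-slope truth: the slope CI covers zero at roughly nominal rate
  cover <- vapply(1:100, function(s) {
    d0 <- simulate_dose_response(inverse_slope = 0, seed = 700 + s)
    ci <- dose_response_fit(d0)$slope_ci
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1))
  expect_gt(mean(cover), 0.88)
  expect_lte(mean(cover), 1)
})

test_that("exosome ratio handles the degenerate denominator", {
  expect_equal(exosome_ratio(100, 100), 1)
  expect_equal(exosome_ratio(140, 10), 14)
  expect_warning(r <- exosome_ratio(100, 0), "undefined")
  expect_true(is.na(r))
})

test_that("two-group comparisons match the standard tests and route on normality", {
  # identical groups: t-test p near 1; degenerate one-sample defined as p = 1
  a <- c(1.1, 2.2, 3.3, 4.4)
  expect_gt(two_group_compare(a, a, test = "welch_t")$p, 0.99)
  one <- two_group_compare(c(1, 1, 1), reference = 1, test = "one_sample_t")
  expect_equal(one$statistic, 0)
  expect_equal(one$p, 1)
  # exact rank-sum: fully separated groups of 3 -> p = 2/C(6,3) = 0.1
  w <- two_group_compare(c(1, 2, 3), c(4, 5, 6), test = "wilcoxon")
  expect_equal(w$p, 0.1)
  # kruskal on three groups passes through the standard statistic
  set.seed(3)
  gr <- list(rnorm(8), rnorm(8, 2), rnorm(8))
  k <- two_group_compare(gr, test = "kruskal")
  expect_equal(k$statistic, unname(kruskal.test(gr)$statistic))
  # skewed data route to wilcoxon under the normality pre-test
  set.seed(9)
  sk <- exp(rnorm(30, 0, 2))
  nm <- rnorm(30)
  expect_message(r <- two_group_compare(sk, nm, test = "welch_t",
                                        normality_check = TRUE),
                 "wilcoxon")
  expect_identical(r$test, "wilcoxon")
  expect_true(r$routed)
})
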