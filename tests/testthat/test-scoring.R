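test_that("modified z-score reproduces the hand-computed worked vector", {
  z <- modified_z(c(1, 2, 3, 4, 100))
  # median 3, MAD 1: 0.6745 * (x - 3)
  expect_equal(z, c(-1.3490, -0.6745, 0, 0.6745, 65.4265), tolerance = 1e-12)
  # the point one MAD above/below the median scores exactly +/- the constant
  expect_identical(z[4], 0.6745)
  expect_identical(z[2], -0.6745)
  # value at the median maps to zero
  expect_identical(z[3], 0)
})

test_that("modified z-score is shift-invariant, scale-equivariant and robustly centred", {
  for (seed in 1:10) {
    set.seed(seed)
    x <- rlnorm(15, 3, 1)
    z <- modified_z(x)
    expect_equal(modified_z(x + 17.3), z, tolerance = 1e-10)
    expect_equal(modified_z(x * 4.2), z, tolerance = 1e-10)
    expect_equal(median(z), 0)
    expect_equal(median(abs(z)), 0.6745, tolerance = 1e-12)
    # order preserving
    expect_identical(order(z), order(x))
  }
})

test_that("zero-MAD vectors use the mean-absolute-deviation fallback or abort", {
  x <- c(1, 1, 1, 1, 9) # median 1, MAD 0, mean abs dev 1.6
  expect_warning(z <- modified_z(x), "MAD is zero")
  expect_equal(z[5], 0.7979 * 8 / 1.6, tolerance = 1e-12)
  expect_error(modified_z(x, mad_fallback = "error"), "MAD is zero")
  expect_silent(expect_equal(modified_z(c(2, 2, 2)), c(0, 0, 0)))
})

test_that("analyte retention follows the censored-fraction rule at the boundary", {
  tab <- tibble::tibble(
    analyte = rep(c("clean", "borderline"), each = 100),
    below_lloq = c(rep(FALSE, 100), rep(TRUE, 43), rep(FALSE, 57))
  )
  res <- filter_analytes_by_lloq(tab, max_censored_fraction = 0.4)
  expect_true(res$retained[res$analyte == "clean"])
  expect_false(res$retained[res$analyte == "borderline"]) # 0.43 > 0.40
  # exactly at the threshold is retained
  tab2 <- tibble::tibble(analyte = "edge",
                         below_lloq = c(rep(TRUE, 40), rep(FALSE, 60)))
  expect_true(filter_analytes_by_lloq(tab2, 0.4)$retained)
})

test_that("censored-value imputation implements half-LLoQ, LLoQ and drop", {
  tab <- tibble::tibble(donor = "D1", unit = c("A", "B"), analyte = "x",
                        concentration = c(0.5, 5), below_lloq = c(TRUE, FALSE))
  lloq <- c(x = 2)
  expect_equal(impute_censored(tab, lloq, "half_lloq")$concentration[1], 1)
  expect_equal(impute_censored(tab, lloq, "lloq")$concentration[1], 2)
  expect_equal(nrow(impute_censored(tab, lloq, "drop")), 1)
  expect_equal(impute_censored(tab, lloq, "half_lloq")$concentration[2], 5)
})

test_that("donor aggregation reports the arithmetic mean and SEM", {
  scored <- tibble::tibble(donor = c("D1", "D2", "D3"), unit = "L1",
                           analyte = "x", mod_z = c(1, 2, 3))
  agg <- aggregate_scores(scored)
  expect_equal(agg$mean_z, 2)
  expect_equal(agg$sem, sd(c(1, 2, 3)) / sqrt(3), tolerance = 1e-12)
  expect_equal(round(agg$sem, 4), 0.5774)
  # single donor: mean passes through, SEM missing
  one <- aggregate_scores(scored[1, ])
  expect_equal(one$mean_z, 1)
  expect_true(is.na(one$sem))
  # identical donors: SEM exactly zero
  same <- aggregate_scores(dplyr::mutate(scored, mod_z = 2))
  expect_equal(same$sem, 0)
})

test_that("per-unit means are invariant to donor ordering", {
  set.seed(8)
  tab <- tidyr::expand_grid(donor = paste0("D", 1:3),
                            unit = paste0("L", 1:10), analyte = c("a", "b"))
  tab$concentration <- rlnorm(nrow(tab), 2, 0.5)
  s1 <- aggregate_scores(score_observations(tab))
  shuffled <- tab[sample(nrow(tab)), ]
  s2 <- aggregate_scores(score_observations(shuffled))
  merged <- dplyr::inner_join(s1, s2, by = c("unit", "analyte"))
  expect_equal(merged$mean_z.x, merged$mean_z.y, tolerance = 1e-12)
})

test_that("quartile groups have size ceiling(n/4), are disjoint, and break ties by id", {
  mk <- function(n, scores) {
    tibble::tibble(unit = sprintf("u%02d", seq_len(n)), analyte = "x",
                   mean_z = scores, is_control = FALSE)
  }
  # n = 23 gives the 6-per-group split
  q23 <- assign_quartiles(mk(23, seq_len(23)), "x")
  expect_equal(sum(q23$quartile == "top"), 6)
  expect_equal(sum(q23$quartile == "bottom"), 6)
  # n = 8, scores 1..8: direct ranking
  q8 <- assign_quartiles(mk(8, 1:8), "x")
  expect_setequal(q8$unit[q8$quartile == "top"], c("u07", "u08"))
  expect_setequal(q8$unit[q8$quartile == "bottom"], c("u01", "u02"))
  expect_length(intersect(q8$unit[q8$quartile == "top"],
                          q8$unit[q8$quartile == "bottom"]), 0)
  # tie at the boundary: lexicographically smaller id enters, reproducibly
  scores <- c(10, 9, 5, 5, 5, 4, 3, 2, 1, 0)
  d <- mk(10, scores) # k = 3; u03/u04/u05 tied at 5 for the last top slot
  q1 <- assign_quartiles(d, "x")
  q2 <- assign_quartiles(d[sample(10), ], "x")
  expect_setequal(q1$unit[q1$quartile == "top"], c("u01", "u02", "u03"))
  expect_identical(sort(q1$unit[q1$quartile == "top"]),
                   sort(q2$unit[q2$quartile == "top"]))
  expect_error(assign_quartiles(mk(7, 1:7), "x"), ">= 8")
})

test_that("the scoring stage retains 7 of 10 default-scenario analytes", {
  sim <- simulate_cytokine_experiment(make_default_scenario(21))
  sp <- score_polarization(sim$table, sim$lloq_map, control_units = "CTRL")
  expect_length(sp$retained_analytes, 7)
  expect_equal(nrow(sp$analyte_retention), 10)
  # quartiles built for every retained analyte over the 25 non-control lines
  expect_equal(sort(unique(sp$quartiles$analyte)), sort(sp$retained_analytes))
  expect_false("CTRL" %in% sp$quartiles$unit)
  expect_equal(sum(sp$quartiles$quartile == "top"),
               7 * ceiling(25 / 4))
})
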