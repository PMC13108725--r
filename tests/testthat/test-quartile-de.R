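test_that("gene filter applies both rules with the documented boundaries", {
  cnt <- rbind(
    low_total   = c(1, 1, 1, 0),   # total 3 <= 3 -> removed
    boundary    = c(0, 0, 5, 5),   # detected in exactly 50% -> kept
    sparse      = c(9, 0, 0, 0),   # detected in 25% -> removed
    expressed   = c(5, 6, 7, 8)
  )
  colnames(cnt) <- paste0("s", 1:4)
  f <- filter_genes(cnt)
  expect_setequal(rownames(f$kept), c("boundary", "expressed"))
  expect_setequal(f$removed$gene, c("low_total", "sparse"))
  # constructed 10-gene toy with 4 designed failures keeps exactly 6
  set.seed(1)
  big <- matrix(rpois(60, 30), 10, 6,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  big[1:2, ] <- 0
  big[3, ] <- c(1, 1, 1, 0, 0, 0)
  big[4, ] <- c(20, 0, 0, 0, 0, 0)
  expect_equal(nrow(filter_genes(big)$kept), 6)
  expect_error(filter_genes(big[0, , drop = FALSE]), "Empty")
})

test_that("size factors reproduce the hand-computed median-of-ratios example", {
  m <- matrix(c(2, 4, 4, 8), 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  # geometric means (2*4)^0.5, (4*8)^0.5; ratios 2/sqrt(8) and 4/sqrt(32)
  expect_equal(unname(size_factors(m)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-10)
  # identical samples: equal factors
  m2 <- cbind(s1 = c(3, 9, 27), s2 = c(3, 9, 27))
  sf2 <- size_factors(m2)
  expect_equal(unname(sf2[1]), unname(sf2[2]))
  # equivariance: doubling one sample doubles its factor relative to the
  # others (factors are defined up to a common scale)
  m3 <- m
  m3[, 2] <- m3[, 2] * 2
  r <- size_factors(m3)
  r0 <- size_factors(m)
  expect_equal(unname((r[2] / r[1]) / (r0[2] / r0[1])), 2,
               tolerance = 1e-10)
  # invariant under gene reordering
  set.seed(2)
  m4 <- matrix(rpois(50 * 4, 40), 50, 4,
               dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
  expect_equal(size_factors(m4), size_factors(m4[sample(50), ]))
  # all-zero sample rejected by name
  m5 <- m
  m5[, 2] <- 0
  expect_error(size_factors(m5), "s2")
})

test_that("size factors agree with the DESeq2 reference on a shared fixture", {
  skip_if_not_installed("DESeq2")
  set.seed(6)
  cnt <- matrix(rnbinom(200 * 6, mu = 50, size = 10), 200, 6,
                dimnames = list(paste0("g", 1:200), paste0("s", 1:6)))
  ref <- DESeq2::estimateSizeFactorsForMatrix(cnt)
  expect_equal(size_factors(cnt), ref, tolerance = 1e-8)
})

test_that("dispersion estimates recover the truth and floor degenerate genes", {
  # NB truth alpha = 0.2 with 20 samples
  meds <- vapply(1:10, function(s) {
    set.seed(s)
    cnt <- matrix(rnbinom(500 * 20, mu = 100, size = 5), 500, 20,
                  dimnames = list(paste0("g", 1:500), paste0("s", 1:20)))
    d <- estimate_dispersion(cnt, rep(1, 20))
    median(d$alpha)
  }, numeric(1))
  expect_true(all(meds > 0.1 & meds < 0.4))
  # Poisson counts at many samples push the dispersion toward the floor
  set.seed(21)
  cntp <- matrix(rpois(500 * 50, 100), 500, 50,
                 dimnames = list(paste0("g", 1:500), paste0("s", 1:50)))
  dp <- estimate_dispersion(cntp, rep(1, 50))
  expect_lt(median(dp$alpha), 0.01)
  # constant gene hits the floor exactly
  cntc <- rbind(flat = rep(10, 20), cntp[1:20, 1:20])
  dc <- estimate_dispersion(cntc, rep(1, 20))
  expect_equal(dc$alpha_mom[dc$gene == "flat"], 1e-8)
  expect_error(estimate_dispersion(cntp[, 1, drop = FALSE], 1),
               "single sample")
})

test_that("Wald tests are null-calibrated and unbiased for planted fold changes", {
  # identical groups: every fold change exactly zero
  cnt <- matrix(rep(c(5L, 20L, 80L), each = 8), 3, 8, byrow = TRUE,
                dimnames = list(paste0("g", 1:3), paste0("s", 1:8)))
  res0 <- wald_test(cnt, rep(1, 8), rep(0.1, 3), rep(c("a", "b"), each = 4))
  expect_equal(res0$lfc_mle, rep(0, 3), tolerance = 1e-6)
  expect_true(all(res0$p_raw > 0.99))

  # permuted-label null: p-values approximately uniform at 2000 genes
  sim <- make_de_counts(n_planted = 0, seed = 51)
  f <- filter_genes(sim$counts)$kept
  sf <- size_factors(f)
  res <- wald_test(f, sf, estimate_dispersion(f, sf), sim$groups)
  expect_lt(suppressWarnings(
    stats::ks.test(res$p_raw, "punif")$statistic), 0.05)

  # planted LFC = 2: mean estimate within +/- 0.3 over seeds
  bias <- vapply(1:10, function(s) {
    sim <- make_de_counts(n_genes = 400, n_planted = 40, lfc = 2,
                          seed = 100 + s)
    f <- filter_genes(sim$counts)$kept
    sf <- size_factors(f)
    res <- wald_test(f, sf, estimate_dispersion(f, sf), sim$groups)
    mean(res$lfc_mle[res$gene %in% sim$planted])
  }, numeric(1))
  expect_lt(abs(mean(bias) - 2), 0.3)

  # all-zero in one group: ridge keeps the estimate finite, p small
  cntz <- rbind(z = c(0L, 0L, 0L, 0L, 50L, 60L, 70L, 80L), cnt)
  resz <- wald_test(cntz, rep(1, 8), rep(0.05, 4),
                    rep(c("a", "b"), each = 4))
  expect_true(is.finite(resz$lfc_mle[resz$gene == "z"]))
  expect_gt(resz$lfc_mle[resz$gene == "z"], 5)
  expect_lt(resz$p_raw[resz$gene == "z"], 0.01)
})

test_that("shrinkage pulls noisy estimates toward zero, monotonically in SE", {
  set.seed(61)
  res <- tibble::tibble(
    gene = paste0("g", 1:200),
    lfc_mle = rnorm(200, 0, 1),
    se = runif(200, 0.1, 1)
  )
  sh <- shrink_lfc(res)
  expect_true(all(abs(sh$lfc_shrunken) <= abs(sh$lfc_mle) + 1e-9))
  expect_equal(sh$lfc_shrunken[sh$lfc_mle == 0], numeric(0)) # none exactly 0
  # zero MLE maps to zero
  res$lfc_mle[1] <- 0
  expect_equal(shrink_lfc(res)$lfc_shrunken[1], 0)
  # monotone: same MLE, larger SE, more shrinkage
  res2 <- tibble::tibble(gene = paste0("g", 1:20),
                         lfc_mle = rep(2, 20),
                         se = seq(0.05, 2, length.out = 20))
  sh2 <- shrink_lfc(res2)
  expect_true(all(diff(sh2$lfc_shrunken) < 0))
  # se -> 0 limit leaves the MLE untouched
  expect_lt(abs(sh2$lfc_shrunken[1] - 2), 0.05)
  # all-null input shrinks the average magnitude
  null_res <- tibble::tibble(gene = paste0("g", 1:100),
                             lfc_mle = rnorm(100, 0, 0.5),
                             se = rep(0.5, 100))
  shn <- shrink_lfc(null_res)
  expect_lt(mean(abs(shn$lfc_shrunken)), mean(abs(shn$lfc_mle)))
})

test_that("significance calls respect the dual threshold", {
  res <- tibble::tibble(
    gene = c("both", "p_only", "lfc_only", "neither"),
    lfc_mle = c(3, 0.6, 3, 0.2),
    se = rep(0.1, 4),
    lfc_shrunken = c(2.9, 0.5, 2.9, 0.1),
    p_raw = c(1e-6, 1e-6, 0.9, 0.9)
  )
  out <- suppressMessages(call_de(res))
  expect_identical(out$gene[out$significant], "both")
})

test_that("the full DE stage reaches the planted power, FDR and AUROC targets", {
  metrics <- sapply(1:10, function(s) {
    sim <- make_de_counts(seed = 200 + s) # 20 planted at LFC 3 among 2000
    f <- filter_genes(sim$counts)$kept
    sf <- size_factors(f)
    res <- suppressMessages(call_de(shrink_lfc(
      wald_test(f, sf, estimate_dispersion(f, sf), sim$groups))))
    isp <- res$gene %in% sim$planted
    c(power = mean(res$significant[isp]),
      fp = mean(res$significant[!isp]),
      auroc = auroc(abs(res$wald), isp))
  })
  expect_gte(mean(metrics["power", ]), 0.8)
  expect_lte(mean(metrics["fp", ]), 0.05)
  expect_gt(mean(metrics["auroc", ]), 0.95)
})

test_that("the quartile DE wrapper runs end to end on the default scenario", {
  sc <- make_default_scenario(71)
  sim <- simulate_cytokine_experiment(sc)
  eb <- simulate_expression_bundle(sc, sim$truth)
  sp <- score_polarization(sim$table, sim$lloq_map, control_units = "CTRL")
  de <- suppressMessages(quartile_de(eb$bundle, sp$quartiles, "VEGF"))
  expect_true(all(c("lfc_shrunken", "p_adj", "significant") %in% names(de)))
  # planted genes for the driving analyte rank above the nulls
  planted <- eb$truth$planted_genes$gene[
    eb$truth$planted_genes$analyte == "VEGF"]
  expect_gt(auroc(abs(de$wald), de$gene %in% planted), 0.95)
})
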